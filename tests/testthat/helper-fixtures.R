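# Shared fixtures: a minimal TIFF writer with resolution tags (the tiff
# package reads but cannot write them), a GeoJSON writer, and an
# independent BFS flood-fill labeler used as the oracle for the Rcpp
# union-find implementation.

# minimal little-endian uncompressed 8-bit RGB TIFF with X/YResolution
write_tiff_with_resolution <- function(path, pixels, microns_per_pixel) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  ppcm <- round(10000 / microns_per_pixel)  # ResolutionUnit = cm
  con <- file(path, "wb"); on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4,
                              endian = "little")
  writeBin(charToRaw("II"), con); u16(42L); u32(8L)
  ntags <- 13L
  off0 <- 8 + 2 + ntags * 12 + 4
  off_bps <- off0; off_xres <- off0 + 6; off_yres <- off0 + 14
  off_data <- off0 + 22
  u16(ntags)
  tag <- function(id, type, count, value) {
    u16(id); u16(type); u32(count); u32(value)
  }
  tag(256, 3, 1, w); tag(257, 3, 1, h); tag(258, 3, 3, off_bps)
  tag(259, 3, 1, 1); tag(262, 3, 1, 2); tag(273, 4, 1, off_data)
  tag(277, 3, 1, 3); tag(278, 3, 1, h); tag(279, 4, 1, h * w * 3)
  tag(282, 5, 1, off_xres); tag(283, 5, 1, off_yres); tag(284, 3, 1, 1)
  tag(296, 3, 1, 3)
  u32(0L)
  u16(c(8L, 8L, 8L))
  u32(c(ppcm, 1L)); u32(c(ppcm, 1L))
  writeBin(as.raw(aperm(pixels, c(3, 2, 1))), con)
  invisible(path)
}

# write an roi_set-shaped polygon list as GeoJSON
write_geojson_roi <- function(path, polygons) {
  feats <- lapply(polygons, function(p) {
    ring <- lapply(seq_len(nrow(p$xy)), function(i) as.numeric(p$xy[i, ]))
    ring <- c(ring, ring[1])
    props <- list(name = p$name)
    if (!is.null(p$role)) props$role <- p$role
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# independent oracle: BFS flood fill, 8-connectivity
flood_fill_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  k <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    k <- k + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- k
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ni <- cur[1] + di; nj <- cur[2] + dj
        if (ni < 1 || ni > h || nj < 1 || nj > w) next
        if (mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- k
          queue <- rbind(queue, c(ni, nj))
        }
      }
    }
  }
  lab
}

# brute-force DTBC recount from a stain mask: flood fill + explicit area
# comparisons, sharing no code with the package pipeline
brute_force_dtbc <- function(mask, calibration, artifact_min = 150,
                             bud_max = 950) {
  lab <- flood_fill_label(mask)
  if (max(lab) == 0) return(list(dtbc = 0L, n_regions = 0L))
  areas <- as.numeric(table(lab[lab > 0])) * calibration^2
  areas <- areas[areas >= artifact_min]
  list(dtbc = sum(areas < bud_max), n_regions = length(areas))
}

# quick random phantom spec for property tests
random_phantom_spec <- function(seed) {
  n_buds <- sample(0:8, 1)
  n_big <- sample(0:3, 1)
  n_art <- sample(0:4, 1)
  phantom_spec(
    canvas = c(260, 260), microns_per_pixel = 1,
    island_areas_um2 = c(runif(n_buds, 160, 900), runif(n_big, 1000, 2500)),
    island_shapes = sample(c("disc", "ellipse", "blob"),
                           n_buds + n_big, TRUE),
    artifact_areas_um2 = runif(n_art, 20, 140),
    noise_sd = 0, seed = seed)
}
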