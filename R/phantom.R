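#' Specification of a stained-island image phantom
#'
#' Describes a synthetic cytokeratin-stained section: DAB-stained tumor
#' islands of known area on a white or hematoxylin-tinted background, plus
#' optional sub-threshold staining artifacts. Ground truth areas are exact
#' because islands are rendered as a fixed number of pixels.
#'
#' @param canvas `c(H, W)` canvas size in pixels.
#' @param microns_per_pixel physical pixel size (um); default 1.
#' @param island_areas_um2 numeric vector of target island areas (um^2).
#' @param island_shapes character vector (recycled) of shapes per island:
#'   `"disc"`, `"ellipse"` or `"blob"`.
#' @param artifact_areas_um2 numeric vector of artifact areas; must all be
#'   below the 150 um^2 artifact floor.
#' @param dab_concentration DAB optical-density concentration of island
#'   pixels (scalar or per island); default 1.
#' @param background `"white"` or `"hematoxylin"` (a light blue tint of
#'   OD 0.25 hematoxylin).
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (grey levels); default 0.
#' @param seed integer seed; the only source of randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(canvas = c(256, 256), microns_per_pixel = 1,
                         island_areas_um2 = numeric(),
                         island_shapes = "disc",
                         artifact_areas_um2 = numeric(),
                         dab_concentration = 1,
                         background = c("white", "hematoxylin"),
                         noise_sd = 0, seed = 1L) {
  background <- match.arg(background)
  if (length(canvas) != 2 || any(canvas < 1)) stop2("bad canvas size")
  if (any(island_areas_um2 <= 0)) stop2("island areas must be positive")
  if (length(artifact_areas_um2) && any(artifact_areas_um2 >= 150))
    stop2("artifact areas must be < 150 um^2")
  total_px <- sum(c(island_areas_um2, artifact_areas_um2)) /
    microns_per_pixel^2
  if (total_px > 0.3 * prod(canvas))
    stop2("total island area exceeds 30% of the canvas; enlarge the canvas")
  structure(list(
    canvas = as.integer(canvas), microns_per_pixel = microns_per_pixel,
    island_areas_um2 = as.numeric(island_areas_um2),
    island_shapes = rep_len(island_shapes,
                            length(island_areas_um2)),
    artifact_areas_um2 = as.numeric(artifact_areas_um2),
    dab_concentration = rep_len(dab_concentration,
                                length(island_areas_um2)),
    background = background, noise_sd = noise_sd,
    seed = as.integer(seed)), class = "phantom_spec")
}

# offsets (di, dj) of exactly n connected pixels around the origin; the
# set is the n cells with smallest shape-dependent radial metric, so it is
# star-shaped and 8-connected
island_offsets <- function(n, shape) {
  r0 <- ceiling(sqrt(n / pi) * 2.6) + 2
  dd <- expand.grid(di = -r0:r0, dj = -r0:r0)
  th <- atan2(dd$di, dd$dj)
  r2 <- dd$di^2 + dd$dj^2
  d <- switch(shape,
    disc = r2,
    ellipse = {
      a <- runif(1, 1.3, 2.2)
      phi <- runif(1, 0, pi)
      u <- dd$dj * cos(phi) + dd$di * sin(phi)
      v <- -dd$dj * sin(phi) + dd$di * cos(phi)
      (u / a)^2 + (v * a)^2
    },
    blob = {
      k <- sample(3:5, 1)
      phi <- runif(1, 0, 2 * pi)
      r2 / (1 + 0.35 * sin(k * th + phi))
    },
    stop2("unknown island shape '", shape, "'"))
  ord <- order(d, r2, dd$di, dd$dj)[seq_len(n)]
  cbind(di = dd$di[ord], dj = dd$dj[ord])
}

#' Generate a stained-island phantom with exact ground truth
#'
#' Islands are placed by rejection sampling with at least 2 pixels of
#' separation (so 8-connected labeling can never merge two islands) and
#' rendered by Beer-Lambert mixing:
#' `I_c = 255 * 10^(-concentration * OD_c)`. Because each island occupies
#' exactly `round(area / mpp^2)` pixels, the recorded ground-truth areas
#' are the achieved, not merely the target, areas. Deterministic given the
#' spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` (a [calibrated_image()]), `rois` (an
#'   [roi_set()] covering the full canvas) and `ground_truth`, a
#'   data.frame with per-object `id`, `kind` (`island`/`artifact`),
#'   `shape`, `target_area_um2`, `pixel_count`, `area_um2`, `is_artifact`
#'   and `is_bud` (relative to the default [bud_params()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    h <- spec$canvas[1]; w <- spec$canvas[2]
    mpp <- spec$microns_per_pixel
    areas <- c(spec$island_areas_um2, spec$artifact_areas_um2)
    kinds <- rep(c("island", "artifact"),
                 c(length(spec$island_areas_um2),
                   length(spec$artifact_areas_um2)))
    shapes <- c(spec$island_shapes,
                rep("disc", length(spec$artifact_areas_um2)))
    concs <- c(spec$dab_concentration,
               rep(1, length(spec$artifact_areas_um2)))
    # place large objects first to ease packing
    ord <- order(-areas)
    occupied <- matrix(FALSE, h, w)   # island pixels
    blocked <- matrix(FALSE, h, w)    # island pixels dilated by 1
    conc_map <- matrix(0, h, w)
    gt <- vector("list", length(areas))
    for (i in ord) {
      n_px <- max(1L, as.integer(round(areas[i] / mpp^2)))
      off <- island_offsets(n_px, shapes[i])
      placed <- FALSE
      for (try in seq_len(400)) {
        ci <- sample.int(h, 1); cj <- sample.int(w, 1)
        ri <- ci + off[, "di"]; rj <- cj + off[, "dj"]
        if (min(ri) < 1 || max(ri) > h || min(rj) < 1 || max(rj) > w) next
        idx <- ri + (rj - 1) * h
        if (any(blocked[idx])) next
        occupied[idx] <- TRUE
        conc_map[idx] <- concs[i]
        for (di in -1:1) for (dj in -1:1) {
          bi <- pmin(pmax(ri + di, 1), h)
          bj <- pmin(pmax(rj + dj, 1), w)
          blocked[bi + (bj - 1) * h] <- TRUE
        }
        placed <- TRUE
        break
      }
      if (!placed)
        stop2("could not place an island of ", areas[i],
              " um^2 after 400 tries; use a larger canvas")
      gt[[i]] <- data.frame(
        id = i, kind = kinds[i], shape = shapes[i],
        target_area_um2 = areas[i], pixel_count = n_px,
        area_um2 = n_px * mpp^2)
    }
    gt <- do.call(rbind, gt)  # list slots are indexed by original id
    if (is.null(gt))
      gt <- data.frame(id = integer(), kind = character(),
                       shape = character(), target_area_um2 = numeric(),
                       pixel_count = integer(), area_um2 = numeric())
    bp <- bud_params()
    gt$is_artifact <- gt$area_um2 < bp$artifact_min_um2
    gt$is_bud <- !gt$is_artifact & gt$area_um2 < bp$bud_max_um2

    odm <- hdab_od_matrix()
    bg_od <- if (spec$background == "white") c(0, 0, 0) else
      0.25 * odm["hematoxylin", ]
    img <- array(0, c(h, w, 3))
    for (k in 1:3) {
      od_k <- bg_od[k] + conc_map * odm["dab", k]
      ch <- 255 * 10^(-od_k)
      if (spec$noise_sd > 0) ch <- ch + rnorm(h * w, sd = spec$noise_sd)
      img[, , k] <- pmin(pmax(round(ch), 0), 255)
    }
    full <- rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))
    list(image = calibrated_image(array(as.integer(img), dim(img)), mpp,
                                  sprintf("phantom(seed=%d)", spec$seed)),
         rois = roi_set(list(list(name = "canvas", role = "include",
                                  xy = full))),
         ground_truth = gt)
  })
}
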