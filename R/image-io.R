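#' Calibrated RGB section image
#'
#' Container for an RGB image together with its physical pixel size. All
#' downstream area arithmetic (artifact floor, bud ceiling) is done in
#' square micrometers, so the calibration is mandatory.
#'
#' @param pixels integer array `H x W x 3`, channel intensities in 0..255.
#' @param microns_per_pixel physical side length of one pixel in micrometers;
#'   must be strictly positive.
#' @param source_id free-text provenance string (defaults to empty).
#'
#' @return An object of class `calibrated_image` with fields `pixels`,
#'   `microns_per_pixel` and `source_id`.
#' @export
calibrated_image <- function(pixels, microns_per_pixel, source_id = "") {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stop2("`pixels` must be an H x W x 3 RGB array")
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    stop2("image must have at least one row and one column")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop2("channel intensities must lie in [0, 255]")
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0)
    stop2("`microns_per_pixel` must be a single positive number")
  structure(
    list(pixels = pixels, microns_per_pixel = as.numeric(microns_per_pixel),
         source_id = as.character(source_id)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px (%s)\n",
              d[1], d[2], x$microns_per_pixel,
              if (nzchar(x$source_id)) x$source_id else "unnamed"))
  invisible(x)
}

# micrometers per pixel from TIFF resolution attributes, NA when absent
.mpp_from_tiff_info <- function(img) {
  res <- attr(img, "x.resolution")
  if (is.null(res) || !is.finite(res) || res <= 0) return(NA_real_)
  unit <- attr(img, "resolution.unit")
  if (is.null(unit)) unit <- "inch"  # TIFF default ResolutionUnit
  switch(unit, inch = 25400 / res, cm = 10000 / res, NA_real_)
}

#' Read a calibrated RGB image from TIFF or PNG
#'
#' Calibration precedence: an explicit `microns_per_pixel` argument overrides
#' file metadata (TIFF X/YResolution tags, PNG pHYs/dpi); if neither is
#' available the read fails, since area filtering is meaningless without a
#' physical scale.
#'
#' @param path path to an 8-bit RGB TIFF or PNG file.
#' @param microns_per_pixel optional explicit calibration (um per pixel).
#' @param source_id provenance label; defaults to the file name.
#'
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, microns_per_pixel = NULL,
                       source_id = basename(path)) {
  if (!file.exists(path)) stop2("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    mpp_meta <- .mpp_from_tiff_info(img)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    mpp_meta <- if (!is.null(info$dpi) && is.finite(info$dpi[1]) &&
                    info$dpi[1] > 0) 25400 / info$dpi[1] else NA_real_
  } else {
    stop2("unsupported image format '", ext, "' (expected TIFF or PNG): ",
          path)
  }
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop2("not an RGB image (expected 3 channels): ", path)
  if (dim(img)[3] > 3)
    stop2("not a plain RGB image (got ", dim(img)[3], " channels): ", path)
  mpp <- if (!is.null(microns_per_pixel)) microns_per_pixel else mpp_meta
  if (is.null(mpp) || is.na(mpp))
    stop2("no calibration: supply `microns_per_pixel` or embed resolution ",
          "metadata in ", path)
  px <- array(as.integer(round(img * 255)), dim = dim(img))
  calibrated_image(px, mpp, source_id)
}

#' Region-of-interest polygon set
#'
#' Polygons delineate the tumor region (`include`) and areas to drop from
#' analysis such as necrosis or salivary glands (`exclude`). Coordinates are
#' in pixel units with the origin at the top-left pixel center, x rightward
#' and y downward.
#'
#' @param polygons list of lists with fields `name`, `role`
#'   (`"include"`/`"exclude"`) and `xy` (n x 2 vertex matrix).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(polygons) {
  for (p in polygons) {
    if (!is.matrix(p$xy) || ncol(p$xy) != 2 || nrow(p$xy) < 3)
      stop2("polygon '", p$name, "' must have at least 3 vertices")
    if (!p$role %in% c("include", "exclude"))
      stop2("polygon '", p$name, "' has unknown role '", p$role,
            "' (expected include or exclude)")
  }
  structure(list(polygons = polygons), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  roles <- vapply(x$polygons, `[[`, "", "role")
  cat(sprintf("<roi_set> %d polygon(s): %d include, %d exclude\n",
              length(roles), sum(roles == "include"),
              sum(roles == "exclude")))
  invisible(x)
}

#' Load an ROI polygon set from a GeoJSON FeatureCollection
#'
#' Each feature must carry a polygon geometry; a `role` property of
#' `"include"` or `"exclude"` selects how it enters the analysis mask
#' (missing role defaults to `include`). Only the outer ring of each polygon
#' is used. Coordinates are pixel units (see [roi_set()]).
#'
#' @param path path to a GeoJSON file.
#' @return An [roi_set()].
#' @export
load_roi <- function(path) {
  if (!file.exists(path)) stop2("ROI file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop2("not a GeoJSON FeatureCollection: ", path)
  polys <- lapply(seq_along(gj$features), function(i) {
    ft <- gj$features[[i]]
    if (is.null(ft$geometry) || !identical(ft$geometry$type, "Polygon"))
      stop2("feature ", i, " has unsupported geometry (expected Polygon)")
    ring <- ft$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(v) as.numeric(v[1:2])))
    # GeoJSON rings repeat the first vertex at the end
    if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ]))
      xy <- xy[-nrow(xy), , drop = FALSE]
    role <- ft$properties$role
    if (is.null(role)) role <- "include"
    name <- ft$properties$name
    if (is.null(name)) name <- paste0("roi_", i)
    if (nrow(xy) < 3)
      stop2("feature ", i, " ('", name, "') has fewer than 3 vertices")
    list(name = name, role = role, xy = xy)
  })
  roi_set(polys)
}

# Even-odd rasterization of one polygon onto an h x w pixel grid.
# Pixel (i, j) has its center at (x, y) = (j - 1, i - 1). The crossing test
# is half-open, so a point on a left/bottom edge is inside and on a
# right/top edge outside; rasterization is therefore deterministic and
# adjacent polygons tile without double-covered pixels.
rasterize_polygon <- function(xy, h, w) {
  px <- 0:(w - 1)
  py <- 0:(h - 1)
  cross <- matrix(0L, h, w)
  n <- nrow(xy)
  j <- n
  for (i in seq_len(n)) {
    x1 <- xy[j, 1]; y1 <- xy[j, 2]
    x2 <- xy[i, 1]; y2 <- xy[i, 2]
    straddle <- (y1 > py) != (y2 > py)
    if (any(straddle)) {
      xint <- x1 + (py[straddle] - y1) * (x2 - x1) / (y2 - y1)
      cross[straddle, ] <- cross[straddle, ] + outer(xint, px, ">")
    }
    j <- i
  }
  cross %% 2L == 1L
}

#' Build the analysis mask from an image and its ROI set
#'
#' The mask is true inside the union of the include polygons and outside the
#' union of the exclude polygons, evaluated at pixel centers with even-odd
#' filling.
#'
#' @param image a [calibrated_image()].
#' @param rois an [roi_set()]; must contain at least one include polygon.
#' @return An object of class `analysis_mask` with fields `mask` (H x W
#'   logical) and `calibration` (um/pixel, inherited from the image).
#' @export
build_mask <- function(image, rois) {
  stopifnot(inherits(image, "calibrated_image"), inherits(rois, "roi_set"))
  roles <- vapply(rois$polygons, `[[`, "", "role")
  if (!any(roles == "include"))
    stop2("ROI set has no include polygon")
  h <- dim(image$pixels)[1]
  w <- dim(image$pixels)[2]
  mk <- matrix(FALSE, h, w)
  for (p in rois$polygons[roles == "include"])
    mk <- mk | rasterize_polygon(p$xy, h, w)
  for (p in rois$polygons[roles == "exclude"])
    mk <- mk & !rasterize_polygon(p$xy, h, w)
  if (!any(mk))
    warning("analysis mask is empty; downstream bud count will be 0",
            call. = FALSE)
  structure(list(mask = mk, calibration = image$microns_per_pixel),
            class = "analysis_mask")
}

#' Physical area of a mask
#'
#' @param mask an `analysis_mask` or `stain_mask`.
#' @return Total true area in square micrometers
#'   (`popcount(mask) * calibration^2`).
#' @export
mask_area_um2 <- function(mask) {
  stopifnot(inherits(mask, c("analysis_mask", "stain_mask")))
  sum(mask$mask) * mask$calibration^2
}

#' Write a binary mask as a PNG for audit
#'
#' @param mask an `analysis_mask` or `stain_mask`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, c("analysis_mask", "stain_mask")))
  png::writePNG(matrix(as.numeric(mask$mask), nrow(mask$mask)), path)
  invisible(path)
}
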