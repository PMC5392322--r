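#' Standard H-DAB optical-density stain matrix
#'
#' Rows are unit-norm optical-density vectors for hematoxylin, DAB and a
#' residual channel (the normalized cross product of the first two, so the
#' matrix is always invertible). These are the widely used published values
#' for hematoxylin/DAB immunohistochemistry; slides stained with a
#' non-standard protocol can override them in [stain_params()].
#'
#' @return A 3 x 3 numeric matrix with rownames `hematoxylin`, `dab`,
#'   `residual` and colnames `R`, `G`, `B`.
#' @export
hdab_od_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(h / sqrt(sum(h^2)), d / sqrt(sum(d^2)), r / sqrt(sum(r^2)))
  dimnames(m) <- list(c("hematoxylin", "dab", "residual"), c("R", "G", "B"))
  m
}

#' Stain separation parameters
#'
#' @param od_matrix 3 x 3 matrix of stain optical-density vectors (rows:
#'   hematoxylin, DAB, residual); rows are normalized to unit Euclidean
#'   norm. Default: [hdab_od_matrix()].
#' @param dab_od_threshold minimum DAB concentration (optical-density
#'   units) for a pixel to count as stained; default 0.15. The original
#'   semi-automated workflow tuned this visually per protocol; here it is
#'   an explicit, recorded parameter.
#' @param analysis_scale_factor integer >= 1; block down-sampling factor
#'   from scan resolution to analysis resolution. Default 4, i.e. a 20x
#'   scan analyzed at 5x.
#'
#' @return An object of class `stain_params`.
#' @export
stain_params <- function(od_matrix = hdab_od_matrix(),
                         dab_od_threshold = 0.15,
                         analysis_scale_factor = 4L) {
  if (!is.matrix(od_matrix) || !all(dim(od_matrix) == c(3, 3)))
    stop2("`od_matrix` must be 3 x 3")
  norms <- sqrt(rowSums(od_matrix^2))
  if (any(norms == 0)) stop2("`od_matrix` has a zero row")
  od_matrix <- od_matrix / norms
  if (abs(det(od_matrix)) < 1e-8)
    stop2("`od_matrix` is singular; stain vectors must be independent")
  if (!is.numeric(dab_od_threshold) || length(dab_od_threshold) != 1 ||
      dab_od_threshold < 0)
    stop2("`dab_od_threshold` must be a single non-negative number")
  if (!is_count(analysis_scale_factor) || analysis_scale_factor < 1)
    stop2("`analysis_scale_factor` must be an integer >= 1")
  structure(list(od_matrix = od_matrix,
                 dab_od_threshold = as.numeric(dab_od_threshold),
                 analysis_scale_factor = as.integer(analysis_scale_factor)),
            class = "stain_params")
}

#' RGB intensities to optical densities
#'
#' Beer-Lambert transform `OD_c = -log10((I_c + 1) / 255)`, clamped at 0.
#' The +1 offset avoids an infinite density at zero intensity and biases
#' densities by less than 0.002 at full transmission.
#'
#' @param pixels numeric array/matrix/vector of intensities in 0..255.
#' @return Optical densities, same shape as `pixels`, all >= 0.
#' @export
rgb_to_od <- function(pixels) {
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop2("intensities must lie in [0, 255]")
  od <- -log10((pixels + 1) / 255)
  od[od < 0] <- 0
  od
}

#' Unmix optical densities into per-stain concentrations
#'
#' Solves the linear Beer-Lambert mixing model `od = conc %*% od_matrix`
#' for the concentrations, so re-mixing the result reproduces the input to
#' numerical precision.
#'
#' @param od numeric array with trailing dimension 3 (H x W x 3), or an
#'   n x 3 matrix, of optical densities.
#' @param params a [stain_params()].
#' @return Concentrations, same shape as `od`; slices/columns are
#'   (hematoxylin, dab, residual).
#' @export
deconvolve <- function(od, params = stain_params()) {
  stopifnot(inherits(params, "stain_params"))
  dm <- dim(od)
  flat <- matrix(od, ncol = 3)  # column-major: channel is the trailing dim
  conc <- flat %*% solve(params$od_matrix)
  if (is.null(dm)) as.numeric(conc) else array(conc, dim = dm)
}

#' Segment DAB-positive tissue at analysis resolution
#'
#' Block-averages the image by `analysis_scale_factor` (emulating analysis
#' at a lower magnification than the scan), unmixes stains, and thresholds
#' the DAB concentration within the analysis region. A down-sampled block
#' belongs to the analysis region when at least half of its source pixels
#' are inside the analysis mask.
#'
#' @param image a [calibrated_image()].
#' @param mask an `analysis_mask` from [build_mask()] with the same
#'   dimensions as the image.
#' @param params a [stain_params()].
#' @return An object of class `stain_mask` with fields `mask` (logical,
#'   `ceil(H/f) x ceil(W/f)`), `calibration` (um/px at analysis
#'   resolution) and `params_used`.
#' @export
segment_dab <- function(image, mask, params = stain_params()) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(mask, "analysis_mask"),
            inherits(params, "stain_params"))
  d <- dim(image$pixels)
  if (!all(dim(mask$mask) == d[1:2]))
    stop2("image and mask dimensions disagree")
  f <- params$analysis_scale_factor
  if (f > min(d[1:2]))
    stop2("analysis_scale_factor (", f, ") exceeds the image extent")
  rgb_small <- lapply(1:3, function(k) block_mean(image$pixels[, , k], f))
  od <- vapply(rgb_small, rgb_to_od,
               matrix(0, nrow(rgb_small[[1]]), ncol(rgb_small[[1]])))
  conc <- deconvolve(od, params)
  dab <- conc[, , 2]
  region <- block_mean(mask$mask * 1, f) >= 0.5
  structure(list(mask = (dab >= params$dab_od_threshold) & region,
                 calibration = image$microns_per_pixel * f,
                 params_used = params),
            class = "stain_mask")
}
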