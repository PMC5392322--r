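#' Bud classification parameters
#'
#' A tumor bud is conventionally an isolated island of up to five tumor
#' cells. With an average single-cell cross-section area of 190 um^2, the
#' default bud ceiling is `5 x 190 = 950` um^2; labeled areas under
#' 150 um^2 are removed as staining artifacts before counting.
#'
#' @param cell_area_um2 average cross-section area of one tumor cell
#'   (um^2); default 190.
#' @param n_cells maximum number of cells in a bud, integer in 1..20;
#'   default 5.
#' @param artifact_min_um2 areas strictly below this floor (um^2) are
#'   discarded as artifacts; default 150.
#' @param bud_rule `"strict"` counts areas `< bud_max_um2` as buds
#'   (default); `"inclusive"` counts `<=`.
#'
#' @return An object of class `bud_params` with the derived field
#'   `bud_max_um2 = n_cells * cell_area_um2`.
#' @export
bud_params <- function(cell_area_um2 = 190, n_cells = 5L,
                       artifact_min_um2 = 150,
                       bud_rule = c("strict", "inclusive")) {
  bud_rule <- match.arg(bud_rule)
  if (!is.numeric(cell_area_um2) || cell_area_um2 <= 0)
    stop2("`cell_area_um2` must be positive")
  if (!is_count(n_cells) || n_cells < 1 || n_cells > 20)
    stop2("`n_cells` must be an integer in [1, 20]")
  if (!is.numeric(artifact_min_um2) || artifact_min_um2 <= 0)
    stop2("`artifact_min_um2` must be positive")
  bud_max <- n_cells * cell_area_um2
  if (bud_max <= artifact_min_um2)
    stop2("bud ceiling (", bud_max, " um^2) must exceed the artifact floor (",
          artifact_min_um2, " um^2)")
  structure(list(cell_area_um2 = as.numeric(cell_area_um2),
                 n_cells = as.integer(n_cells),
                 artifact_min_um2 = as.numeric(artifact_min_um2),
                 bud_max_um2 = as.numeric(bud_max),
                 bud_rule = bud_rule),
            class = "bud_params")
}

#' Label connected stained regions
#'
#' Connected components of the stained-tissue mask under 8-connectivity
#' (diagonal contacts join, so a single cell touching a neighbour corner to
#' corner is not split). Region areas are physical:
#' `pixel_count * calibration^2`.
#'
#' @param stain_mask a `stain_mask` from [segment_dab()] (or any object
#'   with a logical `mask` and a `calibration` in um/px).
#' @return An object of class `labeled_regions`: a list with `regions`
#'   (data.frame: `label`, `pixel_count`, `area_um2`, `centroid_x`,
#'   `centroid_y` in analysis-pixel coordinates) and `calibration`.
#' @export
label_regions <- function(stain_mask) {
  stopifnot(inherits(stain_mask, "stain_mask") ||
              (is.list(stain_mask) && is.matrix(stain_mask$mask)))
  m <- stain_mask$mask
  lab <- label_components_8(m)
  k <- max(lab)
  if (k == 0) {
    regions <- data.frame(label = integer(), pixel_count = integer(),
                          area_um2 = numeric(), centroid_x = numeric(),
                          centroid_y = numeric())
  } else {
    idx <- which(lab > 0)
    l <- lab[idx]
    rows <- (idx - 1) %% nrow(m) + 1
    cols <- (idx - 1) %/% nrow(m) + 1
    counts <- tabulate(l, k)
    regions <- data.frame(
      label = seq_len(k),
      pixel_count = counts,
      area_um2 = counts * stain_mask$calibration^2,
      centroid_x = as.numeric(rowsum(cols - 1, l)) / counts,
      centroid_y = as.numeric(rowsum(rows - 1, l)) / counts)
  }
  structure(list(regions = regions, calibration = stain_mask$calibration),
            class = "labeled_regions")
}

#' Construct labeled regions from known areas
#'
#' Convenience constructor for working directly with a table of region
#' areas (for example areas exported by other image-analysis software).
#'
#' @param area_um2 numeric vector of positive region areas in um^2.
#' @param calibration um/px bookkeeping value (default 1).
#' @return A `labeled_regions` object.
#' @export
labeled_regions_from_areas <- function(area_um2, calibration = 1) {
  if (any(area_um2 <= 0)) stop2("region areas must be positive")
  structure(list(
    regions = data.frame(label = seq_along(area_um2),
                         pixel_count = as.integer(round(area_um2 /
                                                          calibration^2)),
                         area_um2 = as.numeric(area_um2),
                         centroid_x = rep(NA_real_, length(area_um2)),
                         centroid_y = rep(NA_real_, length(area_um2))),
    calibration = calibration), class = "labeled_regions")
}

#' Remove staining artifacts by area
#'
#' Drops regions with an area strictly below the artifact floor (a region
#' of exactly `artifact_min_um2` is retained). Label identities of the
#' surviving regions are preserved, so the operation is idempotent.
#'
#' @param regions a `labeled_regions` object.
#' @param params a [bud_params()].
#' @return The filtered `labeled_regions`.
#' @export
filter_artifacts <- function(regions, params = bud_params()) {
  stopifnot(inherits(regions, "labeled_regions"),
            inherits(params, "bud_params"))
  keep <- regions$regions$area_um2 >= params$artifact_min_um2
  regions$regions <- regions$regions[keep, , drop = FALSE]
  rownames(regions$regions) <- NULL
  regions
}

#' Classify buds and compute the digital tumor bud count
#'
#' Applies the artifact filter (idempotently) and counts the remaining
#' regions whose area falls below the bud ceiling. With the defaults this
#' is the number of labeled islands with `150 <= area < 950` um^2.
#'
#' @param regions a `labeled_regions` object (artifact filtering is
#'   re-applied, so unfiltered input is accepted).
#' @param params a [bud_params()].
#' @return An object of class `bud_count_result`: list with `dtbc`,
#'   `n_regions_total` (post artifact filter), `region_areas_um2` (sorted),
#'   `bud_areas_um2` (sorted) and `params`.
#' @export
classify_buds <- function(regions, params = bud_params()) {
  regions <- filter_artifacts(regions, params)
  a <- sort(regions$regions$area_um2)
  is_bud <- if (params$bud_rule == "strict") a < params$bud_max_um2 else
    a <= params$bud_max_um2
  structure(list(dtbc = sum(is_bud),
                 n_regions_total = length(a),
                 region_areas_um2 = a,
                 bud_areas_um2 = a[is_bud],
                 params = params),
            class = "bud_count_result")
}

#' @export
print.bud_count_result <- function(x, ...) {
  cat(sprintf(paste0("<bud_count_result> DTBC = %d of %d regions ",
                     "(artifact floor %g um^2, bud ceiling %g um^2, %s)\n"),
              x$dtbc, x$n_regions_total, x$params$artifact_min_um2,
              x$params$bud_max_um2, x$params$bud_rule))
  invisible(x)
}

#' Digital tumor bud count for one section image
#'
#' End-to-end scoring of a calibrated section image: analysis mask from the
#' ROI polygons, DAB segmentation at analysis resolution, connected-
#' component labeling, artifact removal, and bud classification. Fully
#' deterministic.
#'
#' @param image a [calibrated_image()].
#' @param rois an [roi_set()].
#' @param stain a [stain_params()].
#' @param bud a [bud_params()].
#' @return A `bud_count_result` (see [classify_buds()]) with the
#'   additional field `regions`, the artifact-filtered `labeled_regions`.
#' @export
compute_dtbc <- function(image, rois, stain = stain_params(),
                         bud = bud_params()) {
  mask <- build_mask(image, rois)
  sm <- segment_dab(image, mask, stain)
  regions <- label_regions(sm)
  res <- classify_buds(regions, bud)
  res$regions <- filter_artifacts(regions, bud)
  res
}

#' Sweep the bud definition over 1..20 cells
#'
#' Recomputes the bud count per patient for every candidate bud definition
#' of `n` cells, i.e. counting labeled areas `>= artifact_min_um2` and
#' below `n * cell_area_um2`. Per patient the counts are non-decreasing in
#' `n` because the thresholds are cumulative.
#'
#' @param region_tables a named list of `labeled_regions` (one per
#'   patient), or a single `labeled_regions`.
#' @param n_range integer vector of cell counts; default `1:20`.
#' @param bud a [bud_params()] supplying `cell_area_um2`,
#'   `artifact_min_um2` and the counting rule.
#' @return data.frame with columns `patient`, `n_cells`, `threshold_um2`,
#'   `count`.
#' @export
sweep_bud_definitions <- function(region_tables, n_range = 1:20,
                                  bud = bud_params()) {
  if (inherits(region_tables, "labeled_regions"))
    region_tables <- list(patient_1 = region_tables)
  if (length(n_range) == 0) stop2("`n_range` must be non-empty")
  if (any(n_range != round(n_range)) || any(n_range < 1))
    stop2("`n_range` must contain positive integers")
  if (is.null(names(region_tables)))
    names(region_tables) <- paste0("patient_", seq_along(region_tables))
  out <- lapply(names(region_tables), function(id) {
    a <- region_tables[[id]]$regions$area_um2
    a <- a[a >= bud$artifact_min_um2]
    thr <- n_range * bud$cell_area_um2
    cnt <- vapply(thr, function(t)
      if (bud$bud_rule == "strict") sum(a < t) else sum(a <= t), 0L)
    data.frame(patient = id, n_cells = as.integer(n_range),
               threshold_um2 = thr, count = cnt)
  })
  do.call(rbind, out)
}
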