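stain1 <- stain_params(analysis_scale_factor = 1L)

mask_of <- function(m, calibration = 1)
  structure(list(mask = m, calibration = calibration,
                 params_used = stain1), class = "stain_mask")

test_that("region labeling computes areas and honors 8-connectivity", {
  m <- matrix(FALSE, 8, 8)
  m[2:4, 2:4] <- TRUE
  lr <- label_regions(mask_of(m, calibration = 1))
  expect_equal(nrow(lr$regions), 1)
  expect_equal(lr$regions$area_um2, 9)

  diag2 <- matrix(FALSE, 5, 5)
  diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE  # diagonal contact only
  expect_equal(nrow(label_regions(mask_of(diag2))$regions), 1)

  expect_equal(nrow(label_regions(mask_of(matrix(FALSE, 4, 4)))$regions), 0)

  # calibration turns pixel counts into physical areas
  lr2 <- label_regions(mask_of(m, calibration = 2))
  expect_equal(lr2$regions$area_um2, 9 * 4)
})

test_that("labeling matches an independent flood-fill oracle on random masks", {
  set.seed(77)
  for (i in 1:100) {
    m <- matrix(runif(30 * 30) < 0.25, 30, 30)
    ours <- label_regions(mask_of(m))$regions
    oracle <- flood_fill_label(m)
    expect_equal(nrow(ours), max(oracle))
    expect_equal(sort(ours$pixel_count),
                 sort(as.integer(table(oracle[oracle > 0]))))
  }
})

test_that("artifact filtering is a strict-below floor and idempotent", {
  lr <- labeled_regions_from_areas(c(100, 890, 885, 1297))
  kept <- filter_artifacts(lr)
  expect_setequal(kept$regions$area_um2, c(890, 885, 1297))
  # boundary: exactly 150 is retained
  expect_equal(filter_artifacts(
    labeled_regions_from_areas(c(150, 149.9)))$regions$area_um2, 150)
  # idempotent, labels preserved
  expect_identical(filter_artifacts(kept), kept)
  empty <- labeled_regions_from_areas(numeric())
  expect_equal(nrow(filter_artifacts(empty)$regions), 0)
})

test_that("bud classification reproduces the worked three-island example", {
  res <- classify_buds(labeled_regions_from_areas(c(890, 885, 1297)))
  expect_equal(res$dtbc, 2)
  expect_equal(res$bud_areas_um2, c(885, 890))
  expect_equal(res$n_regions_total, 3)
  # ceiling is strict by default, inclusive on request
  expect_equal(classify_buds(labeled_regions_from_areas(950))$dtbc, 0)
  expect_equal(classify_buds(labeled_regions_from_areas(950),
                             bud_params(bud_rule = "inclusive"))$dtbc, 1)
  expect_equal(classify_buds(labeled_regions_from_areas(numeric()))$dtbc, 0)
})

test_that("bud parameter arithmetic and validation hold", {
  bp <- bud_params()
  expect_equal(bp$bud_max_um2, 950)
  expect_equal(bp$bud_max_um2, bp$n_cells * bp$cell_area_um2)
  expect_error(bud_params(n_cells = 21), "1, 20")
  expect_error(bud_params(n_cells = 1, cell_area_um2 = 100,
                          artifact_min_um2 = 150), "exceed")
})

test_that("compute_dtbc scores constructed phantoms exactly", {
  sp <- phantom_spec(canvas = c(320, 320),
                     island_areas_um2 = c(rep(400, 12), rep(2000, 3)),
                     artifact_areas_um2 = rep(80, 5), seed = 31)
  ph <- generate_phantom(sp)
  res <- compute_dtbc(ph$image, ph$rois, stain1)
  expect_equal(res$dtbc, 12)
  expect_equal(res$n_regions_total, 15)

  blank <- generate_phantom(phantom_spec(canvas = c(60, 60), seed = 1))
  expect_equal(suppressWarnings(
    compute_dtbc(blank$image, blank$rois, stain1))$dtbc, 0)

  # islands enlarged 3x in area cross the bud ceiling
  sp3 <- phantom_spec(canvas = c(320, 320),
                      island_areas_um2 = rep(1200, 12), seed = 31)
  ph3 <- generate_phantom(sp3)
  res3 <- compute_dtbc(ph3$image, ph3$rois, stain1)
  expect_equal(res3$dtbc, 0)
  expect_equal(res3$n_regions_total, 12)
})

test_that("dtbc is monotone in the bud definition parameters", {
  areas <- c(120, 160, 300, 800, 940, 960, 1500, 2600)
  lr <- labeled_regions_from_areas(areas)
  counts <- vapply(1:20, function(n)
    classify_buds(lr, bud_params(n_cells = n))$dtbc, 0L)
  expect_true(all(diff(counts) >= 0))
  d1 <- classify_buds(lr, bud_params(artifact_min_um2 = 100))$dtbc
  d2 <- classify_buds(lr, bud_params(artifact_min_um2 = 200))$dtbc
  expect_gte(d1, d2)
})

test_that("dtbc is invariant under joint rescaling of pixel size and extent", {
  # same physical areas rendered at two pixel sizes
  areas <- c(300, 500, 700, 1800)
  ph_a <- generate_phantom(phantom_spec(canvas = c(200, 200),
    microns_per_pixel = 1, island_areas_um2 = areas, seed = 17))
  ph_b <- generate_phantom(phantom_spec(canvas = c(400, 400),
    microns_per_pixel = 0.5, island_areas_um2 = areas, seed = 17))
  ra <- compute_dtbc(ph_a$image, ph_a$rois, stain1)
  rb <- compute_dtbc(ph_b$image, ph_b$rois, stain1)
  expect_equal(ra$dtbc, rb$dtbc)
  expect_equal(ra$n_regions_total, rb$n_regions_total)
})

test_that("the bud-definition sweep follows the threshold arithmetic", {
  lr <- labeled_regions_from_areas(c(890, 885, 1297))
  sw <- sweep_bud_definitions(lr)
  expect_equal(sw$threshold_um2, 1:20 * 190)
  expect_equal(sw$count[sw$n_cells == 1], 0)
  expect_equal(sw$count[sw$n_cells == 5], 2)
  expect_equal(sw$count[sw$n_cells == 7], 3)
  expect_true(all(diff(sw$count) >= 0))

  # a single 190 um^2 island is counted from n = 2 upward only (strict <)
  sw1 <- sweep_bud_definitions(labeled_regions_from_areas(190))
  expect_equal(sw1$count, as.integer(1:20 > 1))

  expect_error(sweep_bud_definitions(lr, n_range = integer()), "non-empty")
})
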