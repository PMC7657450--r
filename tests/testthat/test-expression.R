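test_that("pattern expression is a Pearson correlation over the mask", {
  g <- small_grid(12, full = TRUE)
  set.seed(1)
  w <- array(rnorm(prod(g$shape)), g$shape)
  p <- structure(list(weights = w, grid = g), class = "pattern_map")

  expect_equal(pattern_expression(w, p), 1)
  expect_equal(pattern_expression(-2 * w + 7, p), -1)

  ## 100 random pairs against the two-pass textbook oracle
  for (i in 1:20) {
    x <- array(rnorm(prod(g$shape)), g$shape)
    y <- array(rnorm(prod(g$shape)), g$shape)
    m <- array(runif(prod(g$shape)) < 0.5, g$shape)
    expect_equal(pattern_expression(x, y, analysis_mask = m),
                 pearson_oracle(x[m], y[m]), tolerance = 1e-12)
  }

  ## degenerate image flags NA with a warning, never a silent zero
  expect_warning(r <- pattern_expression(array(3, g$shape), p), "zero variance")
  expect_true(is.na(r))
  expect_error(pattern_expression(w, p, analysis_mask = array(FALSE, g$shape)),
               "fewer than 10")
})

test_that("ROI means obey their arithmetic identities", {
  g <- small_grid(10, full = TRUE)
  img <- array(rnorm(1000), g$shape)
  roi1 <- array(FALSE, g$shape); roi1[1:3, 1, 1] <- TRUE
  roi2 <- array(FALSE, g$shape); roi2[5:10, 2, 2] <- TRUE

  expect_equal(roi_mean(array(2.7, g$shape), roi1), 2.7)
  single <- array(FALSE, g$shape); single[4, 4, 4] <- TRUE
  expect_equal(roi_mean(img, single), img[4, 4, 4])

  ## union mean is the size-weighted mean of the parts
  u <- roi1 | roi2
  expect_equal(roi_mean(img, u),
               (3 * roi_mean(img, roi1) + 6 * roi_mean(img, roi2)) / 9,
               tolerance = 1e-12)
  expect_error(roi_mean(img, array(FALSE, g$shape)), "empty")
})

test_that("feature tables have one row per trial with joined outcomes", {
  st <- toy_study(P = 2, A = 4, seed = 2)
  ft <- build_feature_table(st)
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(ft), 8L)
  expect_true(all(c("expression_r", "roi_mean", "roi_vs", "roi_vmpfc",
                    "rating", "log_shares", "study") %in% names(ft)))
  ## log_shares constant within article
  spread <- tapply(ft$log_shares, ft$article_id, function(x) diff(range(x)))
  expect_true(all(spread == 0))

  ## dropped beta volume is an explicit error
  st2 <- st
  st2$betas[[1]][4] <- list(NULL)
  expect_error(build_feature_table(st2), "missing beta")

  ## unjoinable article id
  st3 <- st
  st3$trials$article_id[1] <- 99L
  expect_error(build_feature_table(st3), "article_id")
})

test_that("overlap masking removes ROI voxels and whole touching clusters", {
  g <- small_grid(24)
  p <- make_reference_pattern(g, n_pos = 4, n_neg = 2, cluster_radius_mm = 9,
                              peak_z = 4, bg_sd = 0.3, seed = 2)
  rois <- make_rois(g, p, radius_mm = 6)
  cs <- threshold_pattern(p, 2.56, k_extent = 5)
  masked <- mask_out_overlap(p, cs, rois)

  ## every ROI voxel is zeroed
  expect_true(all(masked$weights[rois$combined_mask] == 0))
  ## clusters intersecting an ROI are zeroed in full (ROIs sit on the two
  ## strongest positive bumps, so at least one cluster is hit)
  hit <- setdiff(unique(cs$labels[rois$combined_mask]), 0L)
  expect_gte(length(hit), 1L)
  for (cl in hit) expect_true(all(masked$weights[cs$labels == cl] == 0))
  ## clusters not touching an ROI keep their weights
  keep <- setdiff(seq_along(cs$sizes), hit)
  for (cl in keep) {
    expect_identical(masked$weights[cs$labels == cl],
                     p$weights[cs$labels == cl])
  }

  ## masking almost everything is an error
  tiny <- p
  tiny$weights[!rois$combined_mask] <- 0
  expect_error(mask_out_overlap(tiny, cs, rois), "fewer than 10")
})

test_that("the smoothing sweep recomputes expression per kernel", {
  st <- toy_study(P = 2, A = 4, seed = 5)
  base <- build_feature_table(st)
  sw <- smoothing_sweep(st$pattern, c(0, 8, 16), st)
  expect_equal(length(sw), 3L)
  expect_named(sw, c("fwhm_0", "fwhm_8", "fwhm_16"))
  ## kernel 0 reproduces the baseline exactly
  expect_equal(sw$fwhm_0$expression_r, base$expression_r)
  ## kernel 8 equals independently smoothing the pattern first
  ps <- st$pattern
  ps$weights <- gaussian_smooth(st$pattern$weights, 8, st$grid)
  indep <- build_feature_table(st, pattern = ps,
                               analysis_mask = st$grid$brain_mask &
                                 is.finite(st$pattern$weights))
  expect_equal(sw$fwhm_8$expression_r, indep$expression_r, tolerance = 1e-12)
  ## default kernel ladder has 11 entries
  expect_equal(length(seq(0, 40, by = 4)), 11L)
})

test_that("expression is invariant to affine maps and flips sign correctly", {
  g <- small_grid(12, full = TRUE)
  set.seed(3)
  img <- array(rnorm(prod(g$shape)), g$shape)
  w <- array(rnorm(prod(g$shape)), g$shape)
  m <- array(TRUE, g$shape)
  base <- pattern_expression(img, w, m)
  expect_equal(pattern_expression(5 * img + 2, w, m), base, tolerance = 1e-12)
  expect_equal(pattern_expression(img, 0.3 * w - 1, m), base,
               tolerance = 1e-12)
  expect_equal(pattern_expression(-img, w, m), -base, tolerance = 1e-12)
})
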