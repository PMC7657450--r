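test_that("canonical HRF has the double-gamma shape and sampling", {
  h <- canonical_hrf(1.5, 32)
  expect_equal(length(h), 22L)          # floor(32/1.5) + 1 samples
  expect_equal(h[1], 0)
  ## scaled against the continuous peak: fine sampling attains 1, coarse
  ## sampling stays just below it
  expect_gt(max(h), 0.9)
  expect_lte(max(h), 1)
  hd <- canonical_hrf(0.01, 32)
  expect_equal(max(hd), 1, tolerance = 1e-6)

  ## peak of the continuous response sits at 5 s
  t_peak <- (which.max(hd) - 1) * 0.01
  expect_lte(abs(t_peak - 5), 0.1)

  expect_error(canonical_hrf(0, 32))
  expect_error(canonical_hrf(1.5, 10))
})

test_that("DCT high-pass basis has the stated size and orthogonality", {
  B <- dct_highpass_basis(400, 1.5, 128)
  expect_equal(ncol(B), 9L)             # floor(2*400*1.5/128)
  G <- crossprod(B)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-10)

  expect_equal(ncol(dct_highpass_basis(40, 1.5, 2 * 40 * 1.5 + 1)), 0L)
  expect_error(dct_highpass_basis(100, 1.5, 2), "cutoff")
})

test_that("design matrices carry one HRF-convolved column per event", {
  ev <- data.frame(onset = c(10, 30, 50), duration = 8,
                   trial_id = c("a", "b", "c"))
  d <- build_design(ev, n_scans = 60, tr_s = 1.5)
  expect_equal(length(d$trial_cols), 3L)
  ## each trial column rises to a clear positive peak (the undershoot of the
  ## double-gamma makes small negative excursions legitimate)
  expect_true(all(apply(d$matrix[, d$trial_cols], 2, max) > 0.5))
  expect_true("intercept" %in% colnames(d$matrix))

  expect_error(build_design(data.frame(onset = 10, duration = 0), 60, 1.5),
               "duration")
  expect_error(build_design(data.frame(onset = 200, duration = 8), 60, 1.5),
               "window")
  expect_error(build_design(data.frame(onset = c(10, 10), duration = 8),
                            60, 1.5), "identical onsets")
})

test_that("noiseless BOLD is reproduced by design times betas and refit", {
  st <- toy_study(P = 2, A = 4, seed = 3, n = 12L)
  sim <- simulate_bold(st, tr_s = 1.5, stim_dur_s = 8, isi_s = 6, ar1 = 0,
                       drift_amp = 0, noise_sd = 0, seed = 1)
  expect_equal(nrow(sim$events), 4L)
  d <- build_design(sim$events, sim$n_scans, sim$tr_s)
  ## rebuild one voxel's series from the design and the true betas
  vox <- which(st$grid$brain_mask)[10]
  betas_true <- vapply(1:4, function(a) st$betas[[1]][[a]]$data[vox], 0)
  rebuilt <- as.vector(d$matrix[, d$trial_cols] %*% betas_true)
  series <- apply(sim$bold[[1]], 4, function(s) s[vox])
  expect_equal(series, rebuilt, tolerance = 1e-10)

  ## noiseless refit recovers the betas to machine precision
  bs <- fit_beta_series(sim$bold[[1]], d, st$grid)
  est <- vapply(1:4, function(a) bs$betas[[a]]$data[vox], 0)
  expect_equal(est, betas_true, tolerance = 1e-8)
})

test_that("beta estimates match a normal-equations oracle on noisy data", {
  set.seed(21)
  n_scans <- 80
  ev <- data.frame(onset = seq(6, 96, by = 13), duration = 6)
  d <- build_design(ev, n_scans, 1.5)
  X <- d$matrix
  grid <- volume_grid(c(5, 5, 2), 3)
  nvox <- prod(grid$shape)
  B <- matrix(rnorm(nvox * length(d$trial_cols)), nvox)
  Y <- B %*% t(X[, d$trial_cols]) + matrix(rnorm(nvox * n_scans), nvox)
  data4d <- array(t(Y), dim = c(n_scans, grid$shape))
  data4d <- aperm(data4d, c(2, 3, 4, 1))
  bs <- fit_beta_series(data4d, d, grid)
  ## oracle: explicit (X'X)^-1 X'y per voxel
  XtXinv <- solve(crossprod(X))
  for (v in sample(nvox, 50)) {
    y <- Y[v, ]
    beta_o <- (XtXinv %*% crossprod(X, y))[d$trial_cols]
    est <- vapply(seq_along(d$trial_cols),
                  function(a) bs$betas[[a]]$data[v], 0)
    expect_equal(est, as.vector(beta_o), tolerance = 1e-8)
  }
})

test_that("rank-deficient designs are reported with offending columns", {
  ev <- data.frame(onset = c(10, 30), duration = 8)
  d <- build_design(ev, 60, 1.5)
  d$matrix <- cbind(d$matrix, dup = d$matrix[, 1])
  data4d <- array(rnorm(8 * 60), dim = c(2, 2, 2, 60))
  expect_error(fit_beta_series(data4d, d, volume_grid(c(2, 2, 2), 3)),
               "rank deficient")
})

test_that("betas are invariant to nuisance-span shifts and unbiased", {
  ev <- data.frame(onset = c(10, 30, 50), duration = 8)
  nuis <- matrix(rnorm(60), 60, 1)
  d <- build_design(ev, 60, 1.5, nuisance = nuis)
  grid <- volume_grid(c(2, 2, 1), 3)
  X <- d$matrix
  set.seed(4)
  Y <- matrix(rnorm(4 * 60), 4, 60)
  mk4d <- function(Y) aperm(array(t(Y), c(60, 2, 2, 1)), c(2, 3, 4, 1))
  b1 <- fit_beta_series(mk4d(Y), d, grid)
  shift <- outer(rep(1, 4), 3 * nuis[, 1] - 2)   # nuisance + intercept span
  b2 <- fit_beta_series(mk4d(Y + shift), d, grid)
  for (a in 1:3) expect_equal(b1$betas[[a]]$data, b2$betas[[a]]$data,
                              tolerance = 1e-8)

  ## unbiasedness: mean beta error over 200 noisy replicates is small
  true_b <- c(1, -0.5, 0.8)
  sig <- as.vector(X[, 1:3] %*% true_b)
  set.seed(9)
  est <- replicate(200, {
    y <- sig + rnorm(60)
    qr.coef(qr(X), y)[1:3]
  })
  bias <- abs(rowMeans(est) - true_b)
  expect_true(all(bias < 0.05 * abs(true_b)))
})

test_that("simulated BOLD at high SNR is recovered voxelwise by the GLM", {
  st <- toy_study(P = 2, A = 6, seed = 8, n = 12L)
  sim <- simulate_bold(st, tr_s = 1.5, stim_dur_s = 8, isi_s = 6,
                       ar1 = 0.2, drift_amp = 0.5, noise_sd = 0.05, seed = 2)
  d <- build_design(sim$events, sim$n_scans, sim$tr_s)
  bs <- fit_beta_series(sim$bold[[1]], d, st$grid)
  mask <- which(st$grid$brain_mask)
  cors <- vapply(sample(mask, 40), function(v) {
    true_b <- vapply(1:6, function(a) st$betas[[1]][[a]]$data[v], 0)
    est <- vapply(1:6, function(a) bs$betas[[a]]$data[v], 0)
    cor(true_b, est)
  }, 0)
  expect_true(all(cors > 0.95))
})
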