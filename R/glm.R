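#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (peak delay 6 s, undershoot delay 16 s,
#' dispersions 1 s, peak:undershoot ratio 6), sampled at `t = 0, tr_s,
#' 2*tr_s, ...` up to `length_s`, and scaled so the peak equals 1. The peak
#' of the continuous function sits at 5 s.
#'
#' @param tr_s sampling interval in seconds (> 0).
#' @param length_s kernel length in seconds (>= 16).
#' @return Numeric vector of `floor(length_s / tr_s) + 1` samples.
#' @export
canonical_hrf <- function(tr_s, length_s = 32) {
  stopifnot(tr_s > 0, length_s >= 16)
  t <- seq(0, length_s, by = tr_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  ## normalise against the continuous peak so scaling is sampling-invariant
  tdense <- seq(0, length_s, by = 0.001)
  hd <- stats::dgamma(tdense, shape = 6, rate = 1) -
    stats::dgamma(tdense, shape = 16, rate = 1) / 6
  h / max(hd)
}

#' Discrete-cosine high-pass basis
#'
#' DCT columns whose period exceeds `cutoff_s`, i.e.
#' `K = floor(2 * n_scans * tr_s / cutoff_s)` columns (the constant term is
#' excluded; an intercept is added separately by [build_design()]). Columns
#' are mutually orthogonal.
#'
#' @param n_scans number of scans (>= 4).
#' @param tr_s repetition time in seconds.
#' @param cutoff_s high-pass cutoff period in seconds (default 128).
#' @return Matrix `n_scans x K` (possibly 0 columns).
#' @export
dct_highpass_basis <- function(n_scans, tr_s, cutoff_s = 128) {
  stopifnot(n_scans >= 4)
  if (cutoff_s < 2 * tr_s) stop("cutoff shorter than 2 * tr_s")
  K <- floor(2 * n_scans * tr_s / cutoff_s)
  t <- seq_len(n_scans) - 1
  B <- matrix(0, n_scans, max(K, 0))
  for (k in seq_len(K)) {
    B[, k] <- cos(pi * k * (2 * t + 1) / (2 * n_scans))
  }
  if (K > 0) colnames(B) <- paste0("dct_", seq_len(K))
  B
}

#' Build a trial-wise first-level design matrix
#'
#' One regressor per event: a boxcar at micro-time resolution (16 bins per
#' TR) convolved with the canonical HRF and sampled at the first micro-time
#' bin of each scan. Discrete-cosine high-pass columns (128 s cutoff),
#' optional nuisance columns and an intercept are appended.
#'
#' @param events data.frame with columns `onset`, `duration` (seconds) and
#'   optional `trial_id`.
#' @param n_scans number of scans.
#' @param tr_s repetition time in seconds.
#' @param nuisance optional numeric matrix of `n_scans` rows (e.g. motion
#'   parameters).
#' @param hp_cutoff_s high-pass cutoff (default 128 s); `NULL` disables.
#' @return A `design_matrix`: list with `matrix`, `trial_cols`, `tr_s`,
#'   `trial_ids`.
#' @export
build_design <- function(events, n_scans, tr_s, nuisance = NULL,
                         hp_cutoff_s = 128) {
  stopifnot(is.data.frame(events), all(c("onset", "duration") %in%
                                         names(events)))
  if (any(events$duration <= 0)) stop("zero- or negative-duration event")
  total_s <- n_scans * tr_s
  if (any(events$onset < 0) || any(events$onset + events$duration > total_s)) {
    stop("events fall outside the scan window")
  }
  if (anyDuplicated(events$onset)) stop("events with identical onsets")
  nev <- nrow(events)
  res <- 16L                                # micro-time bins per TR
  dt <- tr_s / res
  n_micro <- n_scans * res
  hrf <- canonical_hrf(dt, 32)
  X <- matrix(0, n_scans, nev)
  samp <- (seq_len(n_scans) - 1L) * res + 1L   # first bin of each scan
  for (e in seq_len(nev)) {
    u <- numeric(n_micro)
    i0 <- floor(events$onset[e] / dt) + 1L
    i1 <- min(n_micro, ceiling((events$onset[e] + events$duration[e]) / dt))
    u[i0:i1] <- 1
    conv <- stats::convolve(u, rev(hrf), type = "open")[seq_len(n_micro)]
    X[, e] <- conv[samp]
  }
  ids <- if ("trial_id" %in% names(events)) events$trial_id else seq_len(nev)
  colnames(X) <- paste0("trial_", ids)
  extra <- NULL
  if (!is.null(hp_cutoff_s)) {
    B <- dct_highpass_basis(n_scans, tr_s, hp_cutoff_s)
    if (ncol(B) > 0) extra <- cbind(extra, B)
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_scans)
    colnames(nuisance) <- paste0("nuisance_", seq_len(ncol(nuisance)))
    extra <- cbind(extra, nuisance)
  }
  M <- cbind(X, extra, intercept = 1)
  structure(list(matrix = M, trial_cols = seq_len(nev), tr_s = tr_s,
                 trial_ids = ids),
            class = "design_matrix")
}

#' Fit a beta series by per-voxel ordinary least squares
#'
#' Ordinary least squares of every voxel's time series on the full design;
#' only the trial coefficients are kept, one beta volume per trial. The
#' design must be full column rank; rank deficiency is reported with the
#' offending columns.
#'
#' @param data 4D array (x, y, z, scans).
#' @param design a `design_matrix` from [build_design()].
#' @param grid a [volume_grid()] matching the spatial dimensions.
#' @return A `beta_series`: list with `betas` (list of [volume()], one per
#'   trial), `trial_ids`.
#' @export
fit_beta_series <- function(data, design, grid) {
  stopifnot(inherits(design, "design_matrix"), length(dim(data)) == 4L)
  X <- design$matrix
  n_scans <- nrow(X)
  if (dim(data)[4] != n_scans) stop("scan count does not match design")
  if (!identical(as.integer(dim(data)[1:3]), grid$shape)) {
    stop("spatial dimensions do not match grid")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design is rank deficient; offending columns: %s",
                 paste(bad, collapse = ", ")))
  }
  Y <- t(matrix(data, ncol = n_scans))       # scans x voxels
  coefs <- qr.coef(qrX, Y)                   # p x voxels
  trial_rows <- design$trial_cols
  betas <- lapply(trial_rows, function(r) {
    volume(array(coefs[r, ], dim = grid$shape), grid)
  })
  structure(list(betas = betas, trial_ids = design$trial_ids),
            class = "beta_series")
}
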