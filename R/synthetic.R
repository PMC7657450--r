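#' Generator parameters for a synthetic article-viewing study
#'
#' Bundles every knob of the synthetic-study generator. The defaults are the
#' package's calibrated desk-scale study conditions: P = 20 participants each
#' viewing A = 48 articles, with effect sizes tuned so that (i) the two ROI
#' mean signals share about 53% of their trial-to-trial variance, (ii)
#' pattern expression and ROI mean activity share about 4%, and (iii) the
#' within-person standardized effect of pattern expression on log shares sits
#' in the 0.10-0.15 regime while the article-level effect sits near 0.3-0.4.
#'
#' @param P number of participants (>= 2).
#' @param A number of articles (>= 4); every participant views every article
#'   exactly once.
#' @param gamma slope of latent article value on log shares.
#' @param sigma_y residual sd of log shares.
#' @param mu_y mean of log shares (6.2 puts raw shares in the tens to
#'   low-ten-thousands).
#' @param rho coupling between 0 and 1 linking latent article value and each
#'   person's perceived value.
#' @param a1 gain of the distributed pattern signal in the beta images.
#' @param a2 gain of the ROI blob signals in the beta images.
#' @param roi_share latent correlation between the two ROI signals; the
#'   observed trial-level correlation is attenuated by ROI measurement
#'   noise (0.95 latent gives ~0.73 observed, i.e. ~53% shared variance).
#' @param roi_value_gain loading of perceived value on each ROI signal.
#' @param lambda gain of perceived value on the 1-5 self-report rating.
#' @param noise_fwhm_mm smoothing kernel of the spatial noise field (mm).
#' @param noise_sd in-mask sd of the spatial noise field.
#' @param seed integer seed; equal seeds give bitwise-equal datasets.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(P = 20L, A = 48L,
                             gamma = 0.9, sigma_y = 0.9, mu_y = 6.2,
                             rho = 0.6,
                             a1 = 2.8, a2 = 1.6,
                             roi_share = 0.95, roi_value_gain = 0.25,
                             lambda = 0.5,
                             noise_fwhm_mm = 12, noise_sd = 1,
                             seed = 1L) {
  stopifnot(P >= 2, A >= 4, rho >= 0, rho <= 1,
            sigma_y >= 0, noise_sd >= 0, roi_share >= 0, roi_share < 1)
  structure(list(P = as.integer(P), A = as.integer(A), gamma = gamma,
                 sigma_y = sigma_y, mu_y = mu_y, rho = rho, a1 = a1, a2 = a2,
                 roi_share = roi_share, roi_value_gain = roi_value_gain,
                 lambda = lambda, noise_fwhm_mm = noise_fwhm_mm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "generator_params")
}

## random in-mask centers at least min_sep voxels apart, bounded retries
place_centers <- function(grid, n, min_sep_vox, max_tries = 5000L) {
  cand <- which(grid$brain_mask)
  coords <- arrayInd(cand, grid$shape)
  centers <- matrix(NA_real_, n, 3)
  placed <- 0L
  for (t in seq_len(max_tries)) {
    p <- coords[sample.int(nrow(coords), 1L), ]
    if (placed == 0L ||
        min(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                          matrix(p, placed, 3, byrow = TRUE))^2))) >= min_sep_vox) {
      placed <- placed + 1L
      centers[placed, ] <- p
      if (placed == n) return(centers)
    }
  }
  stop(sprintf("could not place %d non-overlapping clusters after %d tries",
               n, max_tries))
}

#' Generate a synthetic signed reference pattern
#'
#' Builds a distributed weight map in z-score units as a sum of spherical
#' Gaussian bumps (positive and negative peaks at random in-mask centres)
#' plus white background noise, emulating a meta-analytic association map
#' whose suprathreshold structure spans many clusters of both signs.
#'
#' @param grid a [volume_grid()].
#' @param n_pos,n_neg number of positive / negative bumps (`n_pos >= 1`).
#' @param cluster_radius_mm Gaussian sd of each bump in mm.
#' @param peak_z peak |weight| of each bump.
#' @param bg_sd sd of the white background added across the mask.
#' @param seed integer seed.
#' @return A `pattern_map`: list with `weights` (array) and `grid`.
#' @export
make_reference_pattern <- function(grid, n_pos = 18L, n_neg = 12L,
                                   cluster_radius_mm = 9, peak_z = 4,
                                   bg_sd = 1, seed = 1L) {
  stopifnot(inherits(grid, "volume_grid"), n_pos >= 1L, n_neg >= 0L)
  set.seed(seed)
  n <- n_pos + n_neg
  s_vox <- cluster_radius_mm / grid$voxel_size_mm
  centers <- place_centers(grid, n, min_sep_vox = 2.5 * s_vox)
  signs <- c(rep(1, n_pos), rep(-1, n_neg))
  w <- array(0, dim = grid$shape)
  ii <- slice.index(w, 1); jj <- slice.index(w, 2); kk <- slice.index(w, 3)
  for (b in seq_len(n)) {
    d2 <- (ii - centers[b, 1])^2 + (jj - centers[b, 2])^2 +
      (kk - centers[b, 3])^2
    w <- w + signs[b] * peak_z * exp(-d2 / (2 * s_vox^2))
  }
  if (bg_sd > 0) w <- w + array(stats::rnorm(length(w), 0, bg_sd), dim(w))
  w[!grid$brain_mask] <- 0
  structure(list(weights = w, grid = grid,
                 centers = centers, center_signs = signs),
            class = "pattern_map")
}

#' @export
print.pattern_map <- function(x, ...) {
  m <- x$weights[x$grid$brain_mask]
  cat(sprintf("<pattern_map %s, weight range [%.3g, %.3g]>\n",
              paste(x$grid$shape, collapse = "x"), min(m), max(m)))
  invisible(x)
}

#' Place reward-value ROIs on the pattern's strongest positive peaks
#'
#' Two spherical binary masks ("vs" and "vmpfc") centred on the two
#' strongest positive bumps of the reference pattern, so that the ROIs
#' overlap the pattern's suprathreshold clusters (the configuration the
#' overlap-masking sensitivity analysis removes).
#'
#' @param grid a [volume_grid()].
#' @param pattern a `pattern_map` from [make_reference_pattern()] with at
#'   least two positive bumps.
#' @param radius_mm sphere radius in mm.
#' @param seed unused placeholder kept for interface stability.
#' @return An `roi_set`: named list of logical arrays `masks` plus
#'   `combined_mask`.
#' @export
make_rois <- function(grid, pattern, radius_mm = 5, seed = NULL) {
  stopifnot(inherits(pattern, "pattern_map"))
  pos <- which(pattern$center_signs > 0)
  if (length(pos) < 2L) stop("pattern must carry at least two positive peaks")
  ## strongest two positive peaks = highest pattern value at the centre
  peak_val <- vapply(pos, function(b) {
    p <- pattern$centers[b, ]
    pattern$weights[p[1], p[2], p[3]]
  }, 0)
  sel <- pos[order(-peak_val)[1:2]]
  r_vox <- radius_mm / grid$voxel_size_mm
  sphere <- function(center) {
    a <- array(FALSE, grid$shape)
    ii <- slice.index(a, 1); jj <- slice.index(a, 2); kk <- slice.index(a, 3)
    d2 <- (ii - center[1])^2 + (jj - center[2])^2 + (kk - center[3])^2
    (d2 <= r_vox^2) & grid$brain_mask
  }
  masks <- list(vs = sphere(pattern$centers[sel[1], ]),
                vmpfc = sphere(pattern$centers[sel[2], ]))
  if (any(masks$vs & masks$vmpfc)) {
    masks$vmpfc <- masks$vmpfc & !masks$vs   # keep masks disjoint
  }
  if (sum(masks$vs) < 8L || sum(masks$vmpfc) < 8L) {
    stop("an ROI has fewer than 8 voxels; increase radius or grid size")
  }
  structure(list(masks = masks,
                 combined_mask = masks$vs | masks$vmpfc, grid = grid),
            class = "roi_set")
}

#' Simulate the article-level outcome table
#'
#' Each article gets a latent value `v_a ~ N(0,1)`; population log shares
#' are `mu_y + gamma * v_a + N(0, sigma_y^2)` and raw shares are the
#' exponentiated counts rounded to at least 1.
#'
#' @param A number of articles (>= 4).
#' @param gamma slope of latent value on log shares.
#' @param sigma_y residual sd of log shares.
#' @param mu_y mean log shares.
#' @param seed integer seed.
#' @return A data.frame with `article_id`, `v_a`, `shares`, `log_shares`.
#' @export
simulate_articles <- function(A, gamma = 0.9, sigma_y = 0.9, mu_y = 6.2,
                              seed = 1L) {
  stopifnot(A >= 4)
  set.seed(seed)
  v_a <- stats::rnorm(A)
  log_sh <- mu_y + gamma * v_a + stats::rnorm(A, 0, sigma_y)
  shares <- pmax(1, round(exp(log_sh)))
  data.frame(article_id = seq_len(A), v_a = v_a, shares = shares,
             log_shares = log(shares))
}

## spatial noise field: white noise, smoothed, then rescaled to the target
## in-mask sd so `noise_sd` keeps its meaning after smoothing
noise_field <- function(grid, fwhm_mm, sd_target) {
  if (sd_target == 0) return(array(0, grid$shape))
  f <- array(stats::rnorm(prod(grid$shape)), grid$shape)
  if (fwhm_mm > 0) f <- gaussian_smooth(f, fwhm_mm, grid)
  f <- f / stats::sd(f[grid$brain_mask]) * sd_target
  f
}

#' Simulate a full synthetic study
#'
#' Generates trial-level beta images, 1-5 self-report ratings and the link
#' to population share counts, with every latent draw recorded in
#' `ground_truth`. Per participant p and article a:
#' `v_pa = rho * v_a + sqrt(1 - rho^2) * N(0,1)` (perceived value); the two
#' ROI signals load on `v_pa` (gain `roi_value_gain`) and share a common
#' trial factor so their correlation is `roi_share`; the beta image is
#' `a1 * v_pa * What + a2 * (ROI signals painted on their masks)` plus a
#' smoothed noise field, where `What` is the unit-norm pattern over the
#' brain mask; the rating is `round(3 + lambda * v_pa + N(0,1))` clipped to
#' 1..5.
#'
#' @param params a [generator_params()].
#' @param pattern a `pattern_map`.
#' @param rois an `roi_set`.
#' @param articles a table from [simulate_articles()] with `params$A` rows.
#' @return A `study_dataset`: list with `betas` (list of P lists of A
#'   [volume()]s), `trials` (data.frame participant/trial/article_id/rating),
#'   `articles`, `grid`, `pattern`, `rois`, `ground_truth`, `params`.
#' @export
simulate_study <- function(params, pattern, rois, articles) {
  stopifnot(inherits(params, "generator_params"),
            inherits(pattern, "pattern_map"), inherits(rois, "roi_set"))
  grid <- pattern$grid
  if (!grids_compatible(grid, rois$grid)) stop("pattern/ROI grid mismatch")
  if (nrow(articles) != params$A) stop("article table does not match params$A")
  set.seed(params$seed)
  P <- params$P; A <- params$A
  mask <- grid$brain_mask

  What <- pattern$weights
  What <- What / sqrt(sum(What[mask]^2))        # unit-norm over the mask

  ## ROI signal structure: s_j = g*v_pa + sqrt(1-g^2)*(sqrt(c)*f + sqrt(1-c)*e_j)
  ## => corr(s1, s2) = g^2 + (1-g^2)*c ; solve c for the target roi_share
  g <- params$roi_value_gain
  c_fac <- max(0, min(1, (params$roi_share - g^2) / (1 - g^2)))

  v_pa <- matrix(params$rho * rep(articles$v_a, each = P) +
                   sqrt(1 - params$rho^2) * stats::rnorm(P * A), P, A)
  f_common <- matrix(stats::rnorm(P * A), P, A)
  e1 <- matrix(stats::rnorm(P * A), P, A)
  e2 <- matrix(stats::rnorm(P * A), P, A)
  s_vs <- g * v_pa + sqrt(1 - g^2) * (sqrt(c_fac) * f_common +
                                        sqrt(1 - c_fac) * e1)
  s_vmpfc <- g * v_pa + sqrt(1 - g^2) * (sqrt(c_fac) * f_common +
                                           sqrt(1 - c_fac) * e2)
  rating_noise <- matrix(stats::rnorm(P * A), P, A)
  rating <- pmin(5L, pmax(1L, as.integer(round(
    3 + params$lambda * v_pa + rating_noise))))

  vs_m <- rois$masks$vs; vm_m <- rois$masks$vmpfc
  betas <- vector("list", P)
  for (p in seq_len(P)) {
    betas[[p]] <- vector("list", A)
    for (a in seq_len(A)) {
      b <- params$a1 * v_pa[p, a] * What
      b[vs_m] <- b[vs_m] + params$a2 * s_vs[p, a]
      b[vm_m] <- b[vm_m] + params$a2 * s_vmpfc[p, a]
      b <- b + noise_field(grid, params$noise_fwhm_mm, params$noise_sd)
      betas[[p]][[a]] <- volume(b, grid)
    }
  }
  trials <- data.frame(
    participant = rep(seq_len(P), times = A),
    trial = rep(seq_len(A), each = P),
    article_id = rep(articles$article_id, each = P),
    rating = as.vector(rating)
  )
  structure(list(
    betas = betas, trials = trials, articles = articles, grid = grid,
    pattern = pattern, rois = rois, params = params,
    ground_truth = list(v_pa = v_pa, s_vs = s_vs, s_vmpfc = s_vmpfc,
                        What = What, params = unclass(params))),
    class = "study_dataset")
}

#' Simulate a full study from parameters alone
#'
#' Convenience wrapper: builds the grid, reference pattern, ROIs and article
#' table from a single seed, then calls [simulate_study()].
#'
#' @param params a [generator_params()].
#' @param grid optional [volume_grid()]; default [ellipsoid_grid()].
#' @param n_pos,n_neg bumps passed to [make_reference_pattern()].
#' @return A `study_dataset`.
#' @export
simulate_default_study <- function(params = generator_params(),
                                   grid = ellipsoid_grid(),
                                   n_pos = 18L, n_neg = 12L) {
  pattern <- make_reference_pattern(grid, n_pos = n_pos, n_neg = n_neg,
                                    seed = params$seed)
  rois <- make_rois(grid, pattern)
  articles <- simulate_articles(params$A, params$gamma, params$sigma_y,
                                params$mu_y, seed = params$seed + 1L)
  simulate_study(params, pattern, rois, articles)
}

#' Simulate BOLD time series from a study's beta images
#'
#' Deeper simulation path used to exercise the first-level GLM: each
#' participant's voxel time series is the trial design (boxcar convolved
#' with the canonical HRF) weighted by that participant's beta images, plus
#' a slow cosine drift and AR(1) noise.
#'
#' @param dataset a `study_dataset`.
#' @param tr_s repetition time in seconds (> 0).
#' @param stim_dur_s stimulus duration per trial in seconds (> 0).
#' @param isi_s inter-stimulus interval in seconds.
#' @param ar1 AR(1) coefficient of the noise, in [0, 1).
#' @param drift_amp amplitude of the slow cosine drift.
#' @param noise_sd innovation sd of the AR(1) noise.
#' @param seed integer seed.
#' @param participants which participants to simulate (default: all).
#' @return List with `bold` (list of 4D arrays x,y,z,t per participant),
#'   `events` (data.frame onset/duration/trial_id), `tr_s`, `n_scans`.
#' @export
simulate_bold <- function(dataset, tr_s = 1.5, stim_dur_s = 8, isi_s = 4,
                          ar1 = 0.3, drift_amp = 0, noise_sd = 1, seed = 1L,
                          participants = NULL) {
  stopifnot(inherits(dataset, "study_dataset"), tr_s > 0, stim_dur_s > 0,
            ar1 >= 0, ar1 < 1)
  set.seed(seed)
  A <- dataset$params$A
  lead_s <- 10
  onsets <- lead_s + (seq_len(A) - 1) * (stim_dur_s + isi_s)
  total_s <- max(onsets) + stim_dur_s + 20
  n_scans <- ceiling(total_s / tr_s)
  events <- data.frame(onset = onsets, duration = stim_dur_s,
                       trial_id = seq_len(A))
  design <- build_design(events, n_scans, tr_s)
  Xtr <- design$matrix[, design$trial_cols, drop = FALSE]
  if (is.null(participants)) participants <- seq_len(dataset$params$P)
  grid <- dataset$grid
  nvox <- prod(grid$shape)
  t_s <- (seq_len(n_scans) - 1) * tr_s
  drift <- drift_amp * cos(pi * t_s / total_s)
  bold <- lapply(participants, function(p) {
    B <- vapply(seq_len(A), function(a) as.vector(dataset$betas[[p]][[a]]$data),
                numeric(nvox))                      # nvox x A
    Y <- tcrossprod(B, Xtr)                         # nvox x n_scans
    if (noise_sd > 0) {
      eps <- matrix(stats::rnorm(nvox * n_scans, 0, noise_sd), nvox, n_scans)
      if (ar1 > 0) {
        for (tt in 2:n_scans) eps[, tt] <- ar1 * eps[, tt - 1] + eps[, tt]
      }
      Y <- Y + eps
    }
    Y <- Y + matrix(drift, nvox, n_scans, byrow = TRUE)
    array(Y, dim = c(grid$shape, n_scans))
  })
  names(bold) <- as.character(participants)
  list(bold = bold, events = events, tr_s = tr_s, n_scans = n_scans)
}

#' Write a study dataset to disk
#'
#' Emits per-trial 3D NIfTI beta images (`sub-XX_trial-YY_beta.nii.gz`),
#' `articles.csv`, `trials.csv` and `ground_truth.json` under `dir`.
#'
#' @param dataset a `study_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in seq_len(dataset$params$P)) {
    for (a in seq_len(dataset$params$A)) {
      write_volume(dataset$betas[[p]][[a]],
                   file.path(dir, sprintf("sub-%02d_trial-%02d_beta.nii.gz",
                                          p, a)))
    }
  }
  utils::write.csv(dataset$articles, file.path(dir, "articles.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  gt <- dataset$ground_truth
  gt$v_pa <- as.vector(gt$v_pa); gt$s_vs <- as.vector(gt$s_vs)
  gt$s_vmpfc <- as.vector(gt$s_vmpfc); gt$What <- NULL
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
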