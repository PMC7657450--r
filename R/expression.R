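#' Pattern expression of a trial image
#'
#' Pearson correlation between the vectorized trial image and the vectorized
#' weight map over the analysis mask — a per-trial scalar similarity to the
#' reference pattern. Degenerate trials (zero variance of either vector
#' inside the mask) yield `NA` with a warning rather than a silent zero.
#'
#' @param image a [volume()] or numeric array.
#' @param pattern a `pattern_map`, [volume()] or numeric array of weights.
#' @param analysis_mask logical array of in-analysis voxels (>= 10 voxels).
#'   Default: the brain mask intersected with finite pattern values.
#' @return A single correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
pattern_expression <- function(image, pattern, analysis_mask = NULL) {
  grid <- NULL
  if (inherits(image, "volume")) { grid <- image$grid; image <- image$data }
  w <- pattern
  if (inherits(w, "pattern_map")) { grid <- grid %||% w$grid; w <- w$weights }
  if (inherits(w, "volume")) { grid <- grid %||% w$grid; w <- w$data }
  if (is.null(analysis_mask)) {
    if (is.null(grid)) stop("need an analysis_mask or gridded inputs")
    analysis_mask <- grid$brain_mask & is.finite(w)
  }
  stopifnot(identical(dim(image), dim(w)),
            identical(dim(image), dim(analysis_mask)))
  if (sum(analysis_mask) < 10L) stop("analysis mask has fewer than 10 voxels")
  x <- image[analysis_mask]; y <- w[analysis_mask]
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values inside the analysis mask")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance inside the analysis mask; expression flagged NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean activity within an ROI
#'
#' @param image a [volume()] or numeric array.
#' @param roi nonempty logical array.
#' @return Arithmetic mean of the image over the ROI voxels.
#' @export
roi_mean <- function(image, roi) {
  if (inherits(image, "volume")) image <- image$data
  stopifnot(identical(dim(image), dim(roi)))
  if (!any(roi)) stop("empty ROI")
  mean(image[roi])
}

#' Assemble the per-trial modelling table
#'
#' One row per (participant, trial): pattern expression, combined and
#' per-ROI mean activity, self-report rating and the article's log share
#' count. Trials whose expression is degenerate are kept with `NA` and
#' flagged; models drop them with a logged count.
#'
#' @param dataset a `study_dataset` (or a list with `betas`, `trials`,
#'   `articles`, `grid` in the same layout for externally supplied data).
#' @param pattern `pattern_map` to score against (default: the dataset's).
#' @param rois `roi_set` (default: the dataset's).
#' @param analysis_mask optional logical array; default brain mask
#'   intersected with finite pattern weights.
#' @param study study label stored in the `study` column.
#' @return A `feature_table` data.frame with columns `participant`, `trial`,
#'   `article_id`, `expression_r`, `roi_mean`, `roi_vs`, `roi_vmpfc`,
#'   `rating`, `log_shares`, `study`, `flagged`.
#' @export
build_feature_table <- function(dataset, pattern = dataset$pattern,
                                rois = dataset$rois, analysis_mask = NULL,
                                study = "study1") {
  grid <- dataset$grid
  if (is.null(analysis_mask)) {
    analysis_mask <- grid$brain_mask & is.finite(pattern$weights)
  }
  tr <- dataset$trials
  art <- dataset$articles
  if (!all(tr$article_id %in% art$article_id)) {
    stop("trial article_id missing from the article table")
  }
  n <- nrow(tr)
  expr <- roi_c <- roi_v <- roi_m <- numeric(n)
  for (i in seq_len(n)) {
    p <- tr$participant[i]; a <- tr$trial[i]
    b <- dataset$betas[[p]][[a]]
    if (is.null(b)) {
      stop(sprintf("missing beta volume for participant %d trial %d", p, a))
    }
    expr[i] <- suppressWarnings(
      pattern_expression(b, pattern, analysis_mask))
    roi_c[i] <- roi_mean(b, rois$combined_mask)
    roi_v[i] <- roi_mean(b, rois$masks$vs)
    roi_m[i] <- roi_mean(b, rois$masks$vmpfc)
  }
  flagged <- !is.finite(expr)
  if (any(flagged)) {
    message(sprintf("%d trial(s) flagged with degenerate expression",
                    sum(flagged)))
  }
  out <- data.frame(
    participant = tr$participant, trial = tr$trial,
    article_id = tr$article_id, expression_r = expr,
    roi_mean = roi_c, roi_vs = roi_v, roi_vmpfc = roi_m,
    rating = tr$rating,
    log_shares = art$log_shares[match(tr$article_id, art$article_id)],
    study = study, flagged = flagged
  )
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Remove ROI-overlapping structure from a pattern
#'
#' Zeroes the weights of (i) every ROI voxel and (ii) every voxel belonging
#' to any suprathreshold cluster that intersects an ROI — the whole cluster
#' is removed, not just its ROI-overlapping part. This is the conservative
#' overlap-masking transform of the sensitivity analysis: what remains of
#' the pattern owes nothing to activity in or around the ROIs.
#'
#' @param pattern a `pattern_map`.
#' @param clusters a `cluster_set` derived from this pattern (e.g. via
#'   [threshold_pattern()]).
#' @param rois an `roi_set`.
#' @return A `pattern_map` with the overlapping structure zeroed.
#' @export
mask_out_overlap <- function(pattern, clusters, rois) {
  stopifnot(inherits(pattern, "pattern_map"),
            inherits(clusters, "cluster_set"), inherits(rois, "roi_set"))
  if (!identical(dim(clusters$labels), pattern$grid$shape)) {
    stop("cluster labels do not match the pattern grid")
  }
  w <- pattern$weights
  roi_mask <- rois$combined_mask
  hit <- setdiff(unique(clusters$labels[roi_mask]), 0L)
  drop <- roi_mask | (clusters$labels %in% hit &
                        array(TRUE, dim(w)))        # whole clusters
  drop <- array(drop, dim(w))
  w[drop] <- 0
  if (sum(w != 0 & pattern$grid$brain_mask) < 10L) {
    stop("masking leaves fewer than 10 nonzero pattern voxels")
  }
  out <- pattern
  out$weights <- w
  out$masked_voxels <- sum(drop & pattern$grid$brain_mask)
  out
}

#' Smoothing-kernel sensitivity sweep
#'
#' Recomputes pattern expression after smoothing the reference pattern with
#' each kernel (the trial data are left untouched), returning one feature
#' table per kernel. Kernel 0 reproduces the baseline table exactly.
#'
#' @param pattern a `pattern_map`.
#' @param kernels_mm nonnegative kernel widths (FWHM, mm).
#' @param dataset a `study_dataset`.
#' @param rois an `roi_set`.
#' @param analysis_mask optional logical array.
#' @return Named list of `feature_table`s, one per kernel.
#' @export
smoothing_sweep <- function(pattern, kernels_mm = seq(0, 40, by = 4),
                            dataset, rois = dataset$rois,
                            analysis_mask = NULL) {
  stopifnot(all(kernels_mm >= 0))
  if (is.null(analysis_mask)) {
    analysis_mask <- pattern$grid$brain_mask & is.finite(pattern$weights)
  }
  out <- lapply(kernels_mm, function(k) {
    pk <- pattern
    if (k > 0) {
      pk$weights <- gaussian_smooth(pattern$weights, k, pattern$grid)
    }
    build_feature_table(dataset, pattern = pk, rois = rois,
                        analysis_mask = analysis_mask)
  })
  names(out) <- paste0("fwhm_", kernels_mm)
  out
}

#' Write a feature table to CSV
#'
#' @param features a `feature_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
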