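#' Monte-Carlo null distribution of the maximum cluster extent
#'
#' AlphaSim-style simulation: on each iteration an iid N(0,1) field is drawn
#' on the grid, smoothed with the stated kernel, re-standardized to zero
#' mean and unit variance within the brain mask (smoothing shrinks the
#' marginal variance, and the voxelwise threshold must keep its nominal tail
#' probability), thresholded at `z_thresh` (both signs when `two_sided`),
#' and the largest suprathreshold cluster extent is recorded.
#'
#' @param grid a [volume_grid()].
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param z_thresh voxelwise threshold (> 0).
#' @param n_iter number of iterations (>= 1; >= 100 for inference use).
#' @param connectivity 6, 18 or 26.
#' @param two_sided if `TRUE` (default) the recorded extent is the maximum
#'   over clusters of both signs.
#' @param seed integer seed.
#' @return A `null_max_cluster_dist`: list with `max_sizes` (length
#'   `n_iter`), plus the settings.
#' @export
simulate_max_cluster_null <- function(grid, fwhm_mm, z_thresh, n_iter,
                                      connectivity = 26L, two_sided = TRUE,
                                      seed = 1L) {
  stopifnot(inherits(grid, "volume_grid"), n_iter >= 1)
  if (z_thresh <= 0) stop("z_thresh must be positive")
  set.seed(seed)
  mask <- grid$brain_mask
  max_sizes <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    f <- array(stats::rnorm(prod(grid$shape)), grid$shape)
    if (fwhm_mm > 0) f <- gaussian_smooth(f, fwhm_mm, grid)
    v <- f[mask]
    f[mask] <- (v - mean(v)) / stats::sd(v)
    mx <- 0L
    pos <- (f > z_thresh) & mask
    if (any(pos)) {
      mx <- max(mx, label_clusters(pos, connectivity)$sizes[1])
    }
    if (two_sided) {
      neg <- (f < -z_thresh) & mask
      if (any(neg)) {
        mx <- max(mx, label_clusters(neg, connectivity)$sizes[1])
      }
    }
    max_sizes[it] <- mx
  }
  structure(list(z_thresh = z_thresh, fwhm_mm = fwhm_mm,
                 connectivity = as.integer(connectivity), n_iter = n_iter,
                 two_sided = two_sided, max_sizes = max_sizes, seed = seed,
                 n_mask = sum(mask)),
            class = "null_max_cluster_dist")
}

#' Cluster-extent threshold controlling family-wise error
#'
#' The smallest extent `k` such that the fraction of null iterations whose
#' largest cluster reaches `k` voxels is strictly below `alpha` (the
#' corrected family-wise error rate is < alpha under repeated sampling).
#'
#' @param null a `null_max_cluster_dist`.
#' @param alpha target family-wise error rate in (0, 1).
#' @return An `extent_threshold`: list with `z_thresh`, `k_extent`, `alpha`,
#'   `achieved_fwer`.
#' @export
extent_threshold <- function(null, alpha = 0.05) {
  stopifnot(inherits(null, "null_max_cluster_dist"), alpha > 0, alpha < 1)
  ms <- null$max_sizes
  for (k in seq_len(max(ms) + 1L)) {
    fwer <- mean(ms >= k)
    if (fwer < alpha) {
      if (!is.null(null$n_mask) && k > null$n_mask / 2) {
        stop(sprintf(
          "alpha = %g effectively unattainable: required extent %d exceeds half the mask (%d voxels); null max extents range %d-%d",
          alpha, k, null$n_mask, min(ms), max(ms)))
      }
      return(structure(list(z_thresh = null$z_thresh, k_extent = k,
                            alpha = alpha, achieved_fwer = fwer),
                       class = "extent_threshold"))
    }
  }
  stop("alpha unattainable from the supplied null distribution")
}

#' Threshold a weight map into signed clusters
#'
#' Positive clusters from `weights > z_thresh`, negative clusters from
#' `weights < -z_thresh`, each labeled separately under the given
#' connectivity; clusters smaller than `k_extent` voxels are discarded. The
#' surviving clusters are relabeled jointly (descending size, ties by
#' smallest linear voxel index) with their sign recorded.
#'
#' @param pattern a `pattern_map`.
#' @param z_thresh voxel threshold on |weight| (default 2.56).
#' @param k_extent minimum cluster extent in voxels (>= 1; default 50).
#' @param connectivity 6, 18 or 26.
#' @return A `cluster_set` (possibly empty) with `sign` entries +1 / -1.
#' @export
threshold_pattern <- function(pattern, z_thresh = 2.56, k_extent = 50L,
                              connectivity = 26L) {
  stopifnot(inherits(pattern, "pattern_map"), k_extent >= 1)
  grid <- pattern$grid
  w <- pattern$weights
  pieces <- list()
  for (sgn in c(1, -1)) {
    bin <- if (sgn > 0) w > z_thresh else w < -z_thresh
    bin <- bin & grid$brain_mask
    if (!any(bin)) next
    cs <- label_clusters(bin, connectivity)
    keep <- which(cs$sizes >= k_extent)
    for (cid in keep) {
      vox <- which(cs$labels == cid)
      pieces[[length(pieces) + 1L]] <-
        list(vox = vox, size = cs$sizes[cid], sign = sgn,
             first = min(vox))
    }
  }
  labels <- array(0L, dim = grid$shape)
  if (length(pieces) == 0L) {
    return(structure(list(labels = labels, sizes = integer(0),
                          sign = numeric(0),
                          connectivity = as.integer(connectivity)),
                     class = "cluster_set"))
  }
  sizes <- vapply(pieces, `[[`, 0L, "size")
  firsts <- vapply(pieces, `[[`, 0L, "first")
  ord <- order(-sizes, firsts)
  for (i in seq_along(ord)) {
    labels[pieces[[ord[i]]]$vox] <- i
  }
  structure(list(labels = labels, sizes = sizes[ord],
                 sign = vapply(pieces, `[[`, 0, "sign")[ord],
                 connectivity = as.integer(connectivity)),
            class = "cluster_set")
}
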