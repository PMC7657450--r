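#' Spatial grid shared by all volumes
#'
#' A `volume_grid` fixes the voxel lattice every image in an analysis lives
#' on: the array shape, the (isotropic) voxel edge length in millimetres, and
#' a boolean brain mask. Every [volume()] and pattern map carries a reference
#' to exactly one grid and must shape-match it; all statistics ignore voxels
#' outside `brain_mask`.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param voxel_size_mm positive scalar, isotropic voxel edge in mm.
#' @param brain_mask logical array of dimension `shape` with at least one
#'   `TRUE` voxel. Default: all voxels included.
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(10, 10, 10), 3)
#' sum(g$brain_mask)
#' @export
volume_grid <- function(shape, voxel_size_mm, brain_mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be three integers >= 1")
  }
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      voxel_size_mm <= 0) {
    stop("`voxel_size_mm` must be a positive scalar")
  }
  if (is.null(brain_mask)) {
    brain_mask <- array(TRUE, dim = shape)
  }
  brain_mask <- array(as.logical(brain_mask), dim = dim(brain_mask))
  if (!identical(dim(brain_mask), shape)) {
    stop("`brain_mask` dimensions do not match `shape`")
  }
  if (!any(brain_mask)) stop("`brain_mask` must contain at least one voxel")
  structure(
    list(shape = shape, voxel_size_mm = as.numeric(voxel_size_mm),
         brain_mask = brain_mask),
    class = "volume_grid"
  )
}

#' Ellipsoidal brain-like mask on a grid shape
#'
#' Convenience constructor for a grid whose mask is the inscribed ellipsoid
#' (a crude whole-brain mask for simulations).
#'
#' @param shape integer vector of length 3.
#' @param voxel_size_mm voxel edge in mm.
#' @return A `volume_grid` with an ellipsoidal mask.
#' @export
ellipsoid_grid <- function(shape = c(40L, 40L, 40L), voxel_size_mm = 3) {
  shape <- as.integer(shape)
  cen <- (shape + 1) / 2
  semi <- shape / 2 - 0.5
  ii <- slice.index(array(0, shape), 1)
  jj <- slice.index(array(0, shape), 2)
  kk <- slice.index(array(0, shape), 3)
  d2 <- ((ii - cen[1]) / semi[1])^2 + ((jj - cen[2]) / semi[2])^2 +
    ((kk - cen[3]) / semi[3])^2
  volume_grid(shape, voxel_size_mm, d2 <= 1)
}

#' Scalar volume on a grid
#'
#' @param data numeric array matching `grid$shape`.
#' @param grid a [volume_grid()].
#' @return An object of class `volume` (list with `data`, `grid`).
#' @export
volume <- function(data, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  data <- array(as.numeric(data), dim = dim(data))
  if (!identical(dim(data), grid$shape)) {
    stop("volume data dimensions do not match grid shape")
  }
  if (any(!is.finite(data[grid$brain_mask]))) {
    stop("volume contains non-finite values inside the brain mask")
  }
  structure(list(data = data, grid = grid), class = "volume")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s at %g mm, %d/%d voxels in mask>\n",
              paste(x$shape, collapse = "x"), x$voxel_size_mm,
              sum(x$brain_mask), prod(x$shape)))
  invisible(x)
}

#' @export
print.volume <- function(x, ...) {
  m <- x$data[x$grid$brain_mask]
  cat(sprintf("<volume %s, in-mask range [%.4g, %.4g]>\n",
              paste(x$grid$shape, collapse = "x"), min(m), max(m)))
  invisible(x)
}

grids_compatible <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) &&
    abs(a$voxel_size_mm - b$voxel_size_mm) < tol
}

#' Read a 3D NIfTI-1 volume
#'
#' Data are stored float32 on disk and promoted to double in memory. If a
#' grid is supplied, the file's geometry (dimensions and voxel size) must
#' match it; the returned volume is attached to that grid.
#'
#' @param path path to a 3D NIfTI-1 file.
#' @param grid optional [volume_grid()] the image must conform to.
#' @return A [volume()].
#' @export
read_volume <- function(path, grid = NULL) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L) {
    stop(sprintf("expected a 3D image, got %dD: %s", length(dm), path))
  }
  vox <- RNifti::pixdim(img)[1:3]
  if (max(vox) - min(vox) > 1e-4) {
    stop("anisotropic voxels are not supported")
  }
  if (is.null(grid)) {
    grid <- volume_grid(dm, vox[1])
  } else {
    if (!identical(as.integer(dm), grid$shape)) {
      stop(sprintf("image dimensions %s do not match grid %s",
                   paste(dm, collapse = "x"),
                   paste(grid$shape, collapse = "x")))
    }
    if (abs(vox[1] - grid$voxel_size_mm) > 1e-4) {
      stop(sprintf("image voxel size %g mm does not match grid %g mm",
                   vox[1], grid$voxel_size_mm))
    }
  }
  volume(array(as.numeric(img), dim = dm), grid)
}

#' Write a volume as NIfTI-1 (float32)
#'
#' @param v a [volume()].
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  s <- v$grid$voxel_size_mm
  hdr <- RNifti::niftiHeader(list(pixdim = c(-1, s, s, s, 1, 0, 0, 0)))
  img <- RNifti::asNifti(v$data, reference = hdr, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Nonzero voxels become `TRUE`.
#'
#' @inheritParams read_volume
#' @return A logical array.
#' @export
read_mask <- function(path, grid = NULL) {
  v <- read_volume(path, grid)
  v$data != 0
}

fwhm_to_sigma_vox <- function(fwhm_mm, voxel_size_mm) {
  fwhm_mm / (2 * sqrt(2 * log(2)) * voxel_size_mm)
}

## 1-D convolution matrix for a Gaussian kernel, rows renormalised so that
## constants are preserved at the edges (each output is a weighted average).
gauss_conv_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(6 * sigma_vox))   # 6 sigma: tails < 2e-8
  off <- (-r):r
  k <- exp(-off^2 / (2 * sigma_vox^2))
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1L & j <= n
    w <- k[ok]
    C[i, j[ok]] <- w / sum(w)
  }
  C
}

smooth_axis <- function(a, C, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- C %*% matrix(ap, nrow = dp[1])
  ap <- array(m, dim = dp)
  aperm(ap, order(perm))
}

#' Gaussian smoothing of a volume
#'
#' Separable 3D Gaussian convolution with kernel standard deviation
#' `sigma_vox = fwhm_mm / (2 * sqrt(2 * log(2)) * voxel_size_mm)`. The kernel
#' is renormalised where it overhangs the volume edge, so constant volumes
#' are returned unchanged. `fwhm_mm = 0` is the identity.
#'
#' @param v a [volume()] (or bare numeric array with `grid` supplied).
#' @param fwhm_mm nonnegative full width at half maximum in mm.
#' @param grid grid to use when `v` is a bare array.
#' @return A smoothed [volume()] (or array if the input was an array).
#' @export
gaussian_smooth <- function(v, fwhm_mm, grid = NULL) {
  if (inherits(v, "volume")) {
    out <- gaussian_smooth(v$data, fwhm_mm, v$grid)
    return(volume(out, v$grid))
  }
  stopifnot(inherits(grid, "volume_grid"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0) {
    stop("`fwhm_mm` must be a nonnegative scalar")
  }
  if (fwhm_mm == 0) return(v)
  sigma <- fwhm_to_sigma_vox(fwhm_mm, grid$voxel_size_mm)
  a <- v
  for (ax in 1:3) {
    a <- smooth_axis(a, gauss_conv_matrix(dim(a)[ax], sigma), ax)
  }
  a
}

connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("connectivity must be one of 6, 18, 26")
  }
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & rowSums(off != 0) <= 2,
                 "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

#' Label connected components of a binary volume
#'
#' Maximal connected components of `TRUE` voxels under 6-, 18- or
#' 26-neighbourhood connectivity (26 is the AFNI-style "touching anywhere"
#' rule used for cluster-extent inference). Labels are assigned
#' deterministically: descending size, ties broken by the smallest linear
#' voxel index in the cluster.
#'
#' @param binary logical array (or `volume` whose data are interpreted as
#'   `!= 0`).
#' @param connectivity 6, 18 or 26.
#' @param grid optional [volume_grid()]; voxels outside `brain_mask` are
#'   treated as background.
#' @return An object of class `cluster_set`: list with integer array
#'   `labels` (0 = background), integer vector `sizes`, numeric `sign`
#'   (filled by [threshold_pattern()], `NA` here), and `connectivity`.
#' @export
label_clusters <- function(binary, connectivity = 26L, grid = NULL) {
  if (inherits(binary, "volume")) {
    grid <- binary$grid
    binary <- binary$data != 0
  }
  connectivity <- as.integer(connectivity)
  off <- connectivity_offsets(connectivity)
  dm <- dim(binary)
  stopifnot(length(dm) == 3L)
  if (!is.null(grid)) {
    stopifnot(identical(grid$shape, dm))
    binary <- binary & grid$brain_mask
  }
  labels <- array(0L, dim = dm)
  idx <- which(binary)
  if (length(idx) == 0L) {
    return(structure(list(labels = labels, sizes = integer(0),
                          sign = numeric(0), connectivity = connectivity),
                     class = "cluster_set"))
  }
  coords <- arrayInd(idx, dm)
  ## map from linear index to row for O(1) membership tests
  inset <- array(0L, dim = dm)
  inset[idx] <- seq_along(idx)
  comp <- integer(length(idx))          # component id per foreground voxel
  ncomp <- 0L
  n1 <- dm[1]; n12 <- dm[1] * dm[2]
  for (s in seq_along(idx)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    comp[s] <- ncomp
    frontier <- s
    while (length(frontier) > 0L) {
      fc <- coords[frontier, , drop = FALSE]
      ## all neighbours of the frontier, in-bounds
      nb_i <- rep(fc[, 1], each = nrow(off)) + off[, 1]
      nb_j <- rep(fc[, 2], each = nrow(off)) + off[, 2]
      nb_k <- rep(fc[, 3], each = nrow(off)) + off[, 3]
      ok <- nb_i >= 1L & nb_i <= dm[1] & nb_j >= 1L & nb_j <= dm[2] &
        nb_k >= 1L & nb_k <= dm[3]
      lin <- (nb_k[ok] - 1L) * n12 + (nb_j[ok] - 1L) * n1 + nb_i[ok]
      rows <- inset[lin]
      rows <- unique(rows[rows != 0L])
      rows <- rows[comp[rows] == 0L]
      comp[rows] <- ncomp
      frontier <- rows
    }
  }
  ## deterministic relabeling: descending size, ties by smallest linear index
  sizes <- tabulate(comp, nbins = ncomp)
  first_idx <- vapply(seq_len(ncomp), function(cid) min(idx[comp == cid]), 0)
  ord <- order(-sizes, first_idx)
  newid <- integer(ncomp)
  newid[ord] <- seq_len(ncomp)
  labels[idx] <- newid[comp]
  structure(list(labels = labels, sizes = sizes[ord],
                 sign = rep(NA_real_, ncomp), connectivity = connectivity),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set: %d clusters, sizes %s, connectivity %d>\n",
              length(x$sizes),
              paste(utils::head(x$sizes, 8), collapse = ","),
              x$connectivity))
  invisible(x)
}
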