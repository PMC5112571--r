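#' 3D scalar volume on a world-referenced grid
#'
#' Shared container for all image-space objects (T1-weighted volumes, T1
#' maps, gadolinium-concentration maps, masks, label volumes): a 3D numeric
#' array plus voxel spacing (mm) and a 4x4 voxel-to-world affine.  Voxelwise
#' arithmetic between two grids requires matching shape and affine.
#'
#' @param voxels 3D numeric (or logical) array.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param affine Optional 4x4 voxel-to-world matrix (0-based voxel indices to
#'   world mm). Default: axes scaled by `spacing` with the world origin at
#'   the grid centre (so the mid-sagittal plane of a symmetric phantom is
#'   x = 0).
#' @param units Unit label for the voxel values (e.g. `"ms"`, `"mM"`).
#'
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, spacing = c(1, 1, 1), affine = NULL,
                        units = "") {
  if (is.logical(voxels)) voxels <- array(as.numeric(voxels), dim(voxels))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L,
            length(spacing) == 3L, all(spacing > 0))
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- -spacing * (dim(voxels) - 1) / 2
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 affine = affine, units = units),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  rng <- range(x$voxels, na.rm = TRUE)
  cat(sprintf("<volume_grid> %s @ %s mm%s; range [%.4g, %.4g], %d NA\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              rng[1], rng[2], sum(is.na(x$voxels))))
  invisible(x)
}

#' @rdname volume_grid
#' @param a,b `volume_grid` objects.
#' @param tol Tolerance on affine equality.
#' @return `same_grid()` returns TRUE/FALSE.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  inherits(a, "volume_grid") && inherits(b, "volume_grid") &&
    identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("incompatible-grids: volumes do not share shape and affine")
  invisible(TRUE)
}

#' @rdname volume_grid
#' @param grid A `volume_grid`.
#' @return `voxel_volume()` returns the voxel volume in mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

# World mm -> 0-based continuous voxel coordinates (rows of `xyz`).
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  inv <- solve(grid$affine)
  t(inv %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

# 0-based voxel coordinates -> world mm.
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

# World coordinates (mm) of every voxel centre along each axis.
axis_world_coords <- function(grid) {
  d <- dim(grid$voxels)
  lapply(1:3, function(ax) {
    ijk <- matrix(0, nrow = d[ax], ncol = 3L)
    ijk[, ax] <- seq_len(d[ax]) - 1
    voxel_to_world(grid, ijk)[, ax]
  })
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over RNifti preserving the voxel-to-world affine.
#'
#' @param grid A [volume_grid].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` a
#'   [volume_grid].
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  img <- RNifti::asNifti(grid$voxels)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  volume_grid(array(as.numeric(img), dim(img)[1:3]),
              spacing = RNifti::pixdim(img)[1:3],
              affine = matrix(as.numeric(aff), 4L, 4L))
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Used for mask-gradient surface normals and optional enhancement-map
#' denoising.  Truncated at 3 sigma; borders use renormalized (clamped)
#' kernels.
#'
#' @param x 3D numeric array.
#' @param sigma Gaussian sigma in voxels (scalar or length-3). `0` returns
#'   `x` unchanged.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth3 <- function(x, sigma = 1) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  sigma <- rep_len(sigma, 3L)
  if (all(sigma <= 0)) return(x)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    x <- convolve_axis(x, k, ax)
  }
  x
}

# 1D convolution along one axis with edge renormalization.
convolve_axis <- function(x, k, ax) {
  d <- dim(x)
  r <- (length(k) - 1L) / 2L
  out <- array(0, d)
  wt <- array(0, d)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(d[ax]) + off
    ok <- src >= 1L & src <= d[ax]
    if (!any(ok)) next
    idx_dst <- which(ok)
    idx_src <- src[ok]
    if (ax == 1L) {
      out[idx_dst, , ] <- out[idx_dst, , ] + k[j] * x[idx_src, , ]
      wt[idx_dst, , ] <- wt[idx_dst, , ] + k[j]
    } else if (ax == 2L) {
      out[, idx_dst, ] <- out[, idx_dst, ] + k[j] * x[, idx_src, ]
      wt[, idx_dst, ] <- wt[, idx_dst, ] + k[j]
    } else {
      out[, , idx_dst] <- out[, , idx_dst] + k[j] * x[, , idx_src]
      wt[, , idx_dst] <- wt[, , idx_dst] + k[j]
    }
  }
  out / wt
}
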