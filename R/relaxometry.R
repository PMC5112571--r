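#' Variable-flip-angle SPGR series
#'
#' Container for a multi-flip-angle spoiled-gradient-echo acquisition used
#' for T1 mapping: one volume per flip angle on a shared grid, with the
#' repetition time.  Defaults match a five-angle protocol (5/10/15/20/35
#' degrees, TR = 10 ms).
#'
#' @param volumes List of [volume_grid] objects, one per flip angle.
#' @param flip_angles Flip angles in degrees.
#' @param TR Repetition time in ms.
#' @return An object of class `vfa_series`.
#' @export
vfa_series <- function(volumes, flip_angles = c(5, 10, 15, 20, 35), TR = 10) {
  stopifnot(is.list(volumes), length(volumes) == length(flip_angles),
            length(unique(flip_angles)) >= 2L, TR > 0)
  for (v in volumes) stop_if_grid_mismatch(volumes[[1]], v)
  structure(list(volumes = volumes, flip_angles = as.numeric(flip_angles),
                 TR = as.numeric(TR)),
            class = "vfa_series")
}

#' SPGR steady-state signal
#'
#' Closed-form spoiled-gradient-echo signal
#' `S = M0 sin(a) (1 - E1) / (1 - E1 cos(a))` with `E1 = exp(-TR/T1)`.
#' Shared by the T1 fit (as its forward model) and the phantom generator.
#'
#' @param T1 Longitudinal relaxation time, ms (scalar or array).
#' @param flip_deg Flip angle in degrees.
#' @param TR Repetition time, ms.
#' @param M0 Equilibrium magnetization scale.
#' @return Signal with the shape of `T1`.
#' @export
spgr_signal <- function(T1, flip_deg, TR, M0 = 1) {
  a <- flip_deg * pi / 180
  E1 <- exp(-TR / T1)
  M0 * sin(a) * (1 - E1) / (1 - E1 * cos(a))
}

#' Fit a T1 map from a VFA SPGR series
#'
#' Standard linearized VFA fit, per voxel: with `y = S/sin(a)` and
#' `x = S/tan(a)`, the SPGR equation becomes `y = E1 x + M0 (1 - E1)`, so
#' an unweighted least-squares line across flip angles gives `E1` as the
#' slope and `T1 = -TR / log(E1)`.  Voxels with slope outside (0, 1), with a
#' fitted T1 outside (1, 10000) ms, or with all-zero signals are flagged
#' invalid (NA in the maps).
#'
#' @param series A [vfa_series].
#' @return List with `t1` (ms, [volume_grid]), `m0`, `r_squared`
#'   (linear-fit R^2) and `valid` (logical array).
#' @export
fit_t1 <- function(series) {
  stopifnot(inherits(series, "vfa_series"))
  ref <- series$volumes[[1]]
  d <- dim(ref$voxels)
  n_ang <- length(series$flip_angles)
  a <- series$flip_angles * pi / 180

  S <- vapply(series$volumes, function(v) as.numeric(v$voxels),
              numeric(prod(d)))                       # n_vox x n_ang
  if (all(!is.finite(S)) || all(S == 0, na.rm = TRUE))
    stop("degenerate-input: entire series is zero or non-finite")
  Y <- sweep(S, 2L, sin(a), "/")
  X <- sweep(S, 2L, tan(a), "/")

  xbar <- rowMeans(X); ybar <- rowMeans(Y)
  sxx <- rowSums(X^2) - n_ang * xbar^2
  sxy <- rowSums(X * Y) - n_ang * xbar * ybar
  syy <- rowSums(Y^2) - n_ang * ybar^2
  slope <- sxy / sxx
  r2 <- ifelse(sxx > 0 & syy > 0, sxy^2 / (sxx * syy), NA_real_)

  t1 <- -series$TR / log(slope)
  valid <- is.finite(slope) & slope > 0 & slope < 1 &
    is.finite(t1) & t1 > 1 & t1 < 10000 &
    rowSums(abs(S)) > 0
  t1[!valid] <- NA_real_
  m0 <- (ybar - slope * xbar) / (1 - slope)
  m0[!valid] <- NA_real_
  r2[!valid] <- NA_real_

  list(t1 = volume_grid(array(t1, d), ref$spacing, ref$affine, units = "ms"),
       m0 = volume_grid(array(m0, d), ref$spacing, ref$affine),
       r_squared = volume_grid(array(r2, d), ref$spacing, ref$affine),
       valid = array(valid, d))
}

#' Gadolinium concentration map from pre/post-contrast T1 maps
#'
#' Converts the contrast-induced change in longitudinal relaxation rate into
#' gadolinium concentration:
#' `[Gd] = (1/T1 - 1/T1_0) / r1` (rates in 1/s), where `T1` is the
#' post-contrast and `T1_0` the pre-contrast relaxation time and `r1` the
#' agent's relaxivity (4 /s/mM for gadodiamide, Gd-DTPA-BMA).  Negative
#' concentrations (noise making T1 > T1_0) are clamped to 0 and counted;
#' voxels invalid in either T1 map propagate as NA.
#'
#' @param t1_post,t1_pre Post- and pre-contrast T1 maps in ms
#'   ([volume_grid]s on one grid).
#' @param r1 Relaxivity in 1/s/mM. Default 4.
#' @return An object of class `gd_map`: list with `concentration`
#'   ([volume_grid], mM), `r1`, `n_clamped`, `n_invalid`.
#' @export
gd_concentration <- function(t1_post, t1_pre, r1 = 4) {
  stop_if_grid_mismatch(t1_post, t1_pre)
  stopifnot(r1 > 0)
  conc <- (1000 / t1_post$voxels - 1000 / t1_pre$voxels) / r1   # ms -> s rates
  n_invalid <- sum(is.na(conc))
  n_clamped <- sum(conc < 0, na.rm = TRUE)
  conc[conc < 0] <- 0
  structure(
    list(concentration = volume_grid(conc, t1_post$spacing, t1_post$affine,
                                     units = "mM"),
         r1 = r1, n_clamped = n_clamped, n_invalid = n_invalid),
    class = "gd_map")
}

#' @export
print.gd_map <- function(x, ...) {
  cat(sprintf("<gd_map> r1 = %g /s/mM; peak [Gd] = %.4g mM; %d clamped, %d invalid voxels\n",
              x$r1, max(x$concentration$voxels, na.rm = TRUE),
              x$n_clamped, x$n_invalid))
  invisible(x)
}

#' Default T1-range tissue thresholds (ms)
#'
#' Boundaries of the half-open T1 intervals used to label brain tissue on the
#' pre-contrast T1 map: blood (1, 700], white matter (700, 1170], gray matter
#' (1170, 1800], cerebrospinal fluid (1800, 5000].
#'
#' @return Named numeric vector of interval boundaries.
#' @export
t1_tissue_thresholds <- function() {
  c(min = 1, blood = 700, white = 1170, gray = 1800, csf = 5000)
}

#' Segment brain tissue by T1 ranges
#'
#' Labels each voxel of a pre-contrast T1 map by half-open interval
#' membership `(lo, hi]`: blood, white matter, gray matter, CSF; voxels
#' outside (1, 5000] ms (or NA) are `unassigned`.
#'
#' @param t1_pre Pre-contrast T1 map in ms ([volume_grid]).
#' @param thresholds Strictly increasing boundaries as returned by
#'   [t1_tissue_thresholds()].
#' @return An object of class `tissue_segmentation`: list with `labels`
#'   (character array), `codes` (integer [volume_grid]; 0 = unassigned,
#'   1 = blood, 2 = white, 3 = gray, 4 = csf), `thresholds`, `counts`.
#' @export
segment_tissue <- function(t1_pre, thresholds = t1_tissue_thresholds()) {
  stopifnot(inherits(t1_pre, "volume_grid"), length(thresholds) == 5L)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("configuration error: thresholds must be strictly increasing")
  t1 <- t1_pre$voxels
  code <- array(0L, dim(t1))
  tissue_names <- c("blood", "white", "gray", "csf")
  for (i in 1:4) {
    sel <- !is.na(t1) & t1 > thresholds[i] & t1 <= thresholds[i + 1]
    code[sel] <- i
  }
  labels <- array(c("unassigned", tissue_names)[code + 1L], dim(t1))
  counts <- table(factor(labels, levels = c(tissue_names, "unassigned")))
  structure(
    list(labels = labels,
         codes = volume_grid(array(as.numeric(code), dim(t1)),
                             t1_pre$spacing, t1_pre$affine, units = "label"),
         thresholds = thresholds, counts = counts),
    class = "tissue_segmentation")
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  cat("<tissue_segmentation> voxel counts:\n")
  print(x$counts)
  invisible(x)
}

#' Write a tissue segmentation as integer-coded NIfTI + JSON legend
#'
#' @param seg A [tissue_segmentation].
#' @param nifti_path Output NIfTI path.
#' @param legend_path Output JSON legend path.
#' @return `nifti_path`, invisibly.
#' @export
write_segmentation <- function(seg, nifti_path, legend_path) {
  write_volume(seg$codes, nifti_path)
  jsonlite::write_json(
    list(`0` = "unassigned", `1` = "blood", `2` = "white",
         `3` = "gray", `4` = "csf",
         thresholds_ms = as.list(seg$thresholds)),
    legend_path, auto_unbox = TRUE, digits = NA)
  invisible(nifti_path)
}
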