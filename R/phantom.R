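#' Synthetic brain-phantom specification
#'
#' Parameters of the 3D digital phantom used to validate the relaxometry and
#' opening-quantification chain: an ellipsoidal brain with white-matter core,
#' central CSF ventricle and a vertical blood vessel (the intravascular
#' reference), wrapped in an ellipsoidal skull shell, plus an ellipsoidal
#' focal gadolinium-uptake region ("opening") with known ground truth.
#' Per-tissue pre-contrast T1 values sit inside the corresponding T1
#' segmentation intervals: white 950 ms, gray 1400 ms, blood 400 ms, CSF
#' 3000 ms.
#'
#' @param shape Grid dimensions. Default `c(96, 96, 64)`.
#' @param spacing Voxel spacing in mm. Default 1 mm isotropic.
#' @param t1_ms Named per-tissue pre-contrast T1 (ms): `white`, `gray`,
#'   `blood`, `csf`.
#' @param opening_center World-mm centre of the uptake ellipsoid (positive x
#'   = ipsilateral side; the mid-sagittal plane is x = 0).
#' @param opening_semi_axes Ellipsoid semi-axes in mm.
#' @param opening_peak_mM Peak added gadolinium concentration in mM.
#' @param opening_profile `"uniform"` or `"gaussian"` radial concentration
#'   profile.
#' @param background_mM Intrinsic gadolinium retention (mM) added to all
#'   brain tissue post-contrast (removed downstream by contralateral
#'   subtraction).
#' @param vessel_mM Intravascular gadolinium concentration (mM).
#' @param snr Per-image signal-to-noise ratio of the synthetic volumes
#'   (mean in-brain signal / noise sd); `Inf` for noiseless.
#' @param r1 Contrast-agent relaxivity in 1/s/mM.
#' @param seed Integer seed; fixed seed gives bit-identical phantoms.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 64), spacing = c(1, 1, 1),
                         t1_ms = c(white = 950, gray = 1400,
                                   blood = 400, csf = 3000),
                         opening_center = c(26, 5, 0),
                         opening_semi_axes = c(4, 4, 4.5),
                         opening_peak_mM = 0.07,
                         opening_profile = c("uniform", "gaussian"),
                         background_mM = 0.015, vessel_mM = 0.15,
                         snr = 50, r1 = 4, seed = 1L) {
  opening_profile <- match.arg(opening_profile)
  stopifnot(length(shape) == 3L, all(shape >= 16),
            all(spacing > 0), all(opening_semi_axes > 0),
            opening_peak_mM >= 0, background_mM >= 0, vessel_mM >= 0,
            snr > 0, r1 > 0)
  thr <- t1_tissue_thresholds()
  lims <- list(white = thr[c("blood", "white")], gray = thr[c("white", "gray")],
               blood = c(thr["min"], thr["blood"]), csf = thr[c("gray", "csf")])
  for (tn in names(lims))
    if (t1_ms[[tn]] <= lims[[tn]][1] || t1_ms[[tn]] > lims[[tn]][2])
      stop(sprintf("configuration error: T1 for %s (%g ms) outside its segmentation interval",
                   tn, t1_ms[[tn]]))
  structure(
    list(shape = as.integer(shape), spacing = as.numeric(spacing),
         t1_ms = t1_ms, opening_center = as.numeric(opening_center),
         opening_semi_axes = as.numeric(opening_semi_axes),
         opening_peak_mM = opening_peak_mM, opening_profile = opening_profile,
         background_mM = background_mM, vessel_mM = vessel_mM,
         snr = snr, r1 = r1, seed = as.integer(seed)),
    class = "phantom_spec")
}

# World-coordinate meshgrid arrays for a grid.
world_mesh <- function(grid) {
  w <- axis_world_coords(grid)
  d <- dim(grid$voxels)
  list(x = array(rep(w[[1]], times = d[2] * d[3]), d),
       y = array(rep(rep(w[[2]], each = d[1]), times = d[3]), d),
       z = array(rep(w[[3]], each = d[1] * d[2]), d))
}

ellipsoid_rho2 <- function(mesh, center, semi) {
  ((mesh$x - center[1]) / semi[1])^2 +
    ((mesh$y - center[2]) / semi[2])^2 +
    ((mesh$z - center[3]) / semi[3])^2
}

#' Build the synthetic brain phantom
#'
#' Forward-generates everything the quantification pipeline consumes, from
#' known ground truth: pre/post-contrast T1 maps (post-contrast rate
#' `R1 = R1_0 + r1 [Gd]`), pre/post VFA SPGR series at flip angles
#' 5/10/15/20/35 degrees (TR = 10 ms), pre/post T1-weighted volumes (SPGR at
#' 8 degrees, TR = 8.5 ms), a matched sham T1w pair (no uptake, independent
#' noise), masks, reference regions, tissue truth labels, and the truth
#' record (voxelized opening volume, delivered amount by direct summation).
#' Gaussian noise is added to image magnitudes at the spec's per-image SNR.
#'
#' @param spec A [phantom_spec].
#' @return List with elements `t1_pre`, `t1_post` (noiseless truth maps,
#'   [volume_grid]), `vfa_pre`, `vfa_post` ([vfa_series]), `t1w_pre`,
#'   `t1w_post`, `t1w_sham_pre`, `t1w_sham_post`, `brain_mask`,
#'   `skull_mask`, `thalamus_mask`, `aca_mask`, `labels`
#'   (truth [tissue_segmentation]-style character array), `conc_truth`
#'   ([volume_grid], mM added by the opening), and `truth` (list:
#'   `opening_volume_mm3`, `delivered_nmol`, `center`, `n_opening_voxels`).
#' @export
build_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  ref <- volume_grid(array(0, spec$shape), spec$spacing)
  mesh <- world_mesh(ref)
  d <- spec$shape

  brain_semi <- pmin(c(36, 36, 24) * spec$spacing / 1,
                     (d - 12) * spec$spacing / 2)
  brain <- ellipsoid_rho2(mesh, c(0, 0, 0), brain_semi) <= 1
  skull <- ellipsoid_rho2(mesh, c(0, 0, 0), brain_semi + 4) <= 1 &
    ellipsoid_rho2(mesh, c(0, 0, 0), brain_semi + 1) > 1
  white <- brain & ellipsoid_rho2(mesh, c(0, 0, 0), brain_semi * 0.55) <= 1
  csf <- brain & ellipsoid_rho2(mesh, c(0, 0, 6), c(5, 9, 4)) <= 1
  vessel <- brain & sqrt(mesh$x^2 + (mesh$y - 18)^2) <= 1.5
  labels <- array("unassigned", d)
  labels[brain] <- "gray"
  labels[white] <- "white"
  labels[csf] <- "csf"
  labels[vessel] <- "blood"

  thal <- brain & ellipsoid_rho2(mesh, c(0, -12, 0), c(4, 4, 4)) <= 1
  aca <- vessel & abs(mesh$z) <= 8

  rho2 <- ellipsoid_rho2(mesh, spec$opening_center, spec$opening_semi_axes)
  opening <- rho2 <= 1
  if (any(opening & !brain))
    stop("configuration error: opening extends outside the brain")
  conc <- array(0, d)
  if (spec$opening_peak_mM > 0) {
    if (spec$opening_profile == "uniform") {
      conc[opening] <- spec$opening_peak_mM
    } else {
      conc[opening] <- spec$opening_peak_mM * exp(-2 * rho2[opening])
    }
  }

  t1_pre <- array(NA_real_, d)
  for (tn in c("gray", "white", "csf", "blood"))
    t1_pre[labels == tn] <- spec$t1_ms[[tn]]

  total_conc <- conc
  total_conc[brain] <- total_conc[brain] + spec$background_mM
  total_conc[vessel] <- spec$vessel_mM
  r1_pre <- 1000 / t1_pre
  t1_post <- 1000 / (r1_pre + spec$r1 * total_conc)

  m0 <- array(0, d)
  m0[brain] <- 1

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  noisy <- function(sig) {
    if (!is.finite(spec$snr)) return(sig)
    sd <- mean(sig[brain]) / spec$snr
    sig + array(stats::rnorm(length(sig), sd = sd), dim(sig))
  }
  render <- function(t1_map, flip, TR) {
    s <- array(0, d)
    inb <- brain & !is.na(t1_map)
    s[inb] <- spgr_signal(t1_map[inb], flip, TR, m0[inb])
    noisy(s)
  }
  vg <- function(v, units = "") volume_grid(v, spec$spacing, ref$affine, units)
  angles <- c(5, 10, 15, 20, 35)
  vfa_pre <- vfa_series(lapply(angles, function(a) vg(render(t1_pre, a, 10))),
                        flip_angles = angles, TR = 10)
  vfa_post <- vfa_series(lapply(angles, function(a) vg(render(t1_post, a, 10))),
                         flip_angles = angles, TR = 10)
  t1w_pre <- vg(render(t1_pre, 8, 8.5))
  t1w_post <- vg(render(t1_post, 8, 8.5))

  t1_sham_post <- 1000 / (r1_pre + spec$r1 * (total_conc - conc))
  t1w_sham_pre <- vg(render(t1_pre, 8, 8.5))
  t1w_sham_post <- vg(render(t1_sham_post, 8, 8.5))

  vv <- voxel_volume(ref)
  list(t1_pre = vg(t1_pre, "ms"), t1_post = vg(t1_post, "ms"),
       vfa_pre = vfa_pre, vfa_post = vfa_post,
       t1w_pre = t1w_pre, t1w_post = t1w_post,
       t1w_sham_pre = t1w_sham_pre, t1w_sham_post = t1w_sham_post,
       brain_mask = vg(array(as.numeric(brain), d), "mask"),
       skull_mask = vg(array(as.numeric(skull), d), "mask"),
       thalamus_mask = thal, aca_mask = aca,
       labels = labels, conc_truth = vg(conc, "mM"),
       spec = spec,
       truth = list(opening_volume_mm3 = sum(opening) * vv,
                    delivered_nmol = sum(conc) * vv,
                    center = spec$opening_center,
                    n_opening_voxels = sum(opening)))
}

#' Build a skull/opening phantom for targeting-accuracy analysis
#'
#' Spherical-shell skull with analytically known surface normals, a planned
#' targeting vector, and an ellipsoidal (optionally elongated and tilted)
#' opening displaced by a known offset from the planned focus.
#'
#' @param shape,spacing Grid geometry. Default 96^3 at 1 mm.
#' @param skull_center World-mm centre of the spherical skull.
#' @param outer_radius,inner_radius Skull shell radii in mm.
#' @param focus Planned focus, world mm.
#' @param trajectory Approach direction (unit vector, from transducer toward
#'   the focus).
#' @param opening_offset Displacement of the true opening centre from the
#'   planned focus, world mm.
#' @param opening_semi_axes Opening ellipsoid semi-axes in mm (long axis
#'   along `opening_axis`).
#' @param opening_axis Unit vector of the opening's long axis.
#' @return List with `skull_mask`, `opening_mask` ([volume_grid]s), `plan`
#'   ([target_plan]), and `truth` (entry point, analytic outer/inner normals
#'   at the trajectory entry, analytic incidence angle, true shift).
#' @export
build_targeting_phantom <- function(shape = c(96, 96, 96), spacing = c(1, 1, 1),
                                    skull_center = c(0, 0, 0),
                                    outer_radius = 42, inner_radius = 38,
                                    focus = c(0, 0, -10),
                                    trajectory = c(0, 0, -1),
                                    opening_offset = c(0, 0, 0),
                                    opening_semi_axes = c(3, 3, 8),
                                    opening_axis = c(0, 0, 1)) {
  stopifnot(outer_radius > inner_radius, inner_radius > 0)
  trajectory <- trajectory / sqrt(sum(trajectory^2))
  opening_axis <- opening_axis / sqrt(sum(opening_axis^2))
  ref <- volume_grid(array(0, shape), spacing)
  mesh <- world_mesh(ref)
  r <- sqrt((mesh$x - skull_center[1])^2 + (mesh$y - skull_center[2])^2 +
              (mesh$z - skull_center[3])^2)
  skull <- r <= outer_radius & r >= inner_radius

  # entry point: first intersection of the approach ray with the outer sphere
  oc <- focus - skull_center
  b <- sum(oc * trajectory)
  disc <- b^2 - (sum(oc^2) - outer_radius^2)
  if (disc < 0)
    stop("configuration error: trajectory misses the skull")
  s_entry <- b + sqrt(disc)          # farthest along -trajectory from focus
  entry <- focus - s_entry * trajectory
  n_outer <- (entry - skull_center) / outer_radius
  s_inner <- b + sqrt(max(b^2 - (sum(oc^2) - inner_radius^2), 0))
  inner_pt <- focus - s_inner * trajectory
  n_inner <- -(inner_pt - skull_center) / sqrt(sum((inner_pt - skull_center)^2))

  center <- focus + opening_offset
  # orthonormal frame with w3 = opening axis
  w3 <- opening_axis
  tmp <- if (abs(w3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w1 <- tmp - sum(tmp * w3) * w3; w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(w3[2] * w1[3] - w3[3] * w1[2],
          w3[3] * w1[1] - w3[1] * w1[3],
          w3[1] * w1[2] - w3[2] * w1[1])
  dx <- mesh$x - center[1]; dy <- mesh$y - center[2]; dz <- mesh$z - center[3]
  u1 <- dx * w1[1] + dy * w1[2] + dz * w1[3]
  u2 <- dx * w2[1] + dy * w2[2] + dz * w2[3]
  u3 <- dx * w3[1] + dy * w3[2] + dz * w3[3]
  opening <- (u1 / opening_semi_axes[1])^2 + (u2 / opening_semi_axes[2])^2 +
    (u3 / opening_semi_axes[3])^2 <= 1

  plan <- target_plan(focus = focus, trajectory = trajectory)
  vg <- function(v) volume_grid(array(as.numeric(v), shape), spacing,
                                ref$affine, units = "mask")
  list(skull_mask = vg(skull), opening_mask = vg(opening), plan = plan,
       truth = list(entry = entry, n_outer = n_outer, n_inner = n_inner,
                    incidence_deg = acos(min(1, abs(sum(trajectory * n_outer)))) * 180 / pi,
                    center = center,
                    shift = sqrt(sum(opening_offset^2))))
}
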