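#' Planned targeting vector
#'
#' The stereotactic plan: the intended focus position and the transducer
#' approach direction (trajectory, pointing from the transducer toward the
#' focus).
#'
#' @param focus World-mm focus coordinate.
#' @param trajectory Approach direction; normalized to unit length.
#' @return An object of class `target_plan`.
#' @export
target_plan <- function(focus, trajectory) {
  stopifnot(length(focus) == 3L, length(trajectory) == 3L)
  nrm <- sqrt(sum(trajectory^2))
  if (nrm == 0) stop("invalid-input: trajectory must be non-zero")
  structure(list(focus = as.numeric(focus),
                 trajectory = as.numeric(trajectory) / nrm),
            class = "target_plan")
}

#' Read a targeting plan from YAML
#'
#' Expects keys `focus` (3 world-mm numbers) and `trajectory` (3 numbers).
#'
#' @param path YAML file path.
#' @return A [target_plan].
#' @export
read_target_plan <- function(path) {
  y <- yaml::read_yaml(path)
  target_plan(unlist(y$focus), unlist(y$trajectory))
}

# Partition a closed mask's boundary into outer (adjacent to the exterior
# background) and inner (adjacent to an enclosed cavity) surface voxels.
# The exterior is grown from the grid border through background voxels by
# iterative 6-neighbour propagation.
skull_surfaces <- function(mask_arr) {
  d <- dim(mask_arr)
  bg <- !mask_arr
  ext <- array(FALSE, d)
  ext[1, , ] <- bg[1, , ]; ext[d[1], , ] <- bg[d[1], , ]
  ext[, 1, ] <- ext[, 1, ] | bg[, 1, ]; ext[, d[2], ] <- ext[, d[2], ] | bg[, d[2], ]
  ext[, , 1] <- ext[, , 1] | bg[, , 1]; ext[, , d[3]] <- ext[, , d[3]] | bg[, , d[3]]
  repeat {
    grown <- shift6_or(ext) & bg
    newext <- ext | grown
    if (sum(newext) == sum(ext)) break
    ext <- newext
  }
  interior <- bg & !ext
  list(outer = mask_arr & shift6_or(ext),
       inner = mask_arr & shift6_or(interior))
}

# Logical OR of the 6 face-neighbour shifts of a 3D logical array.
shift6_or <- function(x) {
  d <- dim(x)
  out <- array(FALSE, d)
  out[-1, , ] <- out[-1, , ] | x[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | x[-1, , ]
  out[, -1, ] <- out[, -1, ] | x[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | x[, -1, ]
  out[, , -1] <- out[, , -1] | x[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | x[, , -1]
  out
}

#' Surface normal of a skull mask from its smoothed 3D gradient
#'
#' Estimates the unit normal of the outer or inner skull surface at the
#' surface voxel nearest to `point`: the binary mask is Gaussian-smoothed
#' (default sigma 1 voxel; raw binary gradients are too noisy), the gradient
#' is taken by central differences in world units, and the normal is
#' oriented away from the skull interior of the requested surface (outward
#' for the outer surface, toward the enclosed cavity for the inner surface).
#'
#' @param skull_mask Skull mask ([volume_grid] or logical array with unit
#'   spacing).
#' @param point World-mm query point; must lie within about one
#'   voxel-diagonal of the requested surface.
#' @param surface `"outer"` or `"inner"`.
#' @param sigma Smoothing sigma in voxels.
#' @return Unit normal vector (world coordinates).
#' @export
surface_normal <- function(skull_mask, point, surface = c("outer", "inner"),
                           sigma = 1) {
  surface <- match.arg(surface)
  grid <- if (inherits(skull_mask, "volume_grid")) skull_mask
          else volume_grid(skull_mask)
  geo <- skull_geometry(grid, sigma)
  surface_normal_at(grid, geo, point, surface)
}

# Precompute the outer/inner surface partition and the smoothed mask once;
# surface_normal_at() evaluates normals against this cache.
skull_geometry <- function(grid, sigma = 1) {
  mask_arr <- grid$voxels > 0.5
  surf <- skull_surfaces(mask_arr)
  sm <- gaussian_smooth3(array(as.numeric(mask_arr), dim(mask_arr)), sigma)
  list(surfaces = surf, smoothed = sm, sigma = sigma)
}

surface_normal_at <- function(grid, geo, point, surface) {
  surf <- geo$surfaces[[surface]]
  if (!any(surf)) stop("off-surface: mask has no ", surface, " surface")
  idx <- which(surf, arr.ind = TRUE) - 1
  wpts <- voxel_to_world(grid, idx)
  d2 <- colSums((t(wpts) - point)^2)
  j <- which.min(d2)
  tol <- 1.5 * sqrt(sum(grid$spacing^2))
  if (sqrt(d2[j]) > tol)
    stop(sprintf("off-surface: point is %.1f mm from the %s surface (tolerance %.1f mm)",
                 sqrt(d2[j]), surface, tol))
  # average the smoothed-mask gradient over the surface voxel and its
  # face neighbours on the same surface to tame discretization jitter
  v0 <- idx[j, ] + 1
  near <- rbind(v0, v0 + c(1, 0, 0), v0 - c(1, 0, 0), v0 + c(0, 1, 0),
                v0 - c(0, 1, 0), v0 + c(0, 0, 1), v0 - c(0, 0, 1))
  d <- dim(surf)
  g <- c(0, 0, 0)
  for (k in seq_len(nrow(near))) {
    v <- near[k, ]
    if (any(v < 1) || any(v > d)) next
    if (!surf[v[1], v[2], v[3]]) next
    g <- g + grad_at(geo$smoothed, v, grid$spacing)
  }
  if (sqrt(sum(g^2)) == 0) stop("off-surface: vanishing gradient at surface voxel")
  # gradient points toward increasing mask (into the skull); both requested
  # orientations face away from the skull material
  -g / sqrt(sum(g^2))
}

# Central-difference gradient of a 3D array at voxel v (1-based), per mm.
grad_at <- function(x, v, spacing) {
  d <- dim(x)
  g <- numeric(3)
  for (ax in 1:3) {
    lo <- v; hi <- v
    lo[ax] <- max(1L, v[ax] - 1L); hi[ax] <- min(d[ax], v[ax] + 1L)
    g[ax] <- (x[hi[1], hi[2], hi[3]] - x[lo[1], lo[2], lo[3]]) /
      ((hi[ax] - lo[ax]) * spacing[ax])
  }
  g
}

# First crossing of the approach ray into/out of the skull mask, marching
# from the transducer side toward the focus in quarter-voxel steps.
trajectory_skull_points <- function(grid, plan, step_frac = 0.25) {
  mask <- grid$voxels > 0.5
  d <- dim(mask)
  diag_len <- sqrt(sum((d * grid$spacing)^2))
  step <- step_frac * min(grid$spacing)
  s <- seq(diag_len, -diag_len, by = -step)
  inside_mask <- function(p) {
    v <- round(world_to_voxel(grid, p)) + 1
    if (any(v < 1) || any(v > d)) return(FALSE)
    mask[v[1], v[2], v[3]]
  }
  entry <- NULL; exit <- NULL
  prev_in <- FALSE
  for (si in s) {
    p <- plan$focus - si * plan$trajectory
    inb <- inside_mask(p)
    if (inb && !prev_in && is.null(entry)) entry <- p
    if (!inb && prev_in && !is.null(entry) && is.null(exit)) {
      exit <- p
      break
    }
    prev_in <- inb
  }
  if (is.null(entry)) stop("missed-skull: trajectory does not intersect the skull mask")
  list(entry = entry, exit = exit %||% entry)
}

#' Incidence and refraction angles at the skull
#'
#' The incidence angle is the angle between the planned trajectory and the
#' outer-surface normal of the skull at the beam entry point; the refraction
#' angle is the angle between the observed BBB-opening vector and the
#' inner-surface normal where the beam leaves the skull.  Both are absolute
#' acute angles (arccos of the absolute dot product), in degrees.
#'
#' @param plan A [target_plan].
#' @param opening_vector Unit direction of the observed opening (from
#'   [opening_vector_fit()]); defaults to the planned trajectory when the
#'   opening direction is undefined.
#' @param skull_mask Skull mask ([volume_grid]).
#' @param sigma Gradient smoothing sigma (voxels).
#' @return List with `incidence_deg`, `refraction_deg`, `entry`, `exit`.
#' @export
incidence_refraction <- function(plan, opening_vector = NULL, skull_mask,
                                 sigma = 1) {
  stopifnot(inherits(plan, "target_plan"))
  grid <- if (inherits(skull_mask, "volume_grid")) skull_mask
          else volume_grid(skull_mask)
  pts <- trajectory_skull_points(grid, plan)
  geo <- skull_geometry(grid, sigma)
  n_out <- surface_normal_at(grid, geo, pts$entry, "outer")
  n_in <- surface_normal_at(grid, geo, pts$exit, "inner")
  ov <- opening_vector %||% plan$trajectory
  ov <- ov / sqrt(sum(ov^2))
  ang <- function(u, v) acos(min(1, abs(sum(u * v)))) * 180 / pi
  list(incidence_deg = ang(plan$trajectory, n_out),
       refraction_deg = ang(ov, n_in),
       entry = pts$entry, exit = pts$exit)
}

#' Centre of mass and direction of the BBB opening
#'
#' The opening's 3D centre of mass, and its direction as the unit vector of
#' the least-squares 3D line through the per-slice 2D centres of mass
#' (slices taken along the third grid axis by convention), oriented toward
#' increasing slice index.  With fewer than two non-empty slices the centre
#' is still returned and the direction is flagged undefined.
#'
#' @param opened_mask Opened-voxel mask ([volume_grid] or logical array).
#' @param slice_axis Grid axis defining "horizontal" slices. Default 3.
#' @return List with `com` (world mm), `direction` (unit vector or NA),
#'   `direction_defined`, `n_slices`.
#' @export
opening_vector_fit <- function(opened_mask, slice_axis = 3L) {
  grid <- if (inherits(opened_mask, "volume_grid")) opened_mask
          else volume_grid(opened_mask)
  mask <- grid$voxels > 0.5
  if (!any(mask)) stop("empty-input: opened mask has no voxels")
  idx <- which(mask, arr.ind = TRUE) - 1
  wpts <- voxel_to_world(grid, idx)
  com <- colMeans(wpts)

  slices <- sort(unique(idx[, slice_axis]))
  centers <- t(vapply(slices, function(s) {
    colMeans(wpts[idx[, slice_axis] == s, , drop = FALSE])
  }, numeric(3)))
  if (length(slices) < 2L)
    return(list(com = com, direction = rep(NA_real_, 3),
                direction_defined = FALSE, n_slices = length(slices)))
  pc <- stats::prcomp(centers, center = TRUE)
  dir <- pc$rotation[, 1]
  # orient toward increasing slice index (world direction of the slice axis)
  axis_world <- grid$affine[1:3, slice_axis]
  if (sum(dir * axis_world) < 0) dir <- -dir
  list(com = com, direction = dir / sqrt(sum(dir^2)),
       direction_defined = TRUE, n_slices = length(slices))
}

#' Target-shift decomposition
#'
#' Decomposes the displacement from the planned focus to the opening centre
#' of mass into the component parallel to the trajectory (axial shift) and
#' perpendicular to it (lateral shift); the total shift is the Euclidean
#' distance, so `total^2 = lateral^2 + axial^2`.
#'
#' @param plan A [target_plan].
#' @param opening_com Opening centre of mass, world mm.
#' @return List with `total_mm`, `lateral_mm`, `axial_mm`.
#' @export
shift_decomposition <- function(plan, opening_com) {
  stopifnot(inherits(plan, "target_plan"), length(opening_com) == 3L)
  d <- as.numeric(opening_com) - plan$focus
  axial <- abs(sum(d * plan$trajectory))
  lat_vec <- d - sum(d * plan$trajectory) * plan$trajectory
  list(total_mm = sqrt(sum(d^2)),
       lateral_mm = sqrt(sum(lat_vec^2)),
       axial_mm = axial)
}

#' Full targeting-accuracy report
#'
#' Combines the opening-vector fit, the skull angles and the shift
#' decomposition into one record.
#'
#' @param plan A [target_plan].
#' @param opened_mask Opened-voxel mask.
#' @param skull_mask Skull mask.
#' @param sigma Gradient smoothing sigma (voxels).
#' @return An object of class `targeting_report`.
#' @export
targeting_report <- function(plan, opened_mask, skull_mask, sigma = 1) {
  fit <- opening_vector_fit(opened_mask)
  ang <- incidence_refraction(plan,
                              if (fit$direction_defined) fit$direction else NULL,
                              skull_mask, sigma = sigma)
  sh <- shift_decomposition(plan, fit$com)
  structure(c(ang[c("incidence_deg", "refraction_deg")], sh,
              list(opening_com = fit$com, opening_vector = fit$direction,
                   direction_defined = fit$direction_defined)),
            class = "targeting_report")
}

#' @export
print.targeting_report <- function(x, ...) {
  cat(sprintf("<targeting_report> incidence %.1f deg, refraction %.1f deg\n",
              x$incidence_deg, x$refraction_deg))
  cat(sprintf("  shift: total %.2f mm (lateral %.2f, axial %.2f)\n",
              x$total_mm, x$lateral_mm, x$axial_mm))
  invisible(x)
}
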