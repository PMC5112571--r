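#' Volume of interest on the targeted region
#'
#' Axis-aligned box in world coordinates placed on the sonicated target; the
#' contralateral control VOI is its mirror image across the mid-sagittal
#' plane.  Default extents 10 x 10 x 32.5 mm (lateral x AP x axial, matching
#' the elongated ultrasound focus).
#'
#' @param center World-mm centre of the ipsilateral VOI.
#' @param extents Box edge lengths in mm per world axis.
#' @param midline World x-coordinate of the mid-sagittal mirror plane
#'   (mirroring is across the first world axis). Default 0.
#' @return An object of class `voi_spec`.
#' @export
voi_spec <- function(center, extents = c(10, 10, 32.5), midline = 0) {
  stopifnot(length(center) == 3L, length(extents) == 3L, all(extents > 0))
  structure(list(center = as.numeric(center), extents = as.numeric(extents),
                 midline = as.numeric(midline)),
            class = "voi_spec")
}

# Logical arrays selecting the ipsilateral and mirrored contralateral VOI
# voxels; boxes extending outside the grid are clipped with a warning.
voi_masks <- function(grid, voi) {
  stopifnot(inherits(grid, "volume_grid"), inherits(voi, "voi_spec"))
  w <- axis_world_coords(grid)
  clipped <- FALSE
  box_mask <- function(center) {
    sel <- lapply(1:3, function(ax)
      w[[ax]] >= center[ax] - voi$extents[ax] / 2 &
      w[[ax]] <= center[ax] + voi$extents[ax] / 2)
    out_of_grid <- vapply(1:3, function(ax) {
      lo <- center[ax] - voi$extents[ax] / 2
      hi <- center[ax] + voi$extents[ax] / 2
      lo < min(w[[ax]]) - grid$spacing[ax] / 2 ||
        hi > max(w[[ax]]) + grid$spacing[ax] / 2
    }, logical(1))
    clipped <<- clipped || any(out_of_grid)
    outer(outer(sel[[1]], sel[[2]], "&"), sel[[3]], "&")
  }
  contra_center <- voi$center
  contra_center[1] <- 2 * voi$midline - voi$center[1]
  res <- list(ipsi = box_mask(voi$center), contra = box_mask(contra_center))
  if (clipped) warning("VOI extends outside the image grid; clipped")
  res
}

#' Normalized contrast-enhancement map
#'
#' Ratio of post- to pre-contrast T1-weighted volumes, linearly rescaled so
#' that the mean ratio of the unsonicated thalamus reference region maps to 0
#' and the mean ratio of the anterior cerebral artery (ACA) reference region
#' maps to 1.  Voxels with near-zero pre-contrast signal are flagged NA.
#'
#' @param post_t1w,pre_t1w Post/pre-contrast T1-weighted [volume_grid]s.
#' @param thalamus_mask,aca_mask Logical arrays (or 0/1 [volume_grid]s)
#'   selecting the two non-empty, disjoint reference regions.
#' @param eps Pre-contrast signal magnitude below which a voxel is invalid.
#' @return A [volume_grid] of normalized enhancement (dimensionless).
#' @export
enhancement_map <- function(post_t1w, pre_t1w, thalamus_mask, aca_mask,
                            eps = 1e-12) {
  stop_if_grid_mismatch(post_t1w, pre_t1w)
  thal <- as_mask_array(thalamus_mask, post_t1w)
  aca <- as_mask_array(aca_mask, post_t1w)
  if (!any(thal) || !any(aca))
    stop("configuration error: empty reference region")
  if (any(thal & aca))
    stop("configuration error: reference regions overlap")
  ratio <- post_t1w$voxels / pre_t1w$voxels
  ratio[abs(pre_t1w$voxels) < eps] <- NA_real_
  m_thal <- mean(ratio[thal], na.rm = TRUE)
  m_aca <- mean(ratio[aca], na.rm = TRUE)
  if (!is.finite(m_thal) || !is.finite(m_aca) ||
      abs(m_aca - m_thal) < 1e-9)
    stop("degenerate-references: thalamus and ACA mean ratios coincide")
  volume_grid((ratio - m_thal) / (m_aca - m_thal),
              post_t1w$spacing, post_t1w$affine, units = "norm-enh")
}

as_mask_array <- function(m, ref) {
  if (inherits(m, "volume_grid")) {
    stop_if_grid_mismatch(m, ref)
    m <- m$voxels
  }
  stopifnot(identical(dim(m), dim(ref$voxels)))
  if (!is.logical(m)) m <- m > 0.5
  m & !is.na(m)
}

#' BBB opening volume from enhancement maps
#'
#' Applies the brain mask and subtracts the sham-cohort enhancement map from
#' the normalized enhancement, counts voxels above the voxelwise enhancement
#' cutoff inside the ipsilateral VOI, subtracts the above-cutoff volume of
#' the mirrored contralateral VOI, and floors the result at 0.  Opening is
#' declared significant when the volume exceeds the significance threshold
#' (default 80 mm^3, the sham-cohort mean + 3 SD).
#'
#' @param enh Normalized enhancement map from [enhancement_map()].
#' @param brain_mask Logical array or 0/1 [volume_grid].
#' @param sham_enh Sham (FUS-/MB-) enhancement map on the same grid, or NULL
#'   to proceed without sham subtraction (logged by message).
#' @param voi A [voi_spec].
#' @param cutoff Voxelwise enhancement cutoff defining an "opened" voxel
#'   after sham subtraction.  Either a number (default 0: any residual
#'   enhancement) or `"half-max"` for data-driven full-width-half-maximum
#'   thresholding: the map is lightly smoothed, the opening's plateau
#'   amplitude is estimated robustly inside the ipsilateral VOI, voxels
#'   above half that amplitude are counted, and one iteration corrects the
#'   half-maximum level for the curvature bias of Gaussian blur
#'   (`0.5 - dnorm(0) * sigma / r` with `r` the equivalent spherical
#'   radius of the first-pass volume).
#' @param significance_threshold Total-volume threshold (mm^3) for declaring
#'   BBB opening. Default 80.
#' @param smooth_sigma Gaussian sigma (voxels) applied to the
#'   sham-subtracted map before thresholding. Default 0 (off); with
#'   `cutoff = "half-max"` a default of 0.6 voxel is used when left at 0.
#' @return An object of class `opening_report` (partially filled): list with
#'   `opening_volume` (mm^3), `significant`, `opened_mask` ([volume_grid]),
#'   `ipsi_volume`, `contra_volume`, `cutoff`.
#' @export
opening_volume <- function(enh, brain_mask, sham_enh, voi, cutoff = 0,
                           significance_threshold = 80, smooth_sigma = 0) {
  stopifnot(inherits(enh, "volume_grid"))
  brain <- as_mask_array(brain_mask, enh)
  x <- enh$voxels
  if (is.null(sham_enh)) {
    message("no sham enhancement supplied; proceeding without sham subtraction")
  } else {
    stop_if_grid_mismatch(enh, sham_enh)
    x <- x - sham_enh$voxels
  }
  x[!brain] <- NA_real_
  halfmax <- identical(cutoff, "half-max")
  if (halfmax && smooth_sigma <= 0) smooth_sigma <- 0.6
  if (smooth_sigma > 0) {
    filled <- x
    filled[is.na(filled)] <- 0
    x <- gaussian_smooth3(filled, smooth_sigma)
    x[!brain] <- NA_real_
  }
  vm <- voi_masks(enh, voi)
  vv <- voxel_volume(enh)
  count_above <- function(cut) {
    op <- !is.na(x) & x > cut
    c(ipsi = sum(op & vm$ipsi) * vv, contra = sum(op & vm$contra) * vv)
  }
  if (halfmax) {
    xs <- x[vm$ipsi & !is.na(x)]
    amp <- mean(xs[xs >= 0.8 * max(xs)])
    cutoff <- 0.5 * amp
    v0 <- max(diff(-count_above(cutoff)), 0)
    if (v0 > 0) {
      sigma_mm <- smooth_sigma * mean(enh$spacing)
      r0 <- max((3 * v0 / (4 * pi))^(1 / 3), 2 * sigma_mm)
      cutoff <- amp * (0.5 - stats::dnorm(0) * sigma_mm / r0)
    }
  }
  ct <- count_above(cutoff)
  opened <- !is.na(x) & x > cutoff
  ipsi <- ct[["ipsi"]]
  contra <- ct[["contra"]]
  vol <- max(ipsi - contra, 0)
  structure(
    list(opening_volume = vol,
         significant = vol > significance_threshold,
         opened_mask = volume_grid(array(as.numeric(opened & vm$ipsi),
                                         dim(x)),
                                   enh$spacing, enh$affine, units = "mask"),
         ipsi_volume = ipsi, contra_volume = contra, cutoff = cutoff,
         significance_threshold = significance_threshold),
    class = "opening_report")
}

#' @export
print.opening_report <- function(x, ...) {
  cat(sprintf("<opening_report> volume = %.1f mm^3 (%ssignificant at %g mm^3)\n",
              x$opening_volume, if (x$significant) "" else "not ",
              x$significance_threshold))
  if (!is.null(x$gd_delivered_nmol))
    cat(sprintf("  delivered Gd = %.3g nmol (%.4g%% of injected)\n",
                x$gd_delivered_nmol, x$delivery_efficiency_pct))
  invisible(x)
}

#' Delivered gadolinium amount and delivery efficiency
#'
#' Filters the concentration map by zeroing voxels exceeding the
#' intravascular (ACA) concentration and applying the brain mask, then
#' integrates concentration x voxel volume over the ipsilateral VOI minus
#' the mirrored contralateral VOI (floored at 0).  With concentration in mM
#' and voxel volume in mm^3, the sum is directly in nmol.  Efficiency is the
#' delivered amount as a percentage of the injected dose.
#'
#' @param gd A [gd_map] or a concentration [volume_grid] in mM.
#' @param brain_mask Logical array or 0/1 [volume_grid].
#' @param aca_concentration Intravascular reference concentration in mM
#'   (voxels above it are treated as vessel and zeroed).
#' @param voi A [voi_spec].
#' @param injected_mol Total injected gadolinium in mol. Default 1e-3
#'   (1 mmol).
#' @return List with `gd_delivered_nmol`, `delivery_efficiency_pct`,
#'   `ipsi_nmol`, `contra_nmol`, `n_vessel_zeroed`.
#' @export
delivered_gd <- function(gd, brain_mask, aca_concentration, voi,
                         injected_mol = 1e-3) {
  conc_grid <- if (inherits(gd, "gd_map")) gd$concentration else gd
  stopifnot(inherits(conc_grid, "volume_grid"), aca_concentration > 0,
            injected_mol > 0)
  brain <- as_mask_array(brain_mask, conc_grid)
  conc <- conc_grid$voxels
  vessel <- !is.na(conc) & conc > aca_concentration
  conc[vessel] <- 0
  conc[!brain] <- 0
  conc[is.na(conc)] <- 0
  vm <- voi_masks(conc_grid, voi)
  vv <- voxel_volume(conc_grid)
  ipsi <- sum(conc[vm$ipsi]) * vv          # mM * mm^3 = nmol
  contra <- sum(conc[vm$contra]) * vv
  delivered_nmol <- max(ipsi - contra, 0)
  list(gd_delivered_nmol = delivered_nmol,
       delivery_efficiency_pct = 100 * delivered_nmol * 1e-9 / injected_mol,
       ipsi_nmol = ipsi, contra_nmol = contra,
       n_vessel_zeroed = sum(vessel))
}

#' Per-tissue breakdown of the BBB opening
#'
#' Splits the opened voxels by tissue label, reporting per-tissue opening
#' volumes and fractions, the tissue composition of the sonicated region,
#' the per-tissue opening probability (opened-and-tissue / sonicated-and-
#' tissue), and the gray:white opening-probability ratio.
#'
#' @param opened_mask Opened-voxel mask (logical array or 0/1
#'   [volume_grid]).
#' @param seg A [tissue_segmentation] on the same grid.
#' @param sonicated_mask Mask of the sonicated region (e.g. the ipsilateral
#'   VOI within the brain).
#' @return List with `table` (data frame per tissue: volume mm^3, fraction of
#'   opening, fraction of sonicated region, opening probability) and
#'   `gray_white_ratio` (NaN, with `ratio_defined = FALSE`, if no opened
#'   voxels or no white-matter opening probability).
#' @export
per_tissue_breakdown <- function(opened_mask, seg, sonicated_mask) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  ref <- seg$codes
  opened <- as_mask_array(opened_mask, ref)
  sonic <- as_mask_array(sonicated_mask, ref)
  if (!any(sonic)) stop("configuration error: empty sonicated region")
  vv <- voxel_volume(ref)
  tissues <- c("blood", "white", "gray", "csf", "unassigned")
  lab <- seg$labels
  rows <- lapply(tissues, function(tn) {
    in_t <- lab == tn
    opened_t <- sum(opened & in_t)
    sonic_t <- sum(sonic & in_t)
    data.frame(tissue = tn,
               opened_volume_mm3 = opened_t * vv,
               opening_fraction = if (any(opened)) opened_t / sum(opened) else 0,
               sonicated_fraction = sonic_t / sum(sonic),
               opening_probability = if (sonic_t > 0)
                 sum(opened & in_t & sonic) / sonic_t else NA_real_)
  })
  tab <- do.call(rbind, rows)
  p_gray <- tab$opening_probability[tab$tissue == "gray"]
  p_white <- tab$opening_probability[tab$tissue == "white"]
  ratio_defined <- any(opened) && is.finite(p_gray) && is.finite(p_white) &&
    p_white > 0
  list(table = tab,
       gray_white_ratio = if (ratio_defined) p_gray / p_white else NaN,
       ratio_defined = ratio_defined)
}

#' Assemble and write a full opening report
#'
#' Merges the opening-volume, delivered-amount and per-tissue results into
#' one record and writes it as JSON (plus an optional one-row CSV).
#'
#' @param opening Result of [opening_volume()].
#' @param delivery Result of [delivered_gd()] (optional).
#' @param tissue Result of [per_tissue_breakdown()] (optional).
#' @param json_path,csv_path Output paths (either may be NULL).
#' @return The merged report list, invisibly.
#' @export
write_opening_report <- function(opening, delivery = NULL, tissue = NULL,
                                 json_path = NULL, csv_path = NULL) {
  rep <- list(opening_volume_mm3 = opening$opening_volume,
              significant = opening$significant,
              cutoff = opening$cutoff,
              significance_threshold_mm3 = opening$significance_threshold)
  if (!is.null(delivery))
    rep <- c(rep, delivery[c("gd_delivered_nmol", "delivery_efficiency_pct",
                             "n_vessel_zeroed")])
  if (!is.null(tissue)) {
    rep$gray_white_ratio <- tissue$gray_white_ratio
    rep$per_tissue <- tissue$table
  }
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  if (!is.null(csv_path)) {
    flat <- rep[!vapply(rep, is.data.frame, logical(1))]
    utils::write.csv(as.data.frame(flat), csv_path, row.names = FALSE)
  }
  invisible(rep)
}
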