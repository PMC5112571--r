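# Small synthetic grid with an ipsilateral blob, used by several tests.
blob_setup <- function(dims = c(40, 40, 40), blob_center = c(10, 0, 0),
                       blob_r = 4.6, value = 1) {
  grid <- volume_grid(array(0, dims))
  mesh <- cavimap:::world_mesh(grid)
  blob <- sqrt((mesh$x - blob_center[1])^2 + (mesh$y - blob_center[2])^2 +
                 (mesh$z - blob_center[3])^2) <= blob_r
  grid$voxels[blob] <- value
  list(grid = grid, blob = blob, mesh = mesh,
       brain = array(TRUE, dims),
       voi = voi_spec(center = blob_center, extents = c(12, 12, 12)))
}

test_that("enhancement normalization maps thalamus to 0 and ACA to 1", {
  dims <- c(10, 10, 4)
  pre <- volume_grid(array(1, dims))
  post <- volume_grid(array(1.25, dims))
  thal <- array(FALSE, dims); thal[1:2, 1, 1] <- TRUE
  aca <- array(FALSE, dims); aca[5:6, 1, 1] <- TRUE
  post$voxels[thal] <- 1.0          # ratio 1.0 at thalamus
  post$voxels[aca] <- 1.5           # ratio 1.5 at ACA
  enh <- enhancement_map(post, pre, thal, aca)
  expect_equal(mean(enh$voxels[thal]), 0, tolerance = 1e-12)
  expect_equal(mean(enh$voxels[aca]), 1, tolerance = 1e-12)
  expect_equal(enh$voxels[8, 8, 2], 0.5, tolerance = 1e-12)  # ratio 1.25
  # sub-thalamus ratios map to negative values
  post$voxels[9, 9, 3] <- 0.8
  enh2 <- enhancement_map(post, pre, thal, aca)
  expect_lt(enh2$voxels[9, 9, 3], 0)
})

test_that("degenerate or invalid reference regions are rejected", {
  dims <- c(6, 6, 2)
  pre <- volume_grid(array(1, dims)); post <- volume_grid(array(1, dims))
  thal <- array(FALSE, dims); thal[1, 1, 1] <- TRUE
  aca <- array(FALSE, dims); aca[3, 3, 1] <- TRUE
  expect_error(enhancement_map(post, pre, thal, aca), "degenerate-references")
  expect_error(enhancement_map(post, pre, array(FALSE, dims), aca),
               "empty reference")
  expect_error(enhancement_map(post, pre, thal, thal), "overlap")
})

test_that("opening volume counts supra-cutoff VOI voxels, minus contralateral", {
  s <- blob_setup()
  truth <- sum(s$blob) * voxel_volume(s$grid)
  op <- opening_volume(s$grid, s$brain, NULL, s$voi, cutoff = 0.5) |>
    suppressMessages()
  expect_equal(op$opening_volume, truth)
  expect_true(op$significant)                      # ~400 mm^3 > 80 mm^3

  # zero enhancement: no opening, not significant
  zero <- volume_grid(array(0, dim(s$grid$voxels)))
  op0 <- suppressMessages(opening_volume(zero, s$brain, NULL, s$voi, cutoff = 0.5))
  expect_equal(op0$opening_volume, 0)
  expect_false(op0$significant)

  # identical blob mirrored contralaterally cancels exactly
  sym <- s$grid
  sym$voxels <- pmax(sym$voxels, sym$voxels[dim(sym$voxels)[1]:1, , ])
  ops <- suppressMessages(opening_volume(sym, s$brain, NULL, s$voi, cutoff = 0.5))
  expect_equal(ops$opening_volume, 0)
})

test_that("sham subtraction removes shared background enhancement", {
  s <- blob_setup()
  shared <- volume_grid(array(0.4, dim(s$grid$voxels)))
  withenh <- volume_grid(s$grid$voxels + 0.4, s$grid$spacing, s$grid$affine)
  op <- opening_volume(withenh, s$brain, shared, s$voi, cutoff = 0.5)
  expect_equal(op$opening_volume, sum(s$blob) * voxel_volume(s$grid))
})

test_that("opening volume grows monotonically with the true blob", {
  vols <- vapply(c(3, 4, 5), function(r) {
    s <- blob_setup(blob_r = r)
    suppressMessages(opening_volume(s$grid, s$brain, NULL, s$voi,
                                    cutoff = 0.5))$opening_volume
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("VOI outside the grid is clipped with a warning", {
  s <- blob_setup()
  voi_big <- voi_spec(center = c(18, 0, 0), extents = c(30, 10, 10))
  expect_warning(suppressMessages(
    opening_volume(s$grid, s$brain, NULL, voi_big, cutoff = 0.5)),
    "clipped")
})

test_that("delivered amount reproduces the 15 nmol / 0.0015% identity", {
  dims <- c(40, 40, 40)
  conc <- volume_grid(array(0, dims), units = "mM")
  mesh <- cavimap:::world_mesh(conc)
  region <- abs(mesh$x - 10) <= 3 & abs(mesh$y) <= 4.5 &
    abs(mesh$z - 0.5) <= 2                        # 6 x 10 x 5 voxel box
  expect_equal(sum(region), 300)
  conc$voxels[region] <- 0.05
  voi <- voi_spec(center = c(10, 0, 0), extents = c(12, 12, 12))
  del <- delivered_gd(conc, array(TRUE, dims), aca_concentration = 0.15,
                      voi = voi)
  expect_equal(del$gd_delivered_nmol, 15, tolerance = 1e-12)
  expect_equal(del$delivery_efficiency_pct, 0.0015, tolerance = 1e-12)

  # doubling concentration doubles the delivered amount (below the filter)
  conc2 <- conc; conc2$voxels <- 2 * conc$voxels
  del2 <- delivered_gd(conc2, array(TRUE, dims), 0.15, voi)
  expect_equal(del2$gd_delivered_nmol, 30, tolerance = 1e-12)

  # everything above the ACA concentration is treated as vessel and zeroed
  del3 <- delivered_gd(conc, array(TRUE, dims), aca_concentration = 0.01,
                       voi = voi)
  expect_equal(del3$gd_delivered_nmol, 0)
  expect_equal(del3$n_vessel_zeroed, 300)
})

test_that("contralateral uptake is subtracted from the delivered amount", {
  dims <- c(40, 40, 40)
  conc <- volume_grid(array(0, dims), units = "mM")
  mesh <- cavimap:::world_mesh(conc)
  ipsi <- abs(mesh$x - 10) <= 2 & abs(mesh$y) <= 2 & abs(mesh$z) <= 2
  contra <- abs(mesh$x + 10) <= 2 & abs(mesh$y) <= 2 & abs(mesh$z) <= 2
  conc$voxels[ipsi] <- 0.05
  conc$voxels[contra] <- 0.02
  voi <- voi_spec(center = c(10, 0, 0), extents = c(12, 12, 12))
  del <- delivered_gd(conc, array(TRUE, dims), 0.15, voi)
  expect_equal(del$gd_delivered_nmol,
               sum(ipsi) * 0.05 - sum(contra) * 0.02, tolerance = 1e-12)
})

test_that("per-tissue breakdown reports fractions and the gray:white ratio", {
  dims <- c(30, 30, 10)
  t1 <- array(1400, dims)                      # gray everywhere ...
  t1[1:15, , ] <- 950                          # ... white on the left half
  seg <- segment_tissue(volume_grid(t1))
  sonic <- array(TRUE, dims)

  opened <- array(FALSE, dims); opened[20:24, 5:9, 3:5] <- TRUE  # all gray
  bd <- per_tissue_breakdown(opened, seg, sonic)
  tab <- bd$table
  expect_equal(tab$opening_fraction[tab$tissue == "gray"], 1)
  expect_equal(tab$opened_volume_mm3[tab$tissue == "white"], 0)
  expect_false(bd$ratio_defined)               # no white opening => no ratio

  # binomial opening: P = 0.6 in gray, 0.2 in white, on a 1:1 composition
  withr::with_seed(21, {
    opened2 <- array(FALSE, dims)
    gray <- seg$labels == "gray"
    opened2[gray] <- runif(sum(gray)) < 0.6
    opened2[!gray] <- runif(sum(!gray)) < 0.2
  })
  bd2 <- per_tissue_breakdown(opened2, seg, sonic)
  expect_equal(bd2$table$sonicated_fraction[bd2$table$tissue == "gray"], 0.5)
  expect_equal(bd2$gray_white_ratio, 3, tolerance = 0.15)

  # degenerate inputs
  bd3 <- per_tissue_breakdown(array(FALSE, dims), seg, sonic)
  expect_true(is.nan(bd3$gray_white_ratio))
  expect_error(per_tissue_breakdown(opened, seg, array(FALSE, dims)),
               "empty sonicated")
})
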