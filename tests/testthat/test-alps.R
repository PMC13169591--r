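test_that("alps_index evaluates the formula and its algebraic properties", {
  expect_equal(alps_index(c(1, 1, 1), c(1, 1, 1)), 1.0)
  expect_equal(alps_index(c(1.2, 0.8, 1.6) * 1e-3, c(1.2, 1.6, 0.8) * 1e-3), 1.5)
  expect_equal(alps_index(c(1.0, 0.6, 1.4), c(1.1, 1.5, 0.5)), 1.9091,
               tolerance = 1e-4)
  expect_error(alps_index(c(1, -0.1, 1), c(1, 1, 1)), "denominator")

  set.seed(3)
  for (k in 1:20) {
    proj <- runif(3, 0.1, 2); assoc <- runif(3, 0.1, 2); cc <- runif(1, 0.1, 10)
    a <- alps_index(proj, assoc)
    # scale invariance
    expect_equal(alps_index(cc * proj, cc * assoc), a, tolerance = 1e-12)
    # swapping numerator and denominator component sets gives the reciprocal
    expect_equal(alps_index(c(proj[2], proj[1], proj[3]),
                            c(assoc[3], assoc[2], assoc[1])),
                 1 / a, tolerance = 1e-12)
  }
})

test_that("directional profiles are exact on uniform and degenerate cases", {
  tv <- uniform_field(c(1.1e-3, 0.9e-3, 0.7e-3))
  prof <- directional_profile(tv, y = 4, z = 2, circle_radius = 2.5)
  expect_true(all(abs(prof$dxx - 1.1e-3) < 1e-15))
  expect_true(all(abs(prof$dyy - 0.9e-3) < 1e-15))
  expect_true(all(abs(prof$dzz - 0.7e-3) < 1e-15))

  # circle smaller than half a voxel: the single-voxel diagonal line
  tv$D[, , , 1] <- array(seq_len(prod(dim(tv$D)[1:3])) * 1e-5, dim(tv$D)[1:3])
  prof2 <- directional_profile(tv, y = 4, z = 2, circle_radius = 0.4)
  expect_equal(prof2$dxx, tv$D[, 4, 2, 1])
})

test_that("profile peaks sit at the planted fiber blocks", {
  ph <- make_phantom(small_phantom_spec())
  td <- ph$truth$tensor_diag
  tv <- alpscog:::tensor_volume_from_diag(td$dxx, td$dyy, td$dzz, ph$truth$voxel)
  ctr <- ph$truth$roi_centers
  prof <- directional_profile(tv, y = ctr$proj_left[2], z = ctr$proj_left[3])
  left <- 1:14
  expect_lte(abs(left[which.max(prof$dzz[left])] - ctr$proj_left[1]), 1)
  expect_lte(abs(left[which.max(prof$dyy[left])] - ctr$assoc_left[1]), 1)
})

test_that("automated ROI localization finds all four blocks on a clean phantom", {
  ph <- make_phantom(small_phantom_spec())
  tv <- fit_tensor(ph$dwi)
  sc <- tensor_scalars(tv)
  rois <- locate_alps_rois(tv, sc$fa, band = ph$truth$band)
  expect_length(rois, 4)
  key2truth <- c(left.projection = "proj_left", right.projection = "proj_right",
                 left.association = "assoc_left", right.association = "assoc_right")
  for (k in names(key2truth)) {
    expect_lte(max(abs(rois[[k]]$center_voxel - ph$truth$roi_centers[[key2truth[k]]])), 1)
  }
  qc <- attr(rois, "qc")
  expect_true(all(vapply(qc, function(x) x[["prominence"]] > 1, logical(1))))
})

test_that("a structureless field has no prominent peak to localize", {
  tv <- uniform_field(rep(0.8e-3, 3), shape = c(32L, 32L, 8L), voxel = c(2, 2, 2))
  expect_error(locate_alps_rois(tv, band = list(y = 14:18, z = 3:5)),
               "no prominent")
})

test_that("ROI sphere membership follows mm-space voxel-center distances", {
  # 2 mm isotropic grid, radius 1.5 mm: only the center voxel is inside
  sh <- c(7L, 7L, 7L)
  tv <- uniform_field(rep(1e-3, 3), sh, voxel = c(2, 2, 2))
  tv$D[, , , 1] <- array(0, sh); tv$D[4, 4, 4, 1] <- 5e-3
  roi <- roi_spec("left", "projection", c(4, 4, 4), c(2, 2, 2), radius = 1.5)
  expect_equal(unname(roi_mean_diffusivities(tv, roi)["Dx"]), 5e-3)

  # radius 2 mm on the same grid: center + 6 face neighbours, verified
  # against explicit enumeration of voxel-center distances
  roi2 <- roi_spec("left", "projection", c(4, 4, 4), c(2, 2, 2), radius = 2)
  inside <- 0
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    if (sqrt(sum((c(dx, dy, dz) * 2)^2)) <= 2) inside <- inside + 1
  expect_equal(inside, 7)
  expect_equal(unname(roi_mean_diffusivities(tv, roi2)["Dx"]), 5e-3 / 7)

  # uniform field: exact block values
  tvu <- uniform_field(c(1.2e-3, 0.9e-3, 0.6e-3), c(8L, 8L, 8L), c(1, 1, 1))
  got <- roi_mean_diffusivities(tvu, roi_spec("left", "projection", c(4, 4, 4), c(1, 1, 1), 1.5))
  expect_equal(unname(got), c(1.2e-3, 0.9e-3, 0.6e-3))

  # empty sphere errors
  tvu$valid[] <- FALSE
  expect_error(roi_mean_diffusivities(tvu, roi_spec("left", "projection",
                                                    c(4, 4, 4), c(1, 1, 1), 1.5)),
               "no valid voxel")
})

test_that("subject_alps recovers the analytic phantom index and is scale invariant", {
  ph <- make_phantom(small_phantom_spec())
  tv <- fit_tensor(ph$dwi)
  res <- subject_alps(tv, band = ph$truth$band)
  expect_equal(unname(res$alps["bilateral"]), unname(ph$truth$alps["bilateral"]),
               tolerance = 1e-6)
  expect_equal(unname(res$alps["bilateral"]),
               mean(c(res$alps["left"], res$alps["right"])), tolerance = 1e-12)

  # doubling every diffusivity leaves the ratio unchanged
  ph2 <- make_phantom(small_phantom_spec(d_background = 1.6e-3,
                                         proj_d = 2 * c(1.2e-3, 0.8e-3, 1.6e-3),
                                         assoc_d = 2 * c(1.2e-3, 1.6e-3, 0.8e-3)))
  res2 <- subject_alps(fit_tensor(ph2$dwi), band = ph2$truth$band)
  expect_equal(unname(res2$alps["bilateral"]), unname(res$alps["bilateral"]),
               tolerance = 1e-6)
})

test_that("forcing ROIs to the truth centers reproduces the analytic index", {
  ph <- make_phantom(small_phantom_spec())
  tv <- fit_tensor(ph$dwi)
  # tensor-fit recovery on the noise-free phantom is essentially exact
  td <- ph$truth$tensor_diag
  rel_err <- max(abs(tv$D[, , , "xx"] - td$dxx) / td$dxx,
                 abs(tv$D[, , , "yy"] - td$dyy) / td$dyy,
                 abs(tv$D[, , , "zz"] - td$dzz) / td$dzz)
  expect_lt(rel_err, 1e-8)

  vox <- ph$truth$voxel
  rois <- list(
    left.projection = roi_spec("left", "projection", ph$truth$roi_centers$proj_left, vox),
    left.association = roi_spec("left", "association", ph$truth$roi_centers$assoc_left, vox),
    right.projection = roi_spec("right", "projection", ph$truth$roi_centers$proj_right, vox),
    right.association = roi_spec("right", "association", ph$truth$roi_centers$assoc_right, vox))
  res <- subject_alps(tv, rois = rois)
  expect_equal(unname(res$alps["bilateral"]), unname(ph$truth$alps["bilateral"]),
               tolerance = 1e-6)

  # an isotropic field with forced ROIs yields ALPS = 1
  tvu <- uniform_field(rep(0.8e-3, 3), c(32L, 32L, 8L), c(2, 2, 2))
  res_iso <- subject_alps(tvu, rois = rois)
  expect_equal(unname(res_iso$alps["bilateral"]), 1, tolerance = 1e-12)
})

test_that("ALPS results round-trip through JSON", {
  ph <- make_phantom(small_phantom_spec())
  res <- subject_alps(fit_tensor(ph$dwi), band = ph$truth$band)
  f <- tempfile(fileext = ".json")
  write_alps_json(res, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$alps$bilateral, unname(res$alps["bilateral"]), tolerance = 1e-12)
  expect_named(back$rois, names(res$rois))
})
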