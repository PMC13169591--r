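test_that("noise-free single-voxel tensors are recovered exactly", {
  D <- diag(c(1.2e-3, 0.8e-3, 0.6e-3))
  tv <- fit_tensor(single_voxel_dwi(D))
  expect_equal(unname(tv$D[1, 1, 1, "xx"]), 1.2e-3, tolerance = 1e-9)
  expect_equal(unname(tv$D[1, 1, 1, "yy"]), 0.8e-3, tolerance = 1e-9)
  expect_equal(unname(tv$D[1, 1, 1, "zz"]), 0.6e-3, tolerance = 1e-9)
  expect_equal(unname(tv$D[1, 1, 1, 4:6]), rep(0, 3), tolerance = 1e-12)

  # full symmetric tensor with off-diagonals, still exact
  R <- diag(3) + 0.1 * matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  Dfull <- R %*% diag(c(1.4e-3, 0.5e-3, 0.3e-3)) %*% t(R)
  tv2 <- fit_tensor(single_voxel_dwi(Dfull))
  got <- c(tv2$D[1, 1, 1, "xx"], tv2$D[1, 1, 1, "yy"], tv2$D[1, 1, 1, "zz"],
           tv2$D[1, 1, 1, "xy"], tv2$D[1, 1, 1, "xz"], tv2$D[1, 1, 1, "yz"])
  want <- c(Dfull[1, 1], Dfull[2, 2], Dfull[3, 3], Dfull[1, 2], Dfull[1, 3], Dfull[2, 3])
  expect_equal(unname(got), want, tolerance = 1e-9)
})

test_that("isotropic voxels have zero FA and equal scalar maps", {
  lam <- 0.9e-3
  tv <- fit_tensor(single_voxel_dwi(diag(rep(lam, 3))))
  sc <- tensor_scalars(tv)
  expect_equal(sc$fa[1, 1, 1], 0, tolerance = 1e-9)
  expect_equal(sc$md[1, 1, 1], lam, tolerance = 1e-9)
  expect_equal(sc$ad[1, 1, 1], lam, tolerance = 1e-9)
  expect_equal(sc$rd[1, 1, 1], lam, tolerance = 1e-9)
})

test_that("tensor scalars match the closed-form eigenvalue definitions", {
  # prolate tensor (1.4, 0.35, 0.35) x 1e-3: MD 0.7e-3, AD 1.4e-3, RD 0.35e-3,
  # FA = sqrt(3/2 * sum((l - MD)^2) / sum(l^2)) = sqrt(0.5) = 0.70711
  lam <- c(1.4, 0.35, 0.35) * 1e-3
  fa_oracle <- sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  expect_equal(fa_oracle, 0.70711, tolerance = 1e-4)
  tv <- fit_tensor(single_voxel_dwi(diag(lam)))
  sc <- tensor_scalars(tv)
  expect_equal(sc$md[1, 1, 1], 0.7e-3, tolerance = 1e-7)
  expect_equal(sc$ad[1, 1, 1], 1.4e-3, tolerance = 1e-7)
  expect_equal(sc$rd[1, 1, 1], 0.35e-3, tolerance = 1e-7)
  expect_equal(sc$fa[1, 1, 1], fa_oracle, tolerance = 1e-6)

  # homogeneity: scaling D leaves FA unchanged and scales MD/AD/RD
  tv2 <- fit_tensor(single_voxel_dwi(diag(2 * lam), bval = 500))
  sc2 <- tensor_scalars(tv2)
  expect_equal(sc2$fa[1, 1, 1], sc$fa[1, 1, 1], tolerance = 1e-6)
  expect_equal(sc2$md[1, 1, 1], 2 * sc$md[1, 1, 1], tolerance = 1e-9)
})

test_that("vectorized symmetric eigenvalues agree with base eigen", {
  set.seed(11)
  for (k in 1:50) {
    A <- matrix(rnorm(9), 3, 3)
    S <- (A + t(A)) / 2
    d6 <- matrix(c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3]), 1, 6)
    expect_equal(as.numeric(alpscog:::eig_sym3(d6)),
                 eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 tolerance = 1e-10)
  }
})

test_that("tensor error shrinks as noise goes to zero", {
  errs <- vapply(c(40, 10, 2.5), function(sig) {
    ph <- make_phantom(small_phantom_spec(noise = "gaussian", sigma = sig, seed = 5))
    tv <- fit_tensor(ph$dwi)
    td <- ph$truth$tensor_diag
    max(abs(tv$D[, , , "xx"] - td$dxx), abs(tv$D[, , , "yy"] - td$dyy),
        abs(tv$D[, , , "zz"] - td$dzz))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("rank-deficient direction sets are rejected", {
  # 8 in-plane directions cannot determine the z-components
  th <- seq(0, pi * 7 / 8, length.out = 8)
  g <- rbind(cos(th), sin(th), 0)
  sig <- array(c(1000, rep(500, 8)), c(1, 1, 1, 9))
  dwi <- dwi_volume(sig, c(2, 2, 2), c(0, rep(1000, 8)), cbind(0, g))
  expect_error(fit_tensor(dwi), "rank-deficient")
})

test_that("nonpositive b0 voxels are flagged invalid, not fatal", {
  ph <- make_phantom(small_phantom_spec())
  dat <- ph$dwi$data
  dat[1, 1, 1, 1] <- 0
  dwi <- dwi_volume(dat, ph$dwi$voxel, ph$dwi$bvals, ph$dwi$bvecs)
  tv <- fit_tensor(dwi)
  expect_false(tv$valid[1, 1, 1])
  expect_true(tv$valid[2, 1, 1])
})
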