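#' Fit diffusion tensors by log-linear least squares
#'
#' Estimates one symmetric diffusion tensor per voxel from the
#' monoexponential model ln S = ln S0 - b g' D g, by unweighted ordinary
#' least squares on the log signal. Voxels with non-positive b0 signal are
#' flagged invalid rather than aborting the fit. Voxels whose fitted tensor
#' has a negative eigenvalue are rebuilt from eigenvalues clamped to
#' \code{clamp_eps} and flagged.
#'
#' @param dwi a \code{\link{dwi_volume}}.
#' @param mask optional logical 3D array restricting the fit.
#' @param clamp_eps floor (mm^2/s) applied to negative eigenvalues.
#' @return An object of class \code{tensor_volume}: a 4D array \code{D}
#'   (x, y, z, component) with components xx, yy, zz, xy, xz, yz; a logical
#'   \code{valid} mask; a logical \code{clamped} flag map; voxel sizes.
#' @export
fit_tensor <- function(dwi, mask = NULL, clamp_eps = 1e-7) {
  stopifnot(inherits(dwi, "dwi_volume"))
  sh <- dim(dwi$data)[1:3]
  nvol <- dim(dwi$data)[4]
  if (nvol < 7L) stopf("at least 7 volumes (1 b0 + 6 directions) are required")
  b <- dwi$bvals
  g <- dwi$bvecs
  # design: ln S = X %*% (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
  X <- cbind(1,
             -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])
  if (qr(X[b > 0, -1, drop = FALSE])$rank < 6L)
    stopf("rank-deficient diffusion design: the b > 0 directions span fewer than 6 independent tensor components")

  if (is.null(mask)) mask <- array(TRUE, sh)
  nvox <- prod(sh)
  sig <- matrix(dwi$data, nrow = nvox, ncol = nvol)
  b0ok <- rowSums(sig[, b == 0, drop = FALSE] <= 0) == 0
  valid <- as.vector(mask) & b0ok
  sigv <- sig[valid, , drop = FALSE]
  sigv[sigv <= 0] <- min(sigv[sigv > 0], na.rm = TRUE) * 1e-3
  beta <- t(qr.coef(qr(X), t(log(sigv))))   # nvalid x 7

  D <- matrix(0, nvox, 6)
  D[valid, ] <- beta[, 2:7]
  ev <- eig_sym3(D[valid, , drop = FALSE])
  bad <- which(ev[, 3] < 0)
  clamped <- logical(nvox)
  if (length(bad)) {
    vi <- which(valid)[bad]
    for (k in seq_along(vi)) {
      i <- vi[k]
      M <- matrix(c(D[i, 1], D[i, 4], D[i, 5],
                    D[i, 4], D[i, 2], D[i, 6],
                    D[i, 5], D[i, 6], D[i, 3]), 3, 3)
      e <- eigen(M, symmetric = TRUE)
      lam <- pmax(e$values, clamp_eps)
      M2 <- e$vectors %*% diag(lam) %*% t(e$vectors)
      D[i, ] <- c(M2[1, 1], M2[2, 2], M2[3, 3], M2[1, 2], M2[1, 3], M2[2, 3])
    }
    clamped[vi] <- TRUE
  }
  structure(list(D = array(D, c(sh, 6L),
                           dimnames = list(NULL, NULL, NULL,
                                           c("xx", "yy", "zz", "xy", "xz", "yz"))),
                 valid = array(valid, sh), clamped = array(clamped, sh),
                 voxel = dwi$voxel), class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  sh <- dim(x$D)[1:3]
  cat(sprintf("Diffusion tensor volume: %d x %d x %d voxels (%d valid, %d clamped)\n",
              sh[1], sh[2], sh[3], sum(x$valid), sum(x$clamped)))
  invisible(x)
}

# Build a tensor_volume directly from diagonal diffusivity fields (used by
# phantom truth and tests).
tensor_volume_from_diag <- function(dxx, dyy, dzz, voxel) {
  sh <- dim(dxx)
  D <- array(0, c(sh, 6L), dimnames = list(NULL, NULL, NULL,
                                           c("xx", "yy", "zz", "xy", "xz", "yz")))
  D[, , , 1] <- dxx; D[, , , 2] <- dyy; D[, , , 3] <- dzz
  structure(list(D = D, valid = array(TRUE, sh), clamped = array(FALSE, sh),
                 voxel = voxel), class = "tensor_volume")
}

#' Scalar maps from a tensor volume
#'
#' Computes the standard rotation-invariant tensor scalars per valid voxel
#' from the sorted eigenvalues l1 >= l2 >= l3 (negative eigenvalues clamped
#' to zero for the scalar definitions): FA (normalized eigenvalue dispersion,
#' dimensionless in [0, 1]; 0 for an all-zero tensor), MD = (l1+l2+l3)/3,
#' AD = l1, RD = (l2+l3)/2, all in mm^2/s.
#'
#' @param tensors a \code{tensor_volume}.
#' @return list of four 3D arrays \code{fa}, \code{md}, \code{ad}, \code{rd}
#'   (NA outside the valid mask), each carrying a \code{quantity} attribute.
#' @export
tensor_scalars <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_volume"))
  sh <- dim(tensors$D)[1:3]
  nvox <- prod(sh)
  D <- matrix(tensors$D, nvox, 6)
  v <- as.vector(tensors$valid)
  ev <- eig_sym3(D[v, , drop = FALSE])
  ev <- pmax(ev, 0)
  md <- rowMeans(ev)
  ad <- ev[, 1]
  rd <- (ev[, 2] + ev[, 3]) / 2
  num <- (ev[, 1] - md)^2 + (ev[, 2] - md)^2 + (ev[, 3] - md)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  out <- lapply(list(fa = fa, md = md, ad = ad, rd = rd), function(val) {
    m <- rep(NA_real_, nvox)
    m[v] <- val
    array(m, sh)
  })
  attr(out$fa, "quantity") <- "FA (dimensionless)"
  attr(out$md, "quantity") <- "MD (mm^2/s)"
  attr(out$ad, "quantity") <- "AD (mm^2/s)"
  attr(out$rd, "quantity") <- "RD (mm^2/s)"
  out
}
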