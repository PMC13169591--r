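#' Specify a periventricular fiber-block DWI phantom
#'
#' Defines a rectangular phantom mimicking the axial band where ALPS ROIs are
#' placed: per hemisphere one projection-fiber block (superior-inferior
#' dominant diffusivity, Dz greatest) medially and one association-fiber
#' block (anterior-posterior dominant, Dy greatest) laterally, embedded in an
#' isotropic background. Left/right blocks are mirror images in x, so the
#' ground-truth ALPS index is identical in the two hemispheres and analytic:
#' mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc) from the prescribed
#' block diffusivities.
#'
#' @param shape integer length-3, grid size in voxels. Default 64 x 64 x 32.
#' @param voxel numeric length-3, voxel size in mm. Default 2.6 x 2.6 x 2.0,
#'   a typical clinical DTI grid.
#' @param d_background isotropic background diffusivity (mm^2/s).
#' @param proj_d,assoc_d length-3 diagonal diffusivities (Dx, Dy, Dz, mm^2/s)
#'   of the projection and association blocks. Projection blocks must have Dz
#'   strictly greatest, association blocks Dy strictly greatest.
#' @param proj_offset,assoc_offset distance (voxels) of block centers from
#'   the midline along x.
#' @param center_y,center_z in-plane anchor (voxel indices) of all blocks.
#' @param extent length-3 odd integers, block size in voxels.
#' @param bval diffusion weighting (s/mm^2) of the weighted volumes.
#' @param directions 3 x n matrix of unit gradient directions; default the
#'   packaged 64-direction table.
#' @param s0 non-diffusion-weighted signal amplitude (arbitrary units).
#' @param noise one of "none", "gaussian", "rician".
#' @param sigma noise standard deviation in signal units; the default
#'   \code{s0/30} gives a b0 signal-to-noise ratio of 30.
#' @param seed integer RNG seed used when noise is simulated.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 32L),
                         voxel = c(2.6, 2.6, 2.0),
                         d_background = 0.8e-3,
                         proj_d = c(1.2e-3, 0.8e-3, 1.6e-3),
                         assoc_d = c(1.2e-3, 1.6e-3, 0.8e-3),
                         proj_offset = 7L,
                         assoc_offset = 15L,
                         center_y = NULL,
                         center_z = NULL,
                         extent = c(5L, 5L, 5L),
                         bval = 1000,
                         directions = NULL,
                         s0 = 1000,
                         noise = c("rician", "gaussian", "none"),
                         sigma = s0 / 30,
                         seed = 1L) {
  noise <- match.arg(noise)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) stopf("`shape` must be 3 integers >= 8")
  if (shape[1] %% 2L != 0L) stopf("`shape[1]` must be even so the midline is between voxels")
  if (is.null(center_y)) center_y <- shape[2] %/% 2L
  if (is.null(center_z)) center_z <- shape[3] %/% 2L
  if (any(c(d_background, proj_d, assoc_d) <= 0))
    stopf("all diffusivities must be > 0")
  if (which.max(proj_d) != 3L || proj_d[3] <= max(proj_d[1:2]))
    stopf("projection block tensor is not superior-inferior dominant (Dz must be strictly greatest)")
  if (which.max(assoc_d) != 2L || assoc_d[2] <= max(assoc_d[c(1, 3)]))
    stopf("association block tensor is not anterior-posterior dominant (Dy must be strictly greatest)")
  if (any(extent %% 2L != 1L)) stopf("`extent` must be odd in each axis")
  if (is.null(directions)) directions <- gradient_table_64()
  half <- shape[1] %/% 2L
  centers_x <- c(proj_L = half - proj_offset + 1L, proj_R = half + proj_offset,
                 assoc_L = half - assoc_offset + 1L, assoc_R = half + assoc_offset)
  lo <- centers_x - extent[1] %/% 2L
  hi <- centers_x + extent[1] %/% 2L
  if (any(lo < 1L) || any(hi > shape[1]))
    stopf("block extents fall outside the grid in x; reduce offsets or extent")
  if (assoc_offset <= proj_offset + extent[1] - 1L)
    stopf("association blocks overlap projection blocks; increase `assoc_offset`")
  structure(list(shape = shape, voxel = as.numeric(voxel),
                 d_background = d_background, proj_d = proj_d, assoc_d = assoc_d,
                 proj_offset = as.integer(proj_offset),
                 assoc_offset = as.integer(assoc_offset),
                 center_y = as.integer(center_y), center_z = as.integer(center_z),
                 extent = as.integer(extent), bval = bval,
                 directions = directions, s0 = s0,
                 noise = noise, sigma = sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Block index ranges for one block centred at (cx, cy, cz).
block_index <- function(center, extent) {
  lapply(1:3, function(i) (center[i] - extent[i] %/% 2L):(center[i] + extent[i] %/% 2L))
}

#' Simulate a DWI phantom with analytic ground-truth ALPS
#'
#' Generates the diffusion-weighted signal of the phantom described by a
#' \code{\link{phantom_spec}} under the monoexponential tensor model
#' S(g, b) = S0 exp(-b g' D g), with optional Gaussian or Rician
#' (magnitude-MRI) noise, and returns both the data and a truth manifest:
#' the exact tensor field, the four ROI centers, the block diffusivity
#' triplets, the analytic ALPS index, and the (y, z) search band containing
#' the blocks.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with elements \code{dwi} (a \code{\link{dwi_volume}}) and
#'   \code{truth} (class \code{phantom_truth}).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape
  dxx <- array(spec$d_background, sh)
  dyy <- array(spec$d_background, sh)
  dzz <- array(spec$d_background, sh)

  half <- sh[1] %/% 2L
  centers <- list(
    proj_left  = c(half - spec$proj_offset + 1L, spec$center_y, spec$center_z),
    proj_right = c(half + spec$proj_offset, spec$center_y, spec$center_z),
    assoc_left  = c(half - spec$assoc_offset + 1L, spec$center_y, spec$center_z),
    assoc_right = c(half + spec$assoc_offset, spec$center_y, spec$center_z))
  dvals <- list(proj_left = spec$proj_d, proj_right = spec$proj_d,
                assoc_left = spec$assoc_d, assoc_right = spec$assoc_d)
  for (nm in names(centers)) {
    ix <- block_index(centers[[nm]], spec$extent)
    if (any(vapply(1:3, function(i) ix[[i]][1] < 1L || max(ix[[i]]) > sh[i], logical(1))))
      stopf("block '%s' falls outside the grid", nm)
    dxx[ix[[1]], ix[[2]], ix[[3]]] <- dvals[[nm]][1]
    dyy[ix[[1]], ix[[2]], ix[[3]]] <- dvals[[nm]][2]
    dzz[ix[[1]], ix[[2]], ix[[3]]] <- dvals[[nm]][3]
  }

  g <- spec$directions
  nvol <- ncol(g) + 1L
  bvals <- c(0, rep(spec$bval, ncol(g)))
  bvecs <- cbind(c(0, 0, 0), g)
  sig <- array(0, c(sh, nvol))
  sig[, , , 1] <- spec$s0
  for (j in seq_len(ncol(g))) {
    adc <- g[1, j]^2 * dxx + g[2, j]^2 * dyy + g[3, j]^2 * dzz
    sig[, , , j + 1L] <- spec$s0 * exp(-spec$bval * adc)
  }
  if (spec$noise != "none" && spec$sigma > 0) {
    sig <- with_seed(spec$seed, {
      n <- length(sig)
      if (spec$noise == "gaussian") {
        pmax(sig + rnorm(n, 0, spec$sigma), 0)
      } else {
        sqrt((sig + rnorm(n, 0, spec$sigma))^2 + rnorm(n, 0, spec$sigma)^2)
      }
    })
    dim(sig) <- c(sh, nvol)
  }

  alps_true <- alps_index(spec$proj_d, spec$assoc_d)
  ext_half <- spec$extent %/% 2L
  truth <- structure(list(
    tensor_diag = list(dxx = dxx, dyy = dyy, dzz = dzz),
    roi_centers = centers,
    roi_d = list(proj = spec$proj_d, assoc = spec$assoc_d),
    alps = c(left = alps_true, right = alps_true, bilateral = alps_true),
    band = list(y = (spec$center_y - ext_half[2]):(spec$center_y + ext_half[2]),
                z = (spec$center_z - ext_half[3]):(spec$center_z + ext_half[3])),
    voxel = spec$voxel), class = "phantom_truth")
  list(dwi = dwi_volume(sig, spec$voxel, bvals, bvecs), truth = truth)
}

#' Simulate a lesion mask with known component count and volume
#'
#' Rasterizes spheres (centers in voxel coordinates, radii in mm) into a
#' binary 3D mask and reports the ground truth: the number of 26-connected
#' components (overlapping spheres merge) and the total volume in ml.
#'
#' @param shape integer length-3 grid size (voxels).
#' @param voxel numeric length-3 voxel size (mm).
#' @param lesions list of \code{list(center = c(x, y, z), radius = mm)}.
#' @return list with \code{mask} (logical array), \code{truth} (list with
#'   \code{count} and \code{volume_ml}).
#' @export
make_lesion_volume <- function(shape, voxel, lesions = list()) {
  shape <- as.integer(shape)
  mask <- array(FALSE, shape)
  cx <- (seq_len(shape[1]) - 1) * voxel[1]
  cy <- (seq_len(shape[2]) - 1) * voxel[2]
  cz <- (seq_len(shape[3]) - 1) * voxel[3]
  for (les in lesions) {
    ctr <- (les$center - 1) * voxel
    r <- les$radius
    xr <- which(abs(cx - ctr[1]) <= r)
    yr <- which(abs(cy - ctr[2]) <= r)
    zr <- which(abs(cz - ctr[3]) <= r)
    if (!length(xr) || !length(yr) || !length(zr)) next
    if (any(les$center < 1) || any(les$center > shape))
      stopf("lesion center outside the grid")
    d2 <- outer(outer((cx[xr] - ctr[1])^2, (cy[yr] - ctr[2])^2, "+"),
                (cz[zr] - ctr[3])^2, "+")
    mask[xr, yr, zr] <- mask[xr, yr, zr] | (d2 <= r^2)
  }
  labels <- label_components_26(mask)
  list(mask = mask,
       truth = list(count = max(labels),
                    volume_ml = sum(mask) * prod(voxel) / 1000))
}
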