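#' Diffusion-weighted volume container
#'
#' Bundles a 4D diffusion-weighted signal array with its acquisition scheme.
#' The axis convention is fixed throughout the package: x = left-right,
#' y = anterior-posterior, z = superior-inferior, so the tensor diagonal in
#' these axes carries the directional diffusivities the ALPS index is built
#' from.
#'
#' @param data 4D numeric array (x, y, z, volume), non-negative signal.
#' @param voxel length-3 numeric, voxel size in mm per axis.
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x nvol numeric matrix of gradient directions; columns for
#'   b > 0 must have unit norm (within 1e-6), b = 0 columns may be zero.
#' @return An object of class \code{dwi_volume}.
#' @export
dwi_volume <- function(data, voxel, bvals, bvecs) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stopf("`data` must be a 4D array (x, y, z, volume)")
  nvol <- dim(data)[4]
  if (length(bvals) != nvol || ncol(bvecs) != nvol)
    stopf("number of b-values (%d) and directions (%d) must equal the number of volumes (%d)",
          length(bvals), ncol(bvecs), nvol)
  if (nrow(bvecs) != 3L) stopf("`bvecs` must be a 3 x nvol matrix")
  if (length(voxel) != 3L || any(voxel <= 0)) stopf("`voxel` must be 3 positive mm sizes")
  if (any(data < 0)) stopf("signals must be non-negative")
  if (!any(bvals == 0)) stopf("at least one b = 0 volume is required")
  nz <- which(bvals > 0)
  nrms <- sqrt(colSums(bvecs[, nz, drop = FALSE]^2))
  if (any(abs(nrms - 1) > 1e-6))
    stopf("gradient directions for b > 0 must be unit vectors (max |norm-1| = %.2e)",
          max(abs(nrms - 1)))
  structure(list(data = data, voxel = as.numeric(voxel),
                 bvals = as.numeric(bvals), bvecs = bvecs,
                 axes = c(x = "left-right", y = "anterior-posterior",
                          z = "superior-inferior")),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI volume: %d x %d x %d voxels, %d volumes\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size: %s mm\n", paste(format(x$voxel), collapse = " x ")))
  cat(sprintf("  b-values: %s (s/mm^2); %d diffusion directions\n",
              paste(unique(x$bvals), collapse = ", "), sum(x$bvals > 0)))
  invisible(x)
}

#' Built-in 64-direction gradient table
#'
#' A fixed, evenly spread set of 64 unit gradient directions (hemispheric
#' Fibonacci-spiral construction), shipped as a plain-text fixture. Used as
#' the package default acquisition scheme for simulated DWI.
#'
#' @return 3 x 64 numeric matrix of unit column vectors.
#' @export
gradient_table_64 <- function() {
  path <- system.file("extdata", "grad64.bvec", package = "alpscog", mustWork = TRUE)
  g <- as.matrix(read.table(path))
  dimnames(g) <- NULL
  sweep(g, 2, sqrt(colSums(g^2)), "/")
}

#' Read a DWI series from NIfTI plus FSL-style bval/bvec files
#'
#' @param nifti path to a 4D NIfTI-1 file.
#' @param bval,bvec paths to FSL-style text files (one row of b-values;
#'   three rows of direction components).
#' @return A \code{\link{dwi_volume}}.
#' @export
read_dwi <- function(nifti, bval, bvec) {
  img <- RNifti::readNifti(nifti)
  bvals <- scan(bval, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec))
  dimnames(bvecs) <- NULL
  vox <- RNifti::pixdim(img)[1:3]
  dwi_volume(unclass(img)[, , , , drop = FALSE], vox, bvals, bvecs)
}

#' Write a DWI series as NIfTI plus FSL-style bval/bvec files
#'
#' @param dwi a \code{\link{dwi_volume}}.
#' @param nifti,bval,bvec output paths.
#' @return Invisibly, the NIfTI path.
#' @export
write_dwi <- function(dwi, nifti, bval, bvec) {
  stopifnot(inherits(dwi, "dwi_volume"))
  img <- RNifti::asNifti(dwi$data)
  RNifti::pixdim(img) <- c(dwi$voxel, 1)
  RNifti::writeNifti(img, nifti, datatype = "double")
  writeLines(paste(format(dwi$bvals, scientific = FALSE, trim = TRUE), collapse = " "), bval)
  write.table(format(dwi$bvecs, digits = 10, scientific = FALSE),
              bvec, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(nifti)
}

#' Read a 3D NIfTI mask as a logical array
#' @param path NIfTI file path.
#' @return list with \code{mask} (logical 3D array) and \code{voxel} (mm).
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  list(mask = unclass(img) != 0, voxel = RNifti::pixdim(img)[1:3])
}
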