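#' Directional-diffusivity profile along the left-right axis
#'
#' For a fixed (y, z) anchor, sweeps a circle of radius \code{circle_radius}
#' (mm, in the axial plane at slice z) along x and averages the tensor
#' diagonal within each circle. The three resulting curves are the
#' color-map profiles used to localize ALPS ROIs: Dxx (red, left-right),
#' Dyy (green, anterior-posterior), Dzz (blue, superior-inferior). The
#' projection-fiber ROI sits at the blue-curve peak and the
#' association-fiber ROI at the green-curve peak.
#'
#' @param tensors a \code{tensor_volume}.
#' @param y,z anchor voxel indices.
#' @param circle_radius circle radius in mm (default 5).
#' @return A data frame of class \code{directional_profile} with columns
#'   \code{x_voxel}, \code{x_mm}, \code{dxx}, \code{dyy}, \code{dzz}
#'   (NA where the circle holds no valid voxel).
#' @export
directional_profile <- function(tensors, y, z, circle_radius = 5) {
  stopifnot(inherits(tensors, "tensor_volume"))
  sh <- dim(tensors$D)[1:3]
  if (y < 1 || y > sh[2] || z < 1 || z > sh[3]) stopf("(y, z) anchor out of bounds")
  if (circle_radius <= 0) stopf("`circle_radius` must be > 0")
  vx <- tensors$voxel[1]; vy <- tensors$voxel[2]
  dxs <- seq(-floor(circle_radius / vx), floor(circle_radius / vx))
  dys <- seq(-floor(circle_radius / vy), floor(circle_radius / vy))
  disc <- expand.grid(dx = dxs, dy = dys)
  disc <- disc[(disc$dx * vx)^2 + (disc$dy * vy)^2 <= circle_radius^2, ]
  out <- matrix(NA_real_, sh[1], 3)
  for (x0 in seq_len(sh[1])) {
    xs <- x0 + disc$dx
    ys <- y + disc$dy
    keep <- xs >= 1 & xs <= sh[1] & ys >= 1 & ys <= sh[2]
    if (!any(keep)) next
    idx <- cbind(xs[keep], ys[keep], z)
    ok <- tensors$valid[idx]
    if (!any(ok)) next
    idx <- idx[ok, , drop = FALSE]
    out[x0, 1] <- mean(tensors$D[cbind(idx, 1L)])
    out[x0, 2] <- mean(tensors$D[cbind(idx, 2L)])
    out[x0, 3] <- mean(tensors$D[cbind(idx, 3L)])
  }
  structure(data.frame(x_voxel = seq_len(sh[1]),
                       x_mm = (seq_len(sh[1]) - 1) * vx,
                       dxx = out[, 1], dyy = out[, 2], dzz = out[, 3]),
            anchor = c(y = y, z = z), circle_radius = circle_radius,
            class = c("directional_profile", "data.frame"))
}

#' ALPS ROI specification
#'
#' @param hemisphere "left" or "right".
#' @param fiber "projection" or "association".
#' @param center_voxel length-3 voxel coordinates of the sphere center.
#' @param voxel voxel size (mm) used to derive mm coordinates.
#' @param radius sphere radius in mm (default 1.5, i.e. a 3 mm sphere).
#' @return list of class \code{roi_spec}.
#' @export
roi_spec <- function(hemisphere, fiber, center_voxel, voxel, radius = 1.5) {
  if (radius <= 0) stopf("ROI radius must be > 0")
  structure(list(hemisphere = match.arg(hemisphere, c("left", "right")),
                 fiber = match.arg(fiber, c("projection", "association")),
                 center_voxel = as.numeric(center_voxel),
                 center_mm = (as.numeric(center_voxel) - 1) * voxel,
                 radius = radius), class = "roi_spec")
}

# Deterministic peak pick: max value; exact plateaus broken by distance to
# `prefer_x` (band center of the hemisphere), then by index.
pick_peak <- function(values, xs, prefer_x) {
  ok <- which(!is.na(values))
  if (!length(ok)) return(NULL)
  mx <- max(values[ok])
  cand <- ok[values[ok] >= mx - 1e-15]
  cand[order(abs(xs[cand] - prefer_x), cand)][1]
}

#' Automatically localize the four ALPS ROIs
#'
#' Scans the candidate (y, z) anchors of \code{band}, builds the directional
#' profile at each, and places, per hemisphere, the projection ROI at the
#' highest blue-curve (Dzz) value and the association ROI at the highest
#' green-curve (Dyy) value across the whole candidate grid. A peak must
#' exceed the hemisphere's median curve level by the factor
#' \code{min_prominence}, otherwise localization fails for that
#' hemisphere/fiber class. Exact plateau ties are broken deterministically
#' toward the hemisphere center. Projection and association ROIs in one
#' hemisphere must not overlap.
#'
#' @param tensors a \code{tensor_volume}.
#' @param fa optional FA map (3D array) used only for ROI QC.
#' @param band list with integer vectors \code{y} and \code{z}: the search
#'   anchors. For phantoms use the truth manifest's band; for real data a
#'   user-supplied periventricular band.
#' @param circle_radius profile circle radius, mm.
#' @param roi_radius ROI sphere radius, mm.
#' @param min_prominence minimum peak / median-background ratio.
#' @param midline x midline in voxel coordinates; default (nx + 1) / 2.
#' @param x_margin voxels next to the midline excluded from the search.
#' @return list of 4 \code{roi_spec} (left/right x projection/association),
#'   with a \code{qc} attribute (peak prominence and FA at each center).
#' @export
locate_alps_rois <- function(tensors, fa = NULL, band,
                             circle_radius = 5, roi_radius = 1.5,
                             min_prominence = 1.1, midline = NULL,
                             x_margin = 2L) {
  stopifnot(inherits(tensors, "tensor_volume"))
  sh <- dim(tensors$D)[1:3]
  if (!length(band$y) || !length(band$z)) stopf("search band is empty")
  if (any(band$y < 1 | band$y > sh[2]) || any(band$z < 1 | band$z > sh[3]))
    stopf("search band out of bounds")
  if (is.null(midline)) midline <- (sh[1] + 1) / 2
  sides <- list(left = which(seq_len(sh[1]) < midline - x_margin),
                right = which(seq_len(sh[1]) > midline + x_margin))
  if (!length(sides$left) || !length(sides$right)) stopf("midline/margin leaves an empty hemisphere")

  # anchors visited nearest-to-band-center first so that exact plateau ties
  # across anchors resolve toward the band center (first hit wins below)
  anchors <- expand.grid(y = band$y, z = band$z)
  ctr_band <- c(mean(range(band$y)), mean(range(band$z)))
  anchors <- anchors[order((anchors$y - ctr_band[1])^2 + (anchors$z - ctr_band[2])^2,
                           anchors$y, anchors$z), , drop = FALSE]

  best <- list()  # keyed by "left.projection" etc.
  for (k in seq_len(nrow(anchors))) {
    yy <- anchors$y[k]; zz <- anchors$z[k]
    prof <- directional_profile(tensors, yy, zz, circle_radius)
    for (side in c("left", "right")) {
      xs <- sides[[side]]
      for (fib in c("projection", "association")) {
        curve <- if (fib == "projection") prof$dzz[xs] else prof$dyy[xs]
        i <- pick_peak(curve, xs, mean(range(xs)))
        if (is.null(i)) next
        val <- curve[i]
        bg <- stats::median(curve, na.rm = TRUE)
        prom <- if (bg > 0) val / bg else Inf
        key <- paste(side, fib, sep = ".")
        if (is.null(best[[key]]) || val > best[[key]]$value + 1e-15) {
          best[[key]] <- list(value = val, prominence = prom,
                              center = c(xs[i], yy, zz))
        }
      }
    }
  }

  failed <- character(0)
  for (side in c("left", "right")) for (fib in c("projection", "association")) {
    key <- paste(side, fib, sep = ".")
    if (is.null(best[[key]]) || best[[key]]$prominence < min_prominence)
      failed <- c(failed, key)
  }
  if (length(failed))
    stopf("no prominent diffusivity peak for: %s (min_prominence = %g)",
          paste(failed, collapse = ", "), min_prominence)

  rois <- list()
  qc <- list()
  for (side in c("left", "right")) {
    pk <- best[[paste(side, "projection", sep = ".")]]
    ak <- best[[paste(side, "association", sep = ".")]]
    sep_mm <- sqrt(sum(((pk$center - ak$center) * tensors$voxel)^2))
    if (sep_mm < 2 * roi_radius)
      stopf("projection and association ROIs overlap in the %s hemisphere (%.1f mm apart)",
            side, sep_mm)
    for (fib in c("projection", "association")) {
      b <- if (fib == "projection") pk else ak
      key <- paste(side, fib, sep = ".")
      rois[[key]] <- roi_spec(side, fib, b$center, tensors$voxel, roi_radius)
      qc[[key]] <- c(prominence = b$prominence,
                     fa_at_center = if (is.null(fa)) NA_real_ else
                       fa[matrix(b$center, 1)])
    }
  }
  structure(rois, qc = qc)
}

#' Mean directional diffusivities inside a spherical ROI
#'
#' Averages Dxx, Dyy, Dzz over valid voxels whose centers lie within the
#' ROI radius of the ROI center, with distances measured in mm so
#' anisotropic voxels are handled correctly. Note that on coarse grids a
#' 1.5 mm radius admits only the center voxel.
#'
#' @param tensors a \code{tensor_volume}.
#' @param roi a \code{roi_spec}.
#' @return named numeric (Dx, Dy, Dz) in mm^2/s.
#' @export
roi_mean_diffusivities <- function(tensors, roi) {
  stopifnot(inherits(tensors, "tensor_volume"), inherits(roi, "roi_spec"))
  sh <- dim(tensors$D)[1:3]
  vox <- tensors$voxel
  ctr <- roi$center_voxel
  if (any(ctr < 1) || any(ctr > sh)) stopf("ROI center outside the volume")
  rng <- lapply(1:3, function(i) {
    lo <- max(1L, floor(ctr[i] - roi$radius / vox[i]))
    hi <- min(sh[i], ceiling(ctr[i] + roi$radius / vox[i]))
    lo:hi
  })
  grid <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  d2 <- ((grid[, 1] - ctr[1]) * vox[1])^2 + ((grid[, 2] - ctr[2]) * vox[2])^2 +
    ((grid[, 3] - ctr[3]) * vox[3])^2
  grid <- grid[d2 <= roi$radius^2, , drop = FALSE]
  grid <- grid[tensors$valid[grid], , drop = FALSE]
  if (!nrow(grid)) stopf("ROI sphere contains no valid voxel")
  c(Dx = mean(tensors$D[cbind(grid, 1L)]),
    Dy = mean(tensors$D[cbind(grid, 2L)]),
    Dz = mean(tensors$D[cbind(grid, 3L)]))
}

#' The ALPS index
#'
#' ALPS = mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc): the ratio of
#' diffusivity along the perivascular (left-right) direction to diffusivity
#' perpendicular to both fiber populations. Dz_proj and Dy_assoc are carried
#' in results for completeness but do not enter the formula.
#'
#' @param proj named or positional numeric (Dx, Dy, Dz) of the
#'   projection-fiber ROI, mm^2/s.
#' @param assoc same for the association-fiber ROI.
#' @return dimensionless scalar > 0.
#' @export
alps_index <- function(proj, assoc) {
  if (length(proj) != 3L || length(assoc) != 3L)
    stopf("`proj` and `assoc` must each hold (Dx, Dy, Dz)")
  if (any(c(proj[1], assoc[1]) <= 0)) stopf("numerator diffusivities must be > 0")
  if (proj[2] <= 0 || assoc[3] <= 0) stopf("denominator diffusivities (Dy_proj, Dz_assoc) must be > 0")
  as.numeric(mean(c(proj[1], assoc[1])) / mean(c(proj[2], assoc[3])))
}

#' Compute a subject's ALPS index with automated ROI placement
#'
#' End-to-end subject-level computation: locates the four ROIs on the
#' directional profile curves (unless \code{rois} is supplied), extracts the
#' per-ROI mean diffusivities, and evaluates the ALPS index per hemisphere;
#' the bilateral index is the arithmetic mean of the two hemispheres.
#'
#' @inheritParams locate_alps_rois
#' @param rois optional list of 4 \code{roi_spec} (keys
#'   \code{left.projection}, \code{left.association}, \code{right.projection},
#'   \code{right.association}) to bypass automatic localization.
#' @return object of class \code{alps_result}: per-hemisphere diffusivity
#'   sextets, left/right/bilateral ALPS, the ROIs and their QC metrics.
#' @export
subject_alps <- function(tensors, fa = NULL, band = NULL,
                         circle_radius = 5, roi_radius = 1.5,
                         min_prominence = 1.1, midline = NULL,
                         x_margin = 2L, rois = NULL) {
  if (is.null(rois)) {
    if (is.null(band)) stopf("either `band` or `rois` must be supplied")
    rois <- locate_alps_rois(tensors, fa, band, circle_radius, roi_radius,
                             min_prominence, midline, x_margin)
  }
  need <- c("left.projection", "left.association", "right.projection", "right.association")
  if (!all(need %in% names(rois)))
    stopf("`rois` must contain: %s", paste(need, collapse = ", "))
  hemi <- list()
  for (side in c("left", "right")) {
    dp <- roi_mean_diffusivities(tensors, rois[[paste0(side, ".projection")]])
    da <- roi_mean_diffusivities(tensors, rois[[paste0(side, ".association")]])
    hemi[[side]] <- list(proj = dp, assoc = da, alps = alps_index(dp, da))
  }
  structure(list(
    left = hemi$left, right = hemi$right,
    alps = c(left = hemi$left$alps, right = hemi$right$alps,
             bilateral = mean(c(hemi$left$alps, hemi$right$alps))),
    rois = rois, qc = attr(rois, "qc")), class = "alps_result")
}

#' @export
print.alps_result <- function(x, digits = 4, ...) {
  cat("ALPS index (diffusion along the perivascular space)\n")
  for (side in c("left", "right")) {
    h <- x[[side]]
    cat(sprintf("  %-5s proj (Dx,Dy,Dz) = (%s) x1e-3; assoc = (%s) x1e-3; ALPS = %.*f\n",
                side,
                paste(format(round(h$proj * 1e3, digits)), collapse = ", "),
                paste(format(round(h$assoc * 1e3, digits)), collapse = ", "),
                digits, h$alps))
  }
  cat(sprintf("  bilateral ALPS = %.*f\n", digits, x$alps["bilateral"]))
  invisible(x)
}

#' Write an ALPS result as JSON
#' @param x an \code{alps_result}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_alps_json <- function(x, path) {
  stopifnot(inherits(x, "alps_result"))
  out <- list(
    alps = as.list(x$alps),
    left = list(proj = as.list(x$left$proj), assoc = as.list(x$left$assoc)),
    right = list(proj = as.list(x$right$proj), assoc = as.list(x$right$assoc)),
    rois = lapply(x$rois, function(r)
      list(hemisphere = r$hemisphere, fiber = r$fiber,
           center_voxel = r$center_voxel, center_mm = r$center_mm,
           radius_mm = r$radius)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
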