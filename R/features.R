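#' TIV-normalized tissue volumes
#'
#' Expresses CSF, gray-matter and white-matter volumes as percentages of
#' total intracranial volume, correcting for head size: nX = 100 * X / TIV.
#' A sanity bound CSFV + GMV + WMV <= 1.05 * TIV is checked and flagged (not
#' fatal) since segmentation volumes can slightly overshoot TIV.
#'
#' @param csfv,gmv,wmv,tiv volumes in ml; \code{tiv} must be positive.
#' @return named numeric (nCSFV, nGMV, nWMV) in percent, with a logical
#'   attribute \code{volume_sum_flag} set when the sanity bound is violated.
#' @export
normalize_volumes <- function(csfv, gmv, wmv, tiv) {
  if (!is_scalar_number(tiv) || tiv <= 0) stopf("`tiv` must be a positive number (ml)")
  if (any(c(csfv, gmv, wmv) <= 0)) stopf("tissue volumes must be positive (ml)")
  out <- 100 * c(nCSFV = csfv, nGMV = gmv, nWMV = wmv) / tiv
  attr(out, "volume_sum_flag") <- (csfv + gmv + wmv) > 1.05 * tiv
  out
}

#' White-matter-mask diffusion summaries
#'
#' Means of FA, MD, AD and RD over the white-matter mask defined by
#' FA > \code{fa_threshold}, a global white-matter diffusion summary. MD, AD
#' and RD are reported in 1e-3 mm^2/s to match the conventional reporting
#' scale.
#'
#' @param fa,md,ad,rd co-registered 3D scalar maps (FA dimensionless, the
#'   rest in mm^2/s), e.g. from \code{\link{tensor_scalars}}.
#' @param fa_threshold FA threshold in (0, 1); default 0.2.
#' @return named numeric (FA, MD, AD, RD); diffusivities in 1e-3 mm^2/s.
#' @export
wm_mask_stats <- function(fa, md, ad, rd, fa_threshold = 0.2) {
  if (fa_threshold < 0 || fa_threshold >= 1) stopf("`fa_threshold` must be in [0, 1)")
  if (!all(dim(fa) == dim(md)) || !all(dim(fa) == dim(ad)) || !all(dim(fa) == dim(rd)))
    stopf("scalar maps must share one grid")
  sel <- !is.na(fa) & fa > fa_threshold
  if (!any(sel)) stopf("white-matter mask FA > %g is empty", fa_threshold)
  c(FA = mean(fa[sel]),
    MD = mean(md[sel]) * 1e3,
    AD = mean(ad[sel]) * 1e3,
    RD = mean(rd[sel]) * 1e3)
}

#' Lesion burden metrics from a binary lesion mask
#'
#' WMLV is the total lesion volume (voxel count times voxel volume, in ml);
#' WMLN is the number of 26-connected lesion components (diagonal contacts
#' merge, matching common lesion-counting behavior).
#'
#' @param mask binary/logical 3D array.
#' @param voxel length-3 voxel size in mm.
#' @return named numeric (WMLV in ml, WMLN count).
#' @export
lesion_metrics <- function(mask, voxel) {
  if (!is.array(mask) || length(dim(mask)) != 3L) stopf("`mask` must be a 3D array")
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1, TRUE, FALSE))) stopf("`mask` must be binary")
  m <- array(as.logical(mask), dim(mask))
  labels <- label_components_26(m)
  c(WMLV = sum(m) * prod(voxel) / 1000, WMLN = max(labels))
}
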