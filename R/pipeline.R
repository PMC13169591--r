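## Orchestration: subject-level feature extraction and cohort-level analysis.

.imaging_vars <- c("alps", "ncsfv", "ngmv", "nwmv", "tiv", "cth",
                   "fa", "md", "ad", "rd", "wmlv", "wmln")
.clinical_vars <- c("age", "education", "duration", "edss")

#' Extract all imaging features for one subject
#'
#' Chains the subject-level computations: tensor fit on the DWI, scalar
#' maps, automated ALPS (with the supplied search band), white-matter-mask
#' diffusion summaries, lesion metrics from an optional lesion mask, and
#' TIV-normalized volumes from optional precomputed volumetrics. A stage
#' failure marks the subject failed with a stage-labelled reason instead of
#' aborting; optional inputs that are absent leave their fields NA.
#'
#' @param entry list with elements \code{dwi} (a \code{\link{dwi_volume}}),
#'   \code{band} (search band for ROI localization), and optionally
#'   \code{lesion_mask} (logical 3D array), \code{volumetrics} (list with
#'   csfv, gmv, wmv, tiv, cth in ml / mm), \code{id}.
#' @param roi_radius,circle_radius,min_prominence ALPS parameters, see
#'   \code{\link{locate_alps_rois}}.
#' @param fa_threshold white-matter mask threshold for the diffusion
#'   summaries.
#' @return list of class \code{subject_record}: feature fields, \code{alps_result},
#'   \code{failed} (logical) and \code{failure} (stage-labelled message).
#' @export
run_subject <- function(entry, roi_radius = 1.5, circle_radius = 5,
                        min_prominence = 1.1, fa_threshold = 0.2) {
  rec <- list(id = if (is.null(entry$id)) NA_character_ else entry$id,
              alps = NA_real_, fa = NA_real_, md = NA_real_, ad = NA_real_,
              rd = NA_real_, wmlv = NA_real_, wmln = NA_real_,
              ncsfv = NA_real_, ngmv = NA_real_, nwmv = NA_real_,
              tiv = NA_real_, cth = NA_real_,
              failed = FALSE, failure = NA_character_)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rec$failed <<- TRUE
      rec$failure <<- sprintf("[%s] %s", name, conditionMessage(e))
      NULL
    })
  }
  tensors <- stage("tensor_fit", fit_tensor(entry$dwi))
  if (!is.null(tensors)) {
    sc <- stage("scalar_maps", tensor_scalars(tensors))
    if (!is.null(sc)) {
      wm <- stage("wm_stats", wm_mask_stats(sc$fa, sc$md, sc$ad, sc$rd, fa_threshold))
      if (!is.null(wm)) {
        rec$fa <- wm[["FA"]]; rec$md <- wm[["MD"]]
        rec$ad <- wm[["AD"]]; rec$rd <- wm[["RD"]]
      }
      ar <- stage("alps", subject_alps(tensors, sc$fa, band = entry$band,
                                       circle_radius = circle_radius,
                                       roi_radius = roi_radius,
                                       min_prominence = min_prominence))
      if (!is.null(ar)) {
        rec$alps <- unname(ar$alps["bilateral"])
        rec$alps_result <- ar
      }
    }
  }
  if (!is.null(entry$lesion_mask)) {
    lm_ <- stage("lesions", lesion_metrics(entry$lesion_mask,
                                           if (is.null(entry$lesion_voxel))
                                             entry$dwi$voxel else entry$lesion_voxel))
    if (!is.null(lm_)) { rec$wmlv <- lm_[["WMLV"]]; rec$wmln <- lm_[["WMLN"]] }
  }
  if (!is.null(entry$volumetrics)) {
    v <- entry$volumetrics
    nv <- stage("volumetrics", normalize_volumes(v$csfv, v$gmv, v$wmv, v$tiv))
    if (!is.null(nv)) {
      rec$ncsfv <- nv[["nCSFV"]]; rec$ngmv <- nv[["nGMV"]]; rec$nwmv <- nv[["nWMV"]]
      rec$tiv <- v$tiv
      if (!is.null(v$cth)) rec$cth <- v$cth
    }
  }
  structure(rec, class = "subject_record")
}

#' Run the full cohort-level statistical pipeline
#'
#' Executes, on a populated cohort table: HC-referenced Z-scoring of all
#' cognitive tests; BICAMS impairment classification; RRMS-vs-HC group
#' comparisons of imaging and cognitive variables with FDR per family;
#' impaired-vs-preserved subgroup comparisons; the Spearman screen of
#' imaging/clinical variables against cognitive Z-scores; covariate-adjusted
#' linear models per cognitive outcome restricted to screen-significant
#' predictors; univariate candidate screening plus backward stepwise
#' logistic regression for impairment; and ROC analysis of the retained
#' predictors. The run is fully deterministic given the table.
#'
#' @param table cohort data.frame (see \code{\link{make_cohort}} for the
#'   column dictionary).
#' @param screen_alpha significance level for both the Spearman screen and
#'   the univariate candidate screen.
#' @param removal_alpha stepwise stay threshold.
#' @param impairment_outcome column used as the stepwise outcome; default
#'   the BICAMS classification computed from the Z-scores
#'   (\code{"impaired"}), alternatively e.g. a simulated latent outcome.
#' @return object of class \code{cohort_report}.
#' @export
run_cohort <- function(table, screen_alpha = 0.05, removal_alpha = 0.05,
                       impairment_outcome = "impaired") {
  need <- c("group", "age", "sex", "education")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("cohort table lacks required column(s): %s",
                          paste(miss, collapse = ", "))
  zs <- z_score_cohort(table)
  tab <- zs$table
  tests <- names(zs$models)
  zcols <- paste0("z_", tests)

  imaging <- intersect(.imaging_vars, names(tab))
  run_family <- function(vars, grouping, data, family) {
    res <- lapply(vars, function(v)
      tryCatch(compare_groups(data, v, grouping, family = family,
                              n_total = nrow(tab)),
               error = function(e) NULL))
    res <- Filter(Negate(is.null), res)
    if (!length(res)) return(NULL)
    q <- as.numeric(fdr_bh(vapply(res, `[[`, numeric(1), "p"), family = family))
    for (i in seq_along(res)) res[[i]]$q <- q[i]
    names(res) <- vapply(res, `[[`, character(1), "variable")
    res
  }
  table1 <- run_family(c("age", "education", imaging), "group", tab, "table1_group")
  table2 <- run_family(tests, "group", tab, "table2_cognitive")

  rrms <- tab[tab$group == "RRMS", , drop = FALSE]
  subgroup <- NULL
  if (impairment_outcome %in% names(rrms)) {
    out_v <- rrms[[impairment_outcome]]
    lv <- unique(stats::na.omit(out_v))
    if (length(lv) == 2 && all(table(out_v) >= 3)) {
      subgroup <- run_family(c("age", "education", imaging), impairment_outcome,
                             rrms, "subgroup_comparisons")
    }
  }

  screen_vars <- intersect(c(.clinical_vars, imaging), names(rrms))
  screen <- spearman_matrix(rrms, screen_vars, zcols)
  screen$q <- matrix(as.numeric(fdr_bh(as.vector(screen$p), "correlation_screen")),
                     nrow(screen$p), ncol(screen$p), dimnames = dimnames(screen$p))

  adjusted <- list()
  for (j in seq_along(zcols)) {
    preds <- intersect(rownames(screen$p)[which(screen$p[, j] < screen_alpha)], imaging)
    if (!length(preds)) next
    adjusted[[zcols[j]]] <- tryCatch(
      adjusted_linear_model(rrms, zcols[j], preds),
      error = function(e) NULL)
  }
  adjusted <- Filter(Negate(is.null), adjusted)

  stepwise <- NULL
  candidates <- character(0)
  if (!is.null(subgroup)) {
    univ_p <- vapply(subgroup, `[[`, numeric(1), "p")
    candidates <- setdiff(names(univ_p)[univ_p < screen_alpha], character(0))
    if (length(candidates)) {
      sw_dat <- rrms
      # code the event as impairment so odds ratios read conventionally
      # (OR < 1 = protective marker)
      out_col <- sw_dat[[impairment_outcome]]
      if (is.character(out_col) || is.factor(out_col))
        sw_dat$.impaired <- as.integer(as.character(out_col) == "impaired")
      else sw_dat$.impaired <- as.integer(out_col != 0)
      stepwise <- tryCatch(
        stepwise_logistic(sw_dat, ".impaired", candidates, removal_alpha),
        error = function(e) NULL)
    }
  }

  structure(list(table = tab, models = zs$models,
                 table1 = table1, table2 = table2, subgroup = subgroup,
                 screen = screen, adjusted = adjusted,
                 candidates = candidates, stepwise = stepwise,
                 params = list(screen_alpha = screen_alpha,
                               removal_alpha = removal_alpha,
                               impairment_outcome = impairment_outcome)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  n <- table(x$table$group)
  cat(sprintf("Cohort report: %d RRMS, %d HC\n", n[["RRMS"]], n[["HC"]]))
  if ("impaired" %in% names(x$table)) {
    imp <- table(x$table$impaired[x$table$group == "RRMS"])
    cat("  BICAMS impairment: ",
        paste(sprintf("%s %d", names(imp), imp), collapse = ", "), "\n", sep = "")
  }
  sig1 <- if (!is.null(x$table1))
    names(Filter(function(r) r$q < 0.05, x$table1)) else character(0)
  cat("  group differences (q < 0.05): ",
      if (length(sig1)) paste(sig1, collapse = ", ") else "none", "\n", sep = "")
  cat(sprintf("  adjusted models fit for %d outcome(s)\n", length(x$adjusted)))
  if (!is.null(x$stepwise)) {
    cat("  stepwise retained: ",
        if (nrow(x$stepwise$retained)) paste(x$stepwise$retained$term, collapse = ", ")
        else "none", "\n", sep = "")
  } else cat("  stepwise: not run (no eligible outcome/candidates)\n")
  invisible(x)
}

#' Write the cohort report tables as TSV and JSON artifacts
#'
#' @param report a \code{cohort_report}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(res) do.call(rbind, lapply(res, function(r)
    data.frame(variable = r$variable, test = r$test, statistic = r$statistic,
               z = r$z, p = r$p, q = r$q, effect_type = r$effect_type,
               effect = r$effect, family = r$family)))
  for (nm in c("table1", "table2", "subgroup")) {
    if (!is.null(report[[nm]]))
      utils::write.table(flat(report[[nm]]), file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(cbind(variable = rownames(report$screen$rho),
                           as.data.frame(report$screen$rho)),
                     file.path(dir, "spearman_rho.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (length(report$adjusted)) {
    adj <- do.call(rbind, lapply(names(report$adjusted), function(nm)
      cbind(outcome = nm, report$adjusted[[nm]]$table)))
    utils::write.table(adj, file.path(dir, "adjusted_models.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$stepwise)) {
    jsonlite::write_json(list(candidates = report$stepwise$candidates,
                              retained = report$stepwise$retained,
                              trace = report$stepwise$trace,
                              model_auc = report$stepwise$model_auc),
                         file.path(dir, "stepwise.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
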