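#' Fit a healthy-control normative model for one cognitive test
#'
#' Ordinary least squares of the raw test score on age, sex and education
#' over healthy-control rows. The residual scale (residual SD with n - p
#' denominator) is the unit of the resulting Z-scores. A zero residual scale
#' (noiseless degenerate fit) is flagged rather than fatal.
#'
#' @param hc data.frame of healthy-control rows with columns \code{age},
#'   \code{sex} (0 = female, 1 = male), \code{education}, and the test.
#' @param test name of the raw score column.
#' @return object of class \code{normative_model} with \code{coef},
#'   \code{scale}, \code{n}, \code{degenerate}, \code{test}.
#' @export
fit_normative <- function(hc, test) {
  need <- c("age", "sex", "education", test)
  miss <- setdiff(need, names(hc))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (nrow(hc) < 5L) stopf("at least 5 healthy-control rows are required")
  if (anyNA(hc[need])) stopf("missing values in normative predictors or score")
  fml <- stats::reformulate(c("age", "sex", "education"), response = test)
  fit <- stats::lm(fml, data = hc)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stopf("collinear normative design; aliased term(s): %s", paste(aliased, collapse = ", "))
  }
  # a noiseless (degenerate) fit is legal and flagged; silence the
  # "essentially perfect fit" warning it provokes
  s <- suppressWarnings(summary(fit)$sigma)
  structure(list(test = test, coef = stats::coef(fit), scale = s,
                 n = nrow(hc), degenerate = s < 1e-10, fit = fit),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("Normative model for '%s' (n_HC = %d)\n", x$test, x$n))
  print(round(x$coef, 4))
  cat(sprintf("  residual scale: %.4f%s\n", x$scale,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
predict.normative_model <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, newdata = newdata))
}

#' Convert raw scores to HC-referenced Z-scores
#'
#' Z = (raw - predicted(age, sex, education)) / residual scale, i.e. the
#' score expressed in healthy-control residual SD units after removing
#' demographic effects. With a degenerate (zero) residual scale an exactly
#' zero residual maps to Z = 0; any other residual is an error.
#'
#' @param model a \code{\link{normative_model}}.
#' @param data data.frame with \code{age}, \code{sex}, \code{education} and
#'   the model's test column.
#' @return numeric vector of Z-scores.
#' @export
z_transform <- function(model, data) {
  stopifnot(inherits(model, "normative_model"))
  resid <- data[[model$test]] - predict(model, data)
  if (model$degenerate) {
    if (any(abs(resid) > 1e-8))
      stopf("degenerate residual scale in normative model for '%s' with nonzero residuals",
            model$test)
    return(rep(0, length(resid)))
  }
  resid / model$scale
}

#' BICAMS impairment classification
#'
#' A subject is classified impaired when at least two of the three BICAMS
#' core domains (processing speed, verbal memory, visuospatial memory) have
#' Z <= -1.5; the boundary value -1.5 counts as an impaired domain.
#' Decreasing any Z can never flip an impaired subject to preserved.
#'
#' @param z_sdmt,z_cvlt,z_bvmt numeric Z-score vectors (recycled to a
#'   common length), no missing values.
#' @return character vector, "impaired" or "preserved".
#' @export
classify_impairment <- function(z_sdmt, z_cvlt, z_bvmt) {
  zs <- cbind(z_sdmt, z_cvlt, z_bvmt)
  if (anyNA(zs) || any(!is.finite(zs))) stopf("missing or non-finite Z-score")
  n_imp <- rowSums(zs <= -1.5)
  ifelse(n_imp >= 2, "impaired", "preserved")
}

#' HC-referenced Z-scoring of a whole cohort table
#'
#' Fits a \code{\link{fit_normative}} model per test on the HC rows and adds
#' a \code{z_<test>} column for every row, plus an \code{impaired} column
#' (BICAMS rule, RRMS rows; NA for HC).
#'
#' @param table cohort data.frame with a \code{group} column (RRMS/HC).
#' @param tests character vector of raw score columns; default the full
#'   battery present in the table.
#' @return list with \code{table} (augmented data.frame) and \code{models}
#'   (named list of normative models).
#' @export
z_score_cohort <- function(table, tests = intersect(cognitive_tests(), names(table))) {
  if (!"group" %in% names(table)) stopf("`table` needs a 'group' column")
  hc <- table[table$group == "HC", , drop = FALSE]
  models <- lapply(tests, function(tn) fit_normative(hc, tn))
  names(models) <- tests
  for (tn in tests) table[[paste0("z_", tn)]] <- z_transform(models[[tn]], table)
  core <- c("sdmt", "cvlt", "bvmt")
  if (all(core %in% tests)) {
    lab <- classify_impairment(table$z_sdmt, table$z_cvlt, table$z_bvmt)
    table$impaired <- ifelse(table$group == "RRMS", lab, NA_character_)
  }
  list(table = table, models = models)
}
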