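#' Backward stepwise logistic regression on Wald p-values
#'
#' Fits the full maximum-likelihood logistic model on all candidate
#' predictors, then iteratively removes the term with the largest Wald
#' p-value while that p exceeds \code{removal_alpha} (default 0.05),
#' recording the elimination trace. Retained terms are reported with B,
#' odds ratio exp(B), Wald 95 percent CI and p; each retained predictor also
#' gets its single-predictor discrimination AUC (orientation >= 0.5 with a
#' direction flag) and the combined final model its fitted-probability AUC.
#' Separation (non-convergence or diverging coefficients) is an error with
#' a diagnostic rather than a silent result.
#'
#' @param table data.frame.
#' @param outcome binary outcome column (0/1, logical, or 2-level factor);
#'   both classes must have at least 5 observations.
#' @param candidates character vector of candidate predictor columns.
#' @param removal_alpha stay threshold on the Wald p-value.
#' @return object of class \code{stepwise_logistic}: \code{$retained}
#'   (data.frame term/B/OR/ci/p/auc), \code{$trace} (elimination steps),
#'   \code{$model_auc}, \code{$fit} (final glm; NULL when intercept-only
#'   data are degenerate), \code{$candidates}.
#' @export
stepwise_logistic <- function(table, outcome, candidates, removal_alpha = 0.05) {
  if (!length(candidates)) stopf("at least one candidate predictor is required")
  miss <- setdiff(c(outcome, candidates), names(table))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  dat <- table[stats::complete.cases(table[c(outcome, candidates)]), c(outcome, candidates)]
  y <- dat[[outcome]]
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  y <- as.integer(y != 0)
  if (sum(y == 0) < 5L || sum(y == 1) < 5L)
    stopf("each outcome class needs >= 5 observations (have %d/%d)", sum(y == 0), sum(y == 1))
  dat$.y <- y

  fit_glm <- function(terms) {
    fml <- if (length(terms)) stats::reformulate(terms, response = ".y") else .y ~ 1
    warned <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                  conditionMessage(w))) warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    cf <- stats::coef(fit)
    if (!fit$converged || warned || any(abs(cf[-1]) > 15))
      stopf("separation detected in logistic fit (terms: %s); coefficients diverge",
            paste(terms, collapse = ", "))
    fit
  }

  terms <- candidates
  trace <- data.frame(step = integer(0), removed = character(0),
                      p_at_removal = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  fit <- fit_glm(terms)
  repeat {
    if (!length(terms)) break
    sm <- summary(fit)$coefficients
    pw <- sm[setdiff(rownames(sm), "(Intercept)"), "Pr(>|z|)", drop = TRUE]
    names(pw) <- setdiff(rownames(sm), "(Intercept)")
    worst <- names(pw)[which.max(pw)]
    if (pw[worst] <= removal_alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = worst,
                                     p_at_removal = unname(pw[worst]),
                                     stringsAsFactors = FALSE))
    terms <- setdiff(terms, worst)
    fit <- fit_glm(terms)
  }

  retained <- data.frame(term = character(0), B = numeric(0), OR = numeric(0),
                         ci_lo = numeric(0), ci_hi = numeric(0), p = numeric(0),
                         auc = numeric(0), stringsAsFactors = FALSE)
  if (length(terms)) {
    sm <- summary(fit)$coefficients
    for (tm in terms) {
      b <- sm[tm, "Estimate"]; se <- sm[tm, "Std. Error"]
      a <- roc_auc(dat[[tm]], y, orient = TRUE)
      retained <- rbind(retained, data.frame(
        term = tm, B = b, OR = exp(b),
        ci_lo = exp(b - 1.96 * se), ci_hi = exp(b + 1.96 * se),
        p = sm[tm, "Pr(>|z|)"], auc = as.numeric(a), stringsAsFactors = FALSE))
    }
  }
  model_auc <- if (length(terms)) roc_auc(stats::fitted(fit), y) else 0.5
  structure(list(candidates = candidates, retained = retained, trace = trace,
                 model_auc = model_auc, removal_alpha = removal_alpha,
                 fit = fit, n = nrow(dat)), class = "stepwise_logistic")
}

#' @export
print.stepwise_logistic <- function(x, digits = 3, ...) {
  cat(sprintf("Backward stepwise logistic regression (Wald, removal p > %g), n = %d\n",
              x$removal_alpha, x$n))
  if (nrow(x$trace)) {
    cat("  removed: ",
        paste(sprintf("%s (p=%.3f)", x$trace$removed, x$trace$p_at_removal),
              collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$retained)) {
    cat("  retained:\n")
    print(cbind(x$retained["term"], round(x$retained[-1], digits)), row.names = FALSE)
  } else cat("  retained: none (intercept-only model)\n")
  cat(sprintf("  combined-model AUC = %.3f\n", x$model_auc))
  invisible(x)
}

#' @export
coef.stepwise_logistic <- function(object, ...) stats::coef(object$fit)

#' @export
summary.stepwise_logistic <- function(object, ...) {
  list(retained = object$retained, trace = object$trace,
       model_auc = object$model_auc)
}
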