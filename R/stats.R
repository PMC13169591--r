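#' Benjamini-Hochberg false discovery rate within a named family
#'
#' Step-up FDR adjustment: on sorted p-values, q(i) = min over j >= i of
#' m p(j) / j, capped at 1 and mapped back to input order. Adjusted values
#' are conventionally called q-values. The family label travels with the
#' result so every q traces to a declared testing family.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param family character label of the testing family.
#' @return numeric vector of q-values with attribute \code{family}.
#' @export
fdr_bh <- function(p, family = "unnamed") {
  if (!length(p)) return(structure(numeric(0), family = family))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  structure(stats::p.adjust(p, method = "BH"), family = family)
}

#' Rank-test effect size r from a standardized test statistic
#'
#' r = |Z| / sqrt(N), the effect size conventionally reported with the
#' Mann-Whitney U test; N is the total study sample size.
#'
#' @param z standardized (normal-approximation) test statistic.
#' @param n_total total sample size.
#' @return numeric effect size in [0, 1] for |Z| <= sqrt(N).
#' @export
effect_size_r <- function(z, n_total) {
  if (n_total <= 0) stopf("`n_total` must be positive")
  abs(z) / sqrt(n_total)
}

# SPSS-style Mann-Whitney: U, tie-corrected asymptotic Z (no continuity
# correction) and asymptotic p.
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (u - n1 * n2 / 2) / sqrt(sig2) else 0
  list(u = u, z = z, p = if (sig2 > 0) 2 * stats::pnorm(-abs(z)) else 1)
}

# Cohen's d with pooled SD from raw samples.
cohens_d <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  if (sp == 0) return(0)
  abs(mean(x) - mean(y)) / sp
}

#' Normality-gated two-group comparison with effect size
#'
#' Implements the cohort-table comparison logic: continuous variables are
#' tested with Shapiro-Wilk (alpha = 0.05) in both groups; if both pass, an
#' independent-samples t-test (pooled variance by default) with Cohen's d
#' (pooled SD) is used and descriptives are mean and SEM; otherwise a
#' Mann-Whitney U test with the tie-corrected asymptotic Z and effect size
#' r = |Z| / sqrt(n_total), with median (Q1, Q3) descriptives. Categorical
#' variables use the Pearson chi-square test with count descriptives. A
#' variable constant and equal in both groups yields the defined degenerate
#' result (statistic 0, p = 1, effect 0).
#'
#' @param table data.frame.
#' @param variable column to compare.
#' @param grouping column holding exactly two group labels.
#' @param family FDR family label carried on the result.
#' @param n_total total N used in r = |Z|/sqrt(N); default the number of
#'   rows of \code{table} (the paper-style convention of using the full
#'   study N even in subgroup comparisons).
#' @param welch use Welch's t instead of the pooled-variance t.
#' @param shapiro_alpha normality gate level.
#' @return object of class \code{stat_result}: variable, test used,
#'   statistic, z (rank tests), p, effect size type and value, descriptives.
#' @export
compare_groups <- function(table, variable, grouping = "group", family = "unnamed",
                           n_total = nrow(table), welch = FALSE,
                           shapiro_alpha = 0.05) {
  if (!variable %in% names(table)) stopf("no column '%s'", variable)
  if (!grouping %in% names(table)) stopf("no column '%s'", grouping)
  keep <- !is.na(table[[variable]]) & !is.na(table[[grouping]])
  x <- table[[variable]][keep]
  g <- factor(table[[grouping]][keep])
  if (nlevels(g) != 2L) stopf("grouping '%s' must have exactly 2 levels (has %d)",
                              grouping, nlevels(g))
  lv <- levels(g)
  categorical <- is.character(x) || is.factor(x) || is.logical(x)

  if (categorical) {
    tabxg <- table(x, g)
    ct <- suppressWarnings(stats::chisq.test(tabxg, correct = FALSE))
    return(structure(list(variable = variable, test = "chi-square",
                          statistic = unname(ct$statistic), z = NA_real_,
                          p = ct$p.value, effect_type = "none", effect = NA_real_,
                          descriptives = tabxg, groups = lv, family = family),
                     class = "stat_result"))
  }

  x1 <- x[g == lv[1]]; x2 <- x[g == lv[2]]
  if (length(x1) < 3L || length(x2) < 3L) stopf("need >= 3 observations per group")
  if (stats::var(x1) == 0 && stats::var(x2) == 0 && mean(x1) == mean(x2)) {
    return(structure(list(variable = variable, test = "t", statistic = 0,
                          z = NA_real_, p = 1, effect_type = "cohens_d", effect = 0,
                          descriptives = data.frame(group = lv, mean = mean(x1),
                                                    sem = 0, n = c(length(x1), length(x2))),
                          groups = lv, family = family), class = "stat_result"))
  }
  sw_p <- vapply(list(x1, x2), function(v) {
    if (stats::var(v) == 0) return(0)  # constant: certainly not Gaussian-compatible
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(sw_p > shapiro_alpha)

  if (normal) {
    tt <- stats::t.test(x1, x2, var.equal = !welch)
    desc <- data.frame(group = lv, mean = c(mean(x1), mean(x2)),
                       sem = c(stats::sd(x1) / sqrt(length(x1)),
                               stats::sd(x2) / sqrt(length(x2))),
                       n = c(length(x1), length(x2)))
    structure(list(variable = variable, test = "t",
                   statistic = unname(tt$statistic), z = NA_real_,
                   p = tt$p.value, effect_type = "cohens_d",
                   effect = cohens_d(x1, x2), descriptives = desc,
                   groups = lv, shapiro_p = sw_p, family = family),
              class = "stat_result")
  } else {
    mw <- mann_whitney_z(x1, x2)
    qf <- function(v) stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
    q1 <- qf(x1); q2 <- qf(x2)
    desc <- data.frame(group = lv, median = c(q1[1], q2[1]),
                       q1 = c(q1[2], q2[2]), q3 = c(q1[3], q2[3]),
                       n = c(length(x1), length(x2)))
    structure(list(variable = variable, test = "mann-whitney",
                   statistic = mw$u, z = mw$z, p = mw$p,
                   effect_type = "r", effect = effect_size_r(mw$z, n_total),
                   descriptives = desc, groups = lv, shapiro_p = sw_p,
                   family = family), class = "stat_result")
  }
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: %s test, statistic = %.4g", x$variable, x$test, x$statistic))
  if (!is.na(x$z)) cat(sprintf(" (Z = %.3f)", x$z))
  cat(sprintf(", p = %.4g", x$p))
  if (x$effect_type != "none")
    cat(sprintf(", %s = %.3f", sub("cohens_d", "Cohen's d", x$effect_type), x$effect))
  cat("\n")
  invisible(x)
}

#' Welch t-test and Cohen's d from printed group summaries
#'
#' Reconstructs the two-sample comparison from published mean, SEM and n per
#' group: SDs are recovered as SEM * sqrt(n), the t statistic is Welch's
#' (only SEMs are available, so no pooled-variance denominator is
#' defensible), and Cohen's d uses the pooled SD.
#'
#' @param mean1,sem1,n1 summary of group 1.
#' @param mean2,sem2,n2 summary of group 2.
#' @return named numeric: \code{t}, \code{df} (Welch-Satterthwaite),
#'   \code{p}, \code{d}.
#' @export
summary_ttest <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (sem1 <= 0 || sem2 <= 0) stopf("SEMs must be positive")
  if (n1 < 2 || n2 < 2) stopf("group sizes must be >= 2")
  se2 <- sem1^2 + sem2^2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  s1 <- sem1 * sqrt(n1); s2 <- sem2 * sqrt(n2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  c(t = t, df = df, p = 2 * stats::pt(-abs(t), df), d = abs(mean1 - mean2) / sp)
}

#' Spearman correlation screen between two variable sets
#'
#' Rank correlations (tie-corrected mid-ranks, p from the t approximation)
#' of every row variable against every column variable; the screening matrix
#' behind covariate-adjusted modelling. Cells with a constant variable are
#' flagged undefined (NA).
#'
#' @param table data.frame.
#' @param row_vars,col_vars column name vectors.
#' @return list with matrices \code{rho} and \code{p} (rows = row_vars).
#' @export
spearman_matrix <- function(table, row_vars, col_vars) {
  miss <- setdiff(c(row_vars, col_vars), names(table))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  rho <- p <- matrix(NA_real_, length(row_vars), length(col_vars),
                     dimnames = list(row_vars, col_vars))
  for (i in seq_along(row_vars)) for (j in seq_along(col_vars)) {
    x <- table[[row_vars[i]]]; y <- table[[col_vars[j]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 5L) next
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(rho = rho, p = p)
}

#' Covariate-adjusted linear model for one cognitive outcome
#'
#' OLS of the outcome on the imaging predictors plus the fixed demographic
#' covariates (age, sex, education). Reports per predictor: unstandardized B
#' with 95 percent CI, standardized beta (B scaled by SD(x)/SD(y)), t, p,
#' q (BH within the model's predictor family), and the variance inflation
#' factor from the auxiliary regression of the predictor on all other
#' right-hand-side terms.
#'
#' @param table data.frame.
#' @param outcome outcome column (typically a Z-score).
#' @param predictors character vector of imaging predictor columns.
#' @param covariates adjustment covariates; default age, sex, education.
#' @param family FDR family label; default the outcome name.
#' @return object of class \code{adjusted_lm} with a per-term results
#'   data.frame (\code{$table}) and the underlying \code{lm} fit.
#' @export
adjusted_linear_model <- function(table, outcome, predictors,
                                  covariates = c("age", "sex", "education"),
                                  family = outcome) {
  if (anyDuplicated(predictors)) stopf("duplicated predictor(s): %s",
                                       paste(unique(predictors[duplicated(predictors)]), collapse = ", "))
  rhs <- c(predictors, covariates)
  miss <- setdiff(c(outcome, rhs), names(table))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  dat <- table[stats::complete.cases(table[c(outcome, rhs)]), c(outcome, rhs)]
  if (nrow(dat) <= length(rhs) + 2L) stopf("too few rows (%d) for %d terms", nrow(dat), length(rhs))
  fit <- stats::lm(stats::reformulate(rhs, response = outcome), data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stopf("singular design; aliased term(s): %s",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  ci <- suppressWarnings(stats::confint(fit))
  sm <- suppressWarnings(summary(fit))$coefficients
  sdy <- stats::sd(dat[[outcome]])
  res <- data.frame(term = predictors, B = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    beta_std = NA_real_, t = NA_real_, p = NA_real_, vif = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(predictors)) {
    tm <- predictors[k]
    res$B[k] <- cf[tm]
    res$ci_lo[k] <- ci[tm, 1]; res$ci_hi[k] <- ci[tm, 2]
    res$beta_std[k] <- cf[tm] * stats::sd(dat[[tm]]) / sdy
    res$t[k] <- sm[tm, "t value"]; res$p[k] <- sm[tm, "Pr(>|t|)"]
    others <- setdiff(rhs, tm)
    r2 <- suppressWarnings(
      summary(stats::lm(stats::reformulate(others, response = tm), data = dat)))$r.squared
    res$vif[k] <- 1 / max(1 - r2, 1e-12)
  }
  res$q <- as.numeric(fdr_bh(res$p, family = family))
  structure(list(outcome = outcome, table = res, covariates = covariates,
                 fit = fit, n = nrow(dat), family = family),
            class = "adjusted_lm")
}

#' @export
print.adjusted_lm <- function(x, digits = 3, ...) {
  cat(sprintf("Adjusted linear model: %s ~ %s (+ %s), n = %d\n",
              x$outcome, paste(x$table$term, collapse = " + "),
              paste(x$covariates, collapse = ", "), x$n))
  print(cbind(x$table["term"], round(x$table[-1], digits)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.adjusted_lm <- function(object, ...) stats::coef(object$fit)

#' Area under the ROC curve via the rank statistic
#'
#' AUC = U / (n1 n0), the Mann-Whitney statistic normalized by the number of
#' case-control pairs, computed from mid-ranks so tied scores receive half
#' credit. With \code{orient = TRUE} the reported value is made >= 0.5 and a
#' \code{flipped} attribute records whether the score direction was
#' reversed.
#'
#' @param scores numeric predictor.
#' @param labels binary class labels (coercible to 0/1); both classes must
#'   be present.
#' @param orient report max(AUC, 1 - AUC) with a direction flag.
#' @return numeric AUC, i.e. the probability a random positive scores above
#'   a random negative.
#' @export
roc_auc <- function(scores, labels, orient = FALSE) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  y <- labels[ok]
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  y <- as.integer(y != 0)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (orient) {
    flipped <- auc < 0.5
    auc <- max(auc, 1 - auc)
    attr(auc, "flipped") <- flipped
  }
  auc
}
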