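## Synthetic two-group cohort generator with planted effect structure.

# Reference moments used to standardize demographic predictors inside the
# generator; ALPS and nWMV are standardized by their own group's moments so
# a planted coefficient is a standardized effect in the analyzed group.
.std <- list(age = c(43, 11), education = c(10, 3.5))

.cog_tests <- c("sdmt", "cvlt", "bvmt", "pasat3", "pasat2",
                "stroop_w", "stroop_c", "stroop_d", "cowa", "mmse", "moca")

# Healthy-control means/SDs per test (SDs reconstructed from reported SEMs
# where applicable; quartile-based scales otherwise).
.cog_hc <- data.frame(
  test = .cog_tests,
  mean = c(53.96, 59.5, 26.19, 74.63, 63.99, 17.13, 23.75, 14.0, 44.94, 28.63, 26.44),
  sd   = c(7.4,   8.5,  2.6,  15.7,  12.5,  3.5,   4.0,   2.2,  4.0,   1.3,   2.1))

#' Specify a synthetic RRMS/HC cohort with planted effects
#'
#' Defines the generative model for a two-group cohort: demographics, group
#' -specific imaging features (ALPS index, normalized tissue volumes, white
#' matter diffusion summaries, lesion burden), and cognitive raw scores that
#' depend linearly on age, sex and education plus planted ALPS and nWMV
#' effects (in standardized units) with Gaussian noise. A latent impairment
#' outcome with prescribed log-odds coefficients (per SD of ALPS and nWMV)
#' and independent null candidate predictors support selection-recovery
#' studies of the stepwise logistic model.
#'
#' All effect coefficients are on the standardized scale: a coefficient b on
#' test T means b standard deviations of T per standard deviation of the
#' predictor. Sex is coded 0 = female, 1 = male throughout.
#'
#' @param n_rrms,n_hc group sizes (default 45 and 41).
#' @param p_male probability of male sex.
#' @param age_mean,age_sd,edu_mean,edu_sd demographic moments (years).
#' @param alps_hc,alps_rrms,nwmv_hc,nwmv_rrms c(mean, sd) of the ALPS index
#'   and normalized white-matter volume (percent) per group.
#' @param covariate_beta named numeric: standardized effects of age, sex and
#'   education on every cognitive test.
#' @param group_beta standardized RRMS deficit applied to every test.
#' @param alps_beta,nwmv_beta named numeric of planted standardized effects
#'   per test (names from the test battery; missing names mean zero).
#' @param resid_sd residual SD of each test in SD units of that test, or
#'   NULL (default) to complete each test's population variance to unity
#'   given its planted and covariate coefficients, so a planted coefficient
#'   is recovered as the standardized effect size in the analyzed group.
#' @param impair_logodds named numeric c(intercept, alps, nwmv): log-odds
#'   model of the latent impairment outcome (per SD of the predictors),
#'   simulated for RRMS rows.
#' @param n_null number of independent standard-normal null candidate
#'   columns (\code{null1}, \code{null2}, ...).
#' @param seed integer RNG seed.
#' @return object of class \code{effect_spec}.
#' @export
effect_spec <- function(n_rrms = 45L, n_hc = 41L,
                        p_male = 0.34,
                        age_mean = 43, age_sd = 11,
                        edu_mean = 10, edu_sd = 3.5,
                        alps_hc = c(1.53, 0.19), alps_rrms = c(1.42, 0.27),
                        nwmv_hc = c(36.1, 1.6), nwmv_rrms = c(35.2, 3.2),
                        covariate_beta = c(age = -0.25, sex = 0, education = 0.25),
                        group_beta = -1.4,
                        alps_beta = c(sdmt = 0.4, pasat3 = 0.3, pasat2 = 0.43, cowa = 0.3),
                        nwmv_beta = c(),
                        resid_sd = NULL,
                        impair_logodds = c(intercept = -0.2, alps = -1.2, nwmv = -0.9),
                        n_null = 3L,
                        seed = 1L) {
  if (n_rrms < 2L || n_hc < 2L) stopf("group sizes must be >= 2")
  if (!is.null(resid_sd) && resid_sd < 0) stopf("`resid_sd` must be >= 0")
  if (any(c(alps_hc[2], alps_rrms[2], nwmv_hc[2], nwmv_rrms[2]) < 0))
    stopf("group SDs must be >= 0")
  full_beta <- function(b) {
    out <- setNames(numeric(length(.cog_tests)), .cog_tests)
    if (length(b)) {
      bad <- setdiff(names(b), .cog_tests)
      if (length(bad)) stopf("unknown test(s): %s", paste(bad, collapse = ", "))
      out[names(b)] <- b
    }
    out
  }
  structure(list(n_rrms = as.integer(n_rrms), n_hc = as.integer(n_hc),
                 p_male = p_male, age_mean = age_mean, age_sd = age_sd,
                 edu_mean = edu_mean, edu_sd = edu_sd,
                 alps_hc = alps_hc, alps_rrms = alps_rrms,
                 nwmv_hc = nwmv_hc, nwmv_rrms = nwmv_rrms,
                 covariate_beta = covariate_beta, group_beta = group_beta,
                 alps_beta = full_beta(alps_beta), nwmv_beta = full_beta(nwmv_beta),
                 resid_sd = resid_sd, impair_logodds = impair_logodds,
                 n_null = as.integer(n_null), seed = as.integer(seed)),
            class = "effect_spec")
}

#' Generate a synthetic cohort table
#'
#' Draws one row per participant under the generative model of an
#' \code{\link{effect_spec}}. Columns: \code{id}, \code{group} (RRMS/HC),
#' \code{sex} (0 = female, 1 = male), \code{age}, \code{education} (years),
#' \code{duration}, \code{edss}, \code{dmt} (RRMS only, NA for HC),
#' imaging features (\code{alps}, \code{ncsfv}, \code{ngmv}, \code{nwmv},
#' \code{tiv}, \code{cth}, \code{fa}, \code{md}, \code{ad}, \code{rd},
#' \code{wmlv}, \code{wmln}), null candidates (\code{null1}, ...), the
#' latent impairment outcome \code{impaired_sim} (RRMS only), and raw
#' cognitive scores (\code{sdmt} ... \code{moca}). Identical spec and seed
#' reproduce the table exactly.
#'
#' @param spec an \code{\link{effect_spec}}.
#' @return data.frame of n_rrms + n_hc rows.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "effect_spec"))
  with_seed(spec$seed, {
    n <- spec$n_rrms + spec$n_hc
    grp <- rep(c("RRMS", "HC"), c(spec$n_rrms, spec$n_hc))
    rrms <- grp == "RRMS"
    age <- pmin(pmax(rnorm(n, spec$age_mean, spec$age_sd), 18), 70)
    sex <- rbinom(n, 1L, spec$p_male)
    edu <- pmin(pmax(round(rnorm(n, spec$edu_mean, spec$edu_sd)), 3), 19)

    draw2 <- function(par_rrms, par_hc)
      ifelse(rrms, rnorm(n, par_rrms[1], par_rrms[2]), rnorm(n, par_hc[1], par_hc[2]))
    alps <- pmax(draw2(spec$alps_rrms, spec$alps_hc), 0.3)
    nwmv <- pmax(draw2(spec$nwmv_rrms, spec$nwmv_hc), 20)
    ngmv <- draw2(c(45.18, 2.0), c(47.77, 3.8))
    ncsfv <- pmax(draw2(c(18.5, 5.0), c(18.6, 1.9)), 5)
    tiv <- draw2(c(1384.7, 160), c(1443.3, 146))
    cth <- draw2(c(2.30, 0.11), c(2.33, 0.06))
    fa <- pmin(pmax(draw2(c(0.26, 0.04), c(0.30, 0.02)), 0.05), 0.9)
    md <- pmax(draw2(c(0.49, 0.04), c(0.50, 0.02)), 0.1)
    ad <- pmax(draw2(c(0.74, 0.03), c(0.76, 0.015)), 0.2)
    rd <- pmax(draw2(c(0.38, 0.05), c(0.36, 0.015)), 0.05)
    wmlv <- ifelse(rrms, pmax(rgamma(n, shape = 1.2, scale = 8), 0.05), NA_real_)
    wmln <- ifelse(rrms, pmax(round(rnorm(n, 18.6, 10.8)), 0), NA_real_)
    duration <- ifelse(rrms, pmax(rgamma(n, shape = 1.5, scale = 4), 0.1), NA_real_)
    edss <- ifelse(rrms, pmin(pmax(round(rnorm(n, 1.7, 1.0) * 2) / 2, 0), 6.5), NA_real_)
    dmt <- ifelse(rrms, ifelse(runif(n) < 0.82, "regular", "untreated"), NA_character_)

    z_age <- (age - .std$age[1]) / .std$age[2]
    z_edu <- (edu - .std$education[1]) / .std$education[2]
    # group-wise standardization: a planted coefficient is a standardized
    # effect in the group the analysis runs on
    std_grp <- function(x, par_rrms, par_hc) {
      z <- (x - ifelse(rrms, par_rrms[1], par_hc[1]))
      z / ifelse(rrms, max(par_rrms[2], 1e-12), max(par_hc[2], 1e-12))
    }
    z_alps <- std_grp(alps, spec$alps_rrms, spec$alps_hc)
    z_nwmv <- std_grp(nwmv, spec$nwmv_rrms, spec$nwmv_hc)
    sex_c <- sex - spec$p_male

    tab <- data.frame(id = sprintf("S%03d", seq_len(n)), group = grp,
                      sex = sex, age = age, education = edu,
                      duration = duration, edss = edss, dmt = dmt,
                      alps = alps, ncsfv = ncsfv, ngmv = ngmv, nwmv = nwmv,
                      tiv = tiv, cth = cth, fa = fa, md = md, ad = ad, rd = rd,
                      wmlv = wmlv, wmln = wmln, stringsAsFactors = FALSE)
    if (spec$n_null > 0) {
      for (k in seq_len(spec$n_null)) tab[[paste0("null", k)]] <- rnorm(n)
    }
    lo <- spec$impair_logodds
    eta <- lo["intercept"] + lo["alps"] * z_alps + lo["nwmv"] * z_nwmv
    imp <- rbinom(n, 1L, stats::plogis(eta))
    tab$impaired_sim <- ifelse(rrms, imp, NA_integer_)

    cb <- spec$covariate_beta
    for (i in seq_along(.cog_tests)) {
      tn <- .cog_tests[i]
      mu <- .cog_hc$mean[i]; sd0 <- .cog_hc$sd[i]
      rs <- if (is.null(spec$resid_sd)) {
        sqrt(max(0, 1 - sum(cb^2) - spec$alps_beta[tn]^2 - spec$nwmv_beta[tn]^2))
      } else spec$resid_sd
      z <- cb["age"] * z_age + cb["sex"] * sex_c + cb["education"] * z_edu +
        spec$alps_beta[tn] * z_alps + spec$nwmv_beta[tn] * z_nwmv +
        ifelse(rrms, spec$group_beta, 0) +
        rs * rnorm(n)
      tab[[tn]] <- mu + sd0 * z
    }
    tab
  })
}

#' The cognitive test battery column names
#' @return character vector of cognitive score column names used by the
#'   cohort table.
#' @export
cognitive_tests <- function() .cog_tests
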