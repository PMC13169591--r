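make_hc <- function(n, f = function(age, sex, edu) 50 - 0.2 * age, sd = 0,
                    seed = 1) {
  set.seed(seed)
  hc <- data.frame(group = "HC",
                   age = runif(n, 20, 60),
                   sex = rbinom(n, 1, 0.4),
                   education = sample(6:18, n, replace = TRUE))
  hc$score <- f(hc$age, hc$sex, hc$education) + rnorm(n, 0, sd)
  hc
}

test_that("noiseless normative fits recover coefficients exactly and flag degeneracy", {
  hc <- make_hc(40, function(a, s, e) 50 - 0.2 * a + 1.5 * s + 0.8 * e)
  m <- fit_normative(hc, "score")
  expect_equal(unname(m$coef), c(50, -0.2, 1.5, 0.8), tolerance = 1e-9)
  expect_true(m$degenerate)

  # permutation invariance
  m2 <- fit_normative(hc[sample(nrow(hc)), ], "score")
  expect_equal(m$coef, m2$coef, tolerance = 1e-9)
})

test_that("normative residual scale estimates the noise SD at large n", {
  hc <- make_hc(500, function(a, s, e) 50 + 0 * a, sd = 10, seed = 2)
  m <- fit_normative(hc, "score")
  # prediction at a typical covariate point recovers the flat mean
  expect_equal(predict(m, data.frame(age = 40, sex = 0, education = 12)), 50,
               tolerance = 0.05)
  expect_equal(m$scale, 10, tolerance = 0.05)
  expect_false(m$degenerate)
})

test_that("collinear normative designs error with the aliased term named", {
  hc <- make_hc(30, sd = 1)
  hc$education <- hc$age * 2   # exact collinearity
  expect_error(fit_normative(hc, "score"), "collinear")
})

test_that("z_transform centers, scales, and satisfies the OLS mean-zero identity", {
  hc <- make_hc(60, function(a, s, e) 40 + 0.3 * e, sd = 5, seed = 3)
  m <- fit_normative(hc, "score")
  # raw equal to the prediction: Z = 0
  subj <- data.frame(age = 35, sex = 1, education = 12)
  subj$score <- predict(m, subj)
  expect_equal(z_transform(m, subj), 0, tolerance = 1e-12)
  # raw 1.5 scales below the prediction: Z = -1.5
  subj$score <- subj$score - 1.5 * m$scale
  expect_equal(z_transform(m, subj), -1.5, tolerance = 1e-12)
  # the fitting sample has mean Z = 0 (OLS residual identity)
  expect_equal(mean(z_transform(m, hc)), 0, tolerance = 1e-9)

  # degenerate scale: zero residuals map to 0, anything else errors
  hc0 <- make_hc(30)
  m0 <- fit_normative(hc0, "score")
  expect_equal(z_transform(m0, hc0), rep(0, 30))
  hc0$score[1] <- hc0$score[1] + 1
  expect_error(z_transform(m0, hc0), "degenerate")
})

test_that("the BICAMS two-of-three rule passes its exhaustive truth table", {
  lo <- -1.6; hi <- 0
  for (a in c(lo, hi)) for (b in c(lo, hi)) for (c in c(lo, hi)) {
    want <- if (sum(c(a, b, c) <= -1.5) >= 2) "impaired" else "preserved"
    expect_equal(classify_impairment(a, b, c), want)
  }
  # boundary: exactly -1.5 counts as an impaired domain
  expect_equal(classify_impairment(-1.6, -1.5, 0), "impaired")
  expect_equal(classify_impairment(-1.5, -1.5, 10), "impaired")
  expect_equal(classify_impairment(-1.4, -1.4, -1.4), "preserved")
  expect_equal(classify_impairment(-3.0, 0, 0), "preserved")
  expect_error(classify_impairment(NA, 0, 0), "missing")
})

test_that("lowering any Z never flips impaired to preserved (monotonicity)", {
  set.seed(4)
  for (k in 1:200) {
    z <- rnorm(3, -1, 1)
    before <- classify_impairment(z[1], z[2], z[3])
    j <- sample(3, 1)
    z[j] <- z[j] - runif(1, 0, 2)
    after <- classify_impairment(z[1], z[2], z[3])
    if (before == "impaired") expect_equal(after, "impaired")
  }
})
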