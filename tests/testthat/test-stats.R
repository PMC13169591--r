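test_that("BH q-values follow the step-up definition", {
  expect_equal(as.numeric(fdr_bh(c(0.005, 0.03, 0.5))), c(0.015, 0.045, 0.5))
  expect_equal(as.numeric(fdr_bh(0.2)), 0.2)
  expect_identical(length(fdr_bh(numeric(0))), 0L)

  set.seed(9)
  for (k in 1:50) {
    p <- runif(sample(1:30, 1))
    q <- as.numeric(fdr_bh(p))
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))           # q >= p elementwise
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))  # monotone in p-rank
  }
})

test_that("rank effect size r reproduces the |Z|/sqrt(N) convention", {
  expect_equal(effect_size_r(-5.088, 86), 0.549, tolerance = 0.001)
  expect_equal(effect_size_r(2.680, 86), 0.289, tolerance = 0.001)
})

test_that("summary t-test matches a full-data Welch test on moment-matched samples", {
  # TIV group summaries: |t| near 1.77, d = 0.381
  tiv <- summary_ttest(1384.66, 23.89, 45, 1443.27, 22.81, 41)
  expect_equal(unname(abs(tiv["t"])), 1.77, tolerance = 0.01)
  expect_lt(abs(unname(tiv["d"]) - 0.381), 5e-4)
  expect_equal(unname(summary_ttest(50, 2, 20, 50, 3, 25)[c("t", "d")]), c(0, 0))

  set.seed(10)
  for (k in 1:10) {
    n1 <- sample(10:50, 1); n2 <- sample(10:50, 1)
    m1 <- rnorm(1, 50, 10); m2 <- rnorm(1, 50, 10)
    s1 <- runif(1, 1, 8); s2 <- runif(1, 1, 8)
    # construct samples with exactly these means and SDs
    e1 <- rnorm(n1); e1 <- (e1 - mean(e1)) / sd(e1)
    e2 <- rnorm(n2); e2 <- (e2 - mean(e2)) / sd(e2)
    x1 <- m1 + s1 * e1; x2 <- m2 + s2 * e2
    full <- t.test(x1, x2)
    got <- summary_ttest(m1, s1 / sqrt(n1), n1, m2, s2 / sqrt(n2), n2)
    expect_equal(unname(got["t"]), unname(full$statistic), tolerance = 1e-9)
    expect_equal(unname(got["p"]), full$p.value, tolerance = 1e-9)
  }
})

test_that("compare_groups gates on normality and reports matched descriptives", {
  set.seed(12)
  tab <- data.frame(group = rep(c("A", "B"), c(45, 41)))
  tab$gauss <- rnorm(86, 10, 2) + (tab$group == "A")
  tab$skewed <- rexp(86) + 2 * (tab$group == "A")
  tab$cat <- sample(c("m", "f"), 86, replace = TRUE)

  g <- compare_groups(tab, "gauss")
  expect_equal(g$test, "t")
  expect_equal(g$effect_type, "cohens_d")
  expect_named(g$descriptives, c("group", "mean", "sem", "n"))
  x1 <- tab$gauss[tab$group == "A"]; x2 <- tab$gauss[tab$group == "B"]
  expect_equal(g$statistic, unname(t.test(x1, x2, var.equal = TRUE)$statistic))

  s <- compare_groups(tab, "skewed")
  expect_equal(s$test, "mann-whitney")
  expect_equal(s$effect, abs(s$z) / sqrt(86), tolerance = 1e-12)
  # asymptotic p agrees with the uncorrected normal approximation
  wt <- wilcox.test(tab$skewed[tab$group == "A"], tab$skewed[tab$group == "B"],
                    exact = FALSE, correct = FALSE)
  expect_equal(s$p, wt$p.value, tolerance = 1e-6)
  expect_named(s$descriptives, c("group", "median", "q1", "q3", "n"))

  ct <- compare_groups(tab, "cat")
  expect_equal(ct$test, "chi-square")

  # identical constant groups: defined degenerate result
  tab$const <- 1
  d <- compare_groups(tab, "const")
  expect_equal(c(d$statistic, d$p, d$effect), c(0, 1, 0))
})

test_that("spearman screen handles monotone, antitone and constant columns", {
  tab <- data.frame(x = 1:20, y = (1:20)^2, yneg = -(1:20)^3, flat = 1,
                    noise = rnorm(20))
  sm <- spearman_matrix(tab, c("x", "flat"), c("y", "yneg"))
  expect_equal(sm$rho["x", "y"], 1)
  expect_equal(sm$rho["x", "yneg"], -1)
  expect_true(all(is.na(sm$rho["flat", ])))

  # null columns: mean rho near zero over seeds
  set.seed(13)
  rhos <- replicate(40, {
    d <- data.frame(a = rnorm(100), b = rnorm(100))
    spearman_matrix(d, "a", "b")$rho[1, 1]
  })
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("adjusted linear models recover noiseless effects with unit VIF", {
  set.seed(14)
  n <- 60
  tab <- data.frame(age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
                    education = sample(6:18, n, TRUE), alps = rnorm(n, 1.5, 0.2))
  tab$z <- 2 + 3 * tab$alps
  m <- adjusted_linear_model(tab, "z", "alps")
  expect_equal(m$table$B, 3, tolerance = 1e-9)
  expect_equal(m$table$vif, 1, tolerance = 0.2)
  expect_true(m$table$ci_lo <= m$table$B && m$table$B <= m$table$ci_hi)

  expect_error(adjusted_linear_model(tab, "z", c("alps", "alps")), "duplicated")
  tab$alps2 <- tab$alps
  expect_error(adjusted_linear_model(tab, "z", c("alps", "alps2")), "aliased")
})

test_that("in-package VIF agrees with the car reference implementation", {
  set.seed(15)
  n <- 80
  tab <- data.frame(age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
                    education = sample(6:18, n, TRUE))
  tab$alps <- rnorm(n, 1.5, 0.2) - 0.002 * tab$age
  tab$nwmv <- rnorm(n, 36, 2) + 2 * tab$alps
  tab$z <- rnorm(n)
  m <- adjusted_linear_model(tab, "z", c("alps", "nwmv"))
  ref <- car::vif(m$fit)
  expect_equal(m$table$vif, unname(ref[c("alps", "nwmv")]), tolerance = 1e-6)
})

test_that("rank AUC equals the pairwise statistic and the pROC reference", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7), c(1, 1, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")

  set.seed(16)
  for (k in 1:10) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(n), 1)  # rounding induces ties
    a <- roc_auc(s, y)
    expect_equal(a, auc_oracle(s, y), tolerance = 1e-12)
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                   direction = "<"))),
                 tolerance = 1e-9)
  }
  # orientation flag
  a <- roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0), orient = TRUE)
  expect_equal(as.numeric(a), 1)
  expect_true(attr(a, "flipped"))
})
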