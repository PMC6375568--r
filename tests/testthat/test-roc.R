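test_that("separated classes give AUC 1 and the midpoint cut-off", {
  r <- optimal_cutoff(roc_curve(c(1, 2, 3, 10, 11, 12),
                                rep(c("athlete", "HCM"), each = 3)))
  expect_equal(r$auc, 1)
  expect_equal(r$optimal_threshold, 6.5)
  expect_equal(r$at_optimum$correctly_classified, 100)
  expect_equal(unname(r$confusion), c(3L, 0L, 0L, 3L))
})

test_that("label-independent values give a near-chance AUC", {
  set.seed(4)
  v <- rnorm(2000)
  lab <- rep(c(TRUE, FALSE), 1000)
  expect_lt(abs(roc_curve(v, lab)$auc - 0.5), 0.04)
})

test_that("single-class input is an explicit error", {
  expect_error(roc_curve(1:5, rep("HCM", 5)), "both classes")
})

test_that("trapezoidal AUC equals the all-pairs concordance oracle", {
  set.seed(7)
  for (i in 1:25) {
    v <- round(rnorm(20), 1)            # rounding forces ties
    pos <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(roc_curve(v, pos)$auc, concordance_oracle(v, pos))
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(8)
  v <- rexp(40); pos <- rep(c(TRUE, FALSE), 20)
  a <- roc_curve(v, pos)$auc
  expect_equal(roc_curve(log(v), pos)$auc, a)
  expect_equal(roc_curve(v^3, pos)$auc, a)
})

test_that("optimal cut-off matches exhaustive search; arrays are monotone", {
  set.seed(9)
  for (i in 1:25) {
    v <- round(rnorm(20), 1)
    pos <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (!any(pos) || all(pos)) next
    r <- optimal_cutoff(roc_curve(v, pos))
    expect_equal(r$at_optimum$correctly_classified / 100,
                 best_accuracy_oracle(v, pos))
    expect_true(all(diff(r$sensitivity) <= 0))
    expect_true(all(diff(r$specificity) >= 0))
  }
})

test_that("an uninformative index falls back to the majority class", {
  r <- optimal_cutoff(roc_curve(rep(5, 10), rep(c("HCM", "athlete"),
                                                c(7, 3))))
  expect_equal(r$at_optimum$correctly_classified, 70)
})

test_that("confusion metrics follow their defining formulas", {
  m <- confusion_metrics(143, 0, 47, 108)
  expect_equal(round(m$ppv), 100)
  expect_equal(round(m$npv), 70)
  expect_equal(m$sensitivity, 100 * 143 / 190)
  expect_equal(confusion_metrics(25, 10, 25, 40)$sensitivity, 50)
  expect_equal(confusion_metrics(5, 0, 3, 2)$ppv, 100)
  # zero denominator is undefined, not zero
  expect_true(is.na(confusion_metrics(0, 0, 5, 5)$ppv))
  expect_error(confusion_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("DeLong self-comparison and rank-preserving transforms are null", {
  set.seed(10)
  v <- rnorm(30); pos <- rep(c(TRUE, FALSE), 15)
  self <- delong_compare(v, v, pos)
  expect_equal(self$auc_diff, 0)
  expect_equal(self$p_value, 1)
  mono <- delong_compare(v, exp(v), pos)
  expect_equal(mono$auc_diff, 0)
})

test_that("DeLong agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  pos <- rep(c(TRUE, FALSE), c(25, 35))
  a <- rnorm(60) + pos * 1.2
  b <- 0.6 * a + rnorm(60, sd = 0.8)
  mine <- delong_compare(a, b, pos)
  ref <- pROC::roc.test(pROC::roc(pos, a, quiet = TRUE),
                        pROC::roc(pos, b, quiet = TRUE), method = "delong")
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-8)
  expect_equal(mine$auc_a, as.numeric(pROC::auc(pROC::roc(pos, a,
                                                          quiet = TRUE))))
})

test_that("DeLong variance matches a bootstrap estimate", {
  set.seed(13)
  pos <- rep(c(TRUE, FALSE), c(30, 30))
  a <- rnorm(60) + pos * 1.0
  b <- 0.5 * a + rnorm(60, sd = 1)
  mine <- delong_compare(a, b, pos)
  auc_of <- function(v, p) {
    r <- rank(v)
    (sum(r[p]) - sum(p) * (sum(p) + 1) / 2) / (sum(p) * sum(!p))
  }
  diffs <- replicate(10000, {
    i <- c(sample(which(pos), replace = TRUE),
           sample(which(!pos), replace = TRUE))
    auc_of(a[i], pos[i]) - auc_of(b[i], pos[i])
  })
  expect_lt(abs(mine$var_diff - var(diffs)) / var(diffs), 0.3)
})

test_that("adjustment is exact when covariates are orthogonal to group", {
  g <- rep(c("athlete", "HCM"), each = 20)
  age <- rep(c(20, 30, 40, 50), 10)         # balanced across groups
  hr <- rep(c(60, 80), 20)
  y <- ifelse(g == "HCM", 7, 3) + 0 * age
  cmp <- suppressWarnings(adjusted_group_compare(y, g, age, hr))
  # radix level order puts HCM first, so the estimate is athlete minus HCM
  expect_equal(cmp$comparison, "athlete vs HCM")
  expect_equal(cmp$estimate, -4)
  expect_lt(cmp$p_value, 1e-10)
})

test_that("stratified comparison recovers known simulated effects", {
  set.seed(14)
  n <- 200
  sex <- rep(c("M", "F"), each = 2 * n)
  g <- rep(rep(c("athlete", "hcm"), each = n), 2)
  age <- runif(4 * n, 20, 60)
  hr <- runif(4 * n, 50, 90)
  eff <- ifelse(sex == "M", 5, 2)
  y <- 10 + eff * (g == "hcm") + 0.05 * age - 0.02 * hr + rnorm(4 * n)
  cmp <- adjusted_group_compare(y, g, age, hr, strata = sex)
  m <- cmp[cmp$stratum == "M", ]
  f <- cmp[cmp$stratum == "F", ]
  expect_lt(abs(m$estimate - 5), 3 * m$se)
  expect_lt(abs(f$estimate - 2), 3 * f$se)
  expect_equal(cmp$covariates, rep("age, heart_rate", 2))
})

test_that("degenerate designs raise explicit errors", {
  y <- rnorm(10); g <- rep(c("a", "b"), 5)
  expect_error(adjusted_group_compare(y, rep("a", 10), runif(10), runif(10)),
               "fewer than 2 groups")
  expect_error(adjusted_group_compare(y, g, rep(1, 10), rep(1, 10)),
               "rank-deficient")
  expect_error(adjusted_group_compare(y[1:5], g, runif(10), runif(10)),
               "lengths differ")
})
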