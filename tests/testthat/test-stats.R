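test_that("chi-square equals the textbook statistic on random tables", {
  set.seed(9)
  for (rep in 1:5) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    res <- pearson_chi2(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E))
    expect_equal(res$df, 2)
    expect_equal(res$p.value, pchisq(res$statistic, 2, lower.tail = FALSE))
  }
})

test_that("all-zero categories are dropped before testing", {
  tab <- rbind(c(7, 1, 5, 0), c(58, 2, 7, 0))   # last column empty
  res <- pearson_chi2(tab)
  expect_equal(res$dropped$cols, 4L)
  expect_equal(res$df, 2)
  expect_error(pearson_chi2(rbind(c(0, 0), c(0, 0))),
               class = "degenerate_table_error")
  expect_error(pearson_chi2(rbind(c(1, 0), c(2, 0))),
               class = "degenerate_table_error")
})

test_that("Yates correction modifies only 2x2 tables", {
  tab <- rbind(c(5, 8), c(51, 16))
  plain <- pearson_chi2(tab, yates = FALSE)
  corrected <- pearson_chi2(tab, yates = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(corrected$statistic, sum((abs(tab - E) - 0.5)^2 / E))
  expect_gt(plain$statistic, corrected$statistic)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(rbind(c(1, 0), c(0, 1))), 1)
  # margins (5,5)/(5,5): extreme diagonal table, p = 2/choose(10,5)
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5))), 2 / 252)
  # a zero margin leaves a single possible table
  expect_equal(fisher_exact(rbind(c(0, 0), c(3, 4))), 1)
  expect_error(fisher_exact(matrix(1, 2, 3)), class = "degenerate_table_error")
})

test_that("Mann-Whitney U equals the pair-count oracle", {
  set.seed(10)
  for (rep in 1:4) {
    x <- round(rnorm(8), 1); y <- round(rnorm(8, 0.5), 1)
    res <- mann_whitney(x, y)
    U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(unname(res$U), U)
  }
  # complete separation
  expect_equal(unname(mann_whitney(1:4, 11:14)$U), 0)
  # identical samples: p = 1 by symmetry (normal approx with correction)
  expect_equal(mann_whitney(rep(3, 5), rep(3, 5))$p.value, 1)
})

test_that("Kaplan-Meier without censoring is the empirical survival curve", {
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # with censoring, product-limit by hand
  km2 <- km_fit(c(1, 2, 2, 4), c(1, 0, 1, 1))
  expect_equal(km2$survival[km2$times == 1], 3 / 4)
  expect_equal(km2$survival[km2$times == 2][1], 3 / 4 * (1 - 1 / 3))
})

test_that("log-rank test matches hand-computed O-E tables and is symmetric", {
  ta <- c(1, 3, 5); ea <- c(1, 1, 0)
  tb <- c(2, 4, 6); eb <- c(1, 1, 1)
  res <- logrank_test(ta, ea, tb, eb)
  # hand computation over event times 1,2,3,4,6 (group A observed events
  # at 1,3; expectations from at-risk proportions)
  oe <- 0; v <- 0
  risk_a <- c(3, 2, 2, 1, 0); risk_b <- c(3, 3, 2, 2, 1)
  obs_a <- c(1, 0, 1, 0, 0)
  for (k in 1:5) {
    n <- risk_a[k] + risk_b[k]
    e_a <- risk_a[k] / n
    oe <- oe + obs_a[k] - e_a
    v <- v + risk_a[k] * risk_b[k] / n^2
  }
  expect_equal(res$statistic, oe^2 / v, tolerance = 1e-10)
  # symmetry in the group labels
  res2 <- logrank_test(tb, eb, ta, ea)
  expect_equal(res$statistic, res2$statistic)
  # identical groups: statistic 0, p = 1
  same <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1)
  expect_error(logrank_test(c(1, 2), c(0, 0), c(3), c(0)),
               class = "no_events_error")
})

test_that("Cox regression recovers a planted hazard ratio of 3", {
  set.seed(18)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = 0.05 * 3^x)
  t_cens <- rexp(n, rate = 0.03)
  fit <- cox_fit(pmin(t_event, t_cens), as.numeric(t_event <= t_cens),
                 matrix(x, ncol = 1, dimnames = list(NULL, "grp")))
  expect_true(fit$converged)
  expect_gt(fit$coefficients$hr, 2.4)
  expect_lt(fit$coefficients$hr, 3.75)
  expect_lt(fit$coefficients$p.value, 1e-6)
  # log-rank direction agreement: positive coefficient, worse survival
  expect_gt(fit$coefficients$coef, 0)
})

test_that("two-subject single-event data has a monotone partial likelihood", {
  # the score equation has no finite root; the fit must flag and cap
  fit <- cox_fit(c(1, 2), c(1, 0), matrix(c(1, 0), ncol = 1))
  expect_true(fit$monotone)
  expect_equal(abs(fit$coefficients$coef), 20)
  expect_gt(fit$coefficients$coef, 0)   # event carried the larger covariate
})

test_that("lasso Cox zeroes a signal-free covariate", {
  set.seed(25)
  n <- 120
  x1 <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, rate = 0.05 * exp(0.9 * x1))
  t_cens <- rexp(n, rate = 0.03)
  X <- cbind(signal = x1, zero = rep(0, n), noise = rnorm(n))
  fit <- cox_fit(pmin(t_event, t_cens), as.numeric(t_event <= t_cens), X,
                 l1_penalty = 0.05)
  cf <- setNames(fit$coefficients$coef, fit$coefficients$term)
  expect_identical(unname(cf["zero"]), 0)
  expect_gt(unname(cf["signal"]), 0)
  expect_true(!is.null(fit$path))
})

test_that("constant covariates are rejected in unpenalised fits", {
  expect_error(cox_fit(c(1, 2, 3), c(1, 1, 0), matrix(1, 3, 1)),
               class = "configuration_error")
})

test_that("report tables assemble counts, medians and p-values", {
  set.seed(30)
  df <- data.frame(
    group = rep(c("high", "low"), c(13, 67)),
    stage = sample(c("I", "II", "III"), 80, TRUE),
    marker = rlnorm(80),
    time_months = rexp(80, 0.02),
    event = rbinom(80, 1, 0.4)
  )
  df$event[1] <- 1
  tab <- group_comparison_table(df, "group", categorical = "stage",
                                continuous = "marker")
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$p.value >= 0 & tab$p.value <= 1))
  ct <- cox_table(df, "time_months", "event", c("group", "stage"),
                  multivariable = c("group", "stage"))
  expect_equal(sum(ct$analysis == "univariable"), 2)
  expect_equal(sum(ct$analysis == "multivariable"), 2)
  expect_true(all(ct$hr > 0))
})
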