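test_that("patient risk is the maximum slide score", {
  expect_equal(patient_risk(c(a = 0.7), "a"), 0.7)
  expect_equal(patient_risk(c(a = -1.2, b = 0.3, c = 0.1), c("a", "b", "c")), 0.3)
  expect_equal(patient_risk(c(a = 0.2, b = 0.2), c("a", "b")), 0.2)
  expect_error(patient_risk(c(a = 1), "z"), class = "configuration_error")
})

test_that("Breslow baseline matches hand-computed risk-set sums", {
  # all scores 0, events at t=1,2, censored at 3: H0(1)=1/3, H0(2)=1/3+1/2
  b <- breslow_baseline(c(0, 0, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(b$event_times, c(1, 2))
  expect_equal(b$cum_hazard, c(1 / 3, 1 / 3 + 1 / 2))
  # single subject, event at t=1, score 0: H0(1)=1, S0(1)=exp(-1)
  b1 <- breslow_baseline(0, 1, 1)
  expect_equal(b1$cum_hazard, 1)
  expect_equal(survival_probability(0, b1, 1), exp(-1))
  expect_error(breslow_baseline(c(0, 0), c(1, 2), c(0, 0)),
               class = "no_events_error")
})

test_that("baseline with zero scores equals the Nelson-Aalen estimator", {
  # 10-subject toy data; cumulative hazard is a sum of d_i / n_i terms
  times <- c(2, 3, 3, 5, 7, 8, 10, 11, 13, 15)
  events <- c(1, 1, 1, 0, 1, 0, 1, 0, 1, 0)
  b <- breslow_baseline(rep(0, 10), times, events)
  expect_equal(b$event_times, c(2, 3, 7, 10, 13))
  expect_equal(b$cum_hazard,
               cumsum(c(1 / 10, 2 / 9, 1 / 6, 1 / 4, 1 / 2)))
  # cross-check against the survival package estimator
  sf <- survival::survfit(survival::Surv(times, events) ~ 1, ctype = 1)
  expect_equal(b$cum_hazard, sf$cumhaz[sf$n.event > 0])
})

test_that("shifting scores and predictions leaves survival curves unchanged", {
  set.seed(6)
  sc <- rnorm(12); t <- rexp(12, 0.1); e <- rbinom(12, 1, 0.7); e[1] <- 1
  b0 <- breslow_baseline(sc, t, e)
  bc <- breslow_baseline(sc + 3, t, e)
  for (h in c(5, 10, 20)) {
    expect_equal(survival_probability(1.2, b0, h),
                 survival_probability(1.2 + 3, bc, h), tolerance = 1e-12)
  }
})

test_that("survival probability follows the baseline-power law", {
  b <- breslow_baseline(c(0, 0, 0), c(10, 20, 30), c(1, 1, 0))
  # risk 0 reproduces S0
  expect_equal(survival_probability(0, b, 15), exp(-b$cum_hazard[1]))
  # horizon before the first event time: probability exactly 1
  expect_equal(survival_probability(2.5, b, 5), 1)
  # power identity S^exp(risk)
  s0 <- survival_probability(0, b, 25)
  expect_equal(survival_probability(log(2), b, 25), s0^2)
  # monotone decreasing in risk
  r <- seq(-2, 2, 0.5)
  p <- survival_probability(r, b, 25)
  expect_true(all(diff(p) < 0))
})

test_that("stratification applies a strict threshold rule", {
  s <- stratify(c(p1 = 0.95, p2 = 0.89, p3 = 0.9), threshold = 0.9)
  grp <- setNames(s$patients$group, s$patients$patient_id)
  expect_equal(unname(grp["p1"]), "low")
  expect_equal(unname(grp["p2"]), "high")
  expect_equal(unname(grp["p3"]), "low")   # exactly at threshold -> low
})

test_that("concordance equals the all-pairs oracle and its closed cases", {
  # perfect anti-ordering with all events
  expect_equal(concordance_index(c(5, 4, 3, 2, 1), 1:5, rep(1, 5)), 1)
  # all risks tied
  expect_equal(concordance_index(rep(2, 6), 1:6, rep(1, 6)), 0.5)
  set.seed(12)
  for (rep in 1:5) {
    n <- 20
    r <- rnorm(n); t <- rexp(n); e <- rbinom(n, 1, 0.6); e[1] <- 1
    expect_equal(concordance_index(r, t, e), cindex_oracle(r, t, e))
  }
  expect_error(concordance_index(c(1, 2), c(3, 4), c(0, 0)),
               class = "undefined_result_error")
})

test_that("concordance is invariant under strictly monotone transforms", {
  set.seed(17)
  r <- rnorm(15); t <- rexp(15); e <- rbinom(15, 1, 0.7); e[2] <- 1
  c0 <- concordance_index(r, t, e)
  expect_equal(concordance_index(3 * r - 7, t, e), c0)
  expect_equal(concordance_index(exp(r), t, e), c0)
  expect_equal(concordance_index(atan(r), t, e), c0)
})

test_that("cross-validation partitions patients, not slides", {
  co <- tiny_cohort(n_patients = 8, seed = 3)
  cv <- cross_validate(co$graphs, co$survival, tiny_backbone(),
                       train_config(epochs = 5, seed = 1),
                       n_folds = 4, seed = 2)
  expect_length(cv$folds, 8)
  expect_equal(as.integer(sort(table(cv$folds))), c(2L, 2L, 2L, 2L))
  # every slide of a patient shares the patient's fold, and each patient
  # is scored as a test case exactly once
  expect_setequal(cv$patients$patient_id, unique(co$survival$patient_id))
  expect_equal(anyDuplicated(cv$patients$patient_id), 0)
  for (pid in names(cv$folds)) {
    expect_equal(unique(cv$patients$fold[cv$patients$patient_id == pid]),
                 unname(cv$folds[pid]))
  }
})
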