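test_that("synthetic slides are deterministic and honour the blob count", {
  cfg <- slide_sim_config(width = 320, height = 320, seed = 77)
  s1 <- simulate_slide(cfg)
  s2 <- simulate_slide(cfg)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth, s2$truth)
  empty <- simulate_slide(slide_sim_config(width = 300, height = 300,
                                           n_blobs = 0, speck_count = 0,
                                           seed = 1))
  expect_false(any(empty$truth))
})

test_that("the masking pipeline recovers the planted truth mask", {
  sl <- simulate_slide(slide_sim_config(width = 640, height = 640,
                                        hole_spec = c(400, 9), seed = 12))
  tm <- compute_tissue_mask(sl$image)
  iou <- sum(tm$mask & sl$truth) / sum(tm$mask | sl$truth)
  expect_gte(iou, 0.95)
  # specks (area 25) must all be gone
  speck_only <- tm$mask & !sl$truth
  lab <- label_components(tm$mask, 8)
  areas <- tabulate(lab)
  expect_true(all(areas[areas > 0] >= 100))
})

test_that("cohort simulation is seed-deterministic with valid structure", {
  cfg <- cohort_sim_config(n_patients = 10, slides_per_patient = c(1, 2),
                           nodes_per_graph = c(6, 10), feature_dim = 16,
                           seed = 42)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$survival, c2$survival)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$graphs[[3]]$features, c2$graphs[[3]]$features)
  # per-slide rows match graphs, times shared within patient
  expect_equal(length(c1$graphs), nrow(c1$survival))
  for (pid in unique(c1$survival$patient_id)) {
    expect_equal(length(unique(c1$survival$time_months[
      c1$survival$patient_id == pid])), 1)
  }
  expect_error(simulate_cohort(cohort_sim_config(
    aggressive_fraction_range = c(0.9, 0.1))), class = "configuration_error")
})

test_that("planted signal raises the feature mean on signal dimensions", {
  cfg <- cohort_sim_config(n_patients = 10, slides_per_patient = c(1, 1),
                           nodes_per_graph = c(40, 40), feature_dim = 32,
                           signal_dim_count = 8,
                           aggressive_fraction_range = c(0.7, 0.9), seed = 3)
  co <- simulate_cohort(cfg)
  m_sig <- mean(vapply(co$graphs, function(g) mean(g$features[, 1:8]), numeric(1)))
  m_null <- mean(vapply(co$graphs, function(g) mean(g$features[, 9:32]), numeric(1)))
  expect_gt(m_sig, 1)            # ~ rho * shift = 0.8 * 2
  expect_lt(abs(m_null), 0.2)
})

test_that("event fraction follows the competing-exponentials formula", {
  cfg <- cohort_sim_config(seed = 1)
  set.seed(99)
  rho <- runif(2000, 0.05, 0.95)
  eta <- cfg$beta_true * rho
  out <- gnnsurv:::simulate_survival_times(eta, cfg)
  h <- cfg$baseline_rate * exp(eta)
  expected <- mean(h / (h + cfg$censor_rate))
  expect_equal(mean(out$event), expected, tolerance = 0.05)
  # censor rate -> 0 gives event fraction -> 1
  cfg2 <- cohort_sim_config(censor_rate = 1e-9, seed = 1)
  out2 <- gnnsurv:::simulate_survival_times(eta[1:500], cfg2)
  expect_gte(mean(out2$event), 0.99)
})

test_that("a null cohort carries no survival signal", {
  co <- simulate_cohort(cohort_sim_config(n_patients = 60,
                                          slides_per_patient = c(1, 1),
                                          nodes_per_graph = c(6, 8),
                                          feature_dim = 8, signal_dim_count = 4,
                                          beta_true = 0, seed = 8))
  # times are independent of rho when beta_true = 0
  expect_lt(abs(cor(co$truth$rho, rank(co$truth$time_months))), 0.3)
})

test_that("Weibull event times respect the proportional-hazards ordering", {
  cfg <- cohort_sim_config(time_dist = "weibull", weibull_shape = 2,
                           censor_rate = 1e-9, seed = 2)
  set.seed(5)
  eta <- c(rep(0, 400), rep(2, 400))
  out <- gnnsurv:::simulate_survival_times(eta, cfg)
  # high-hazard group fails earlier on average
  expect_lt(median(out$time_months[eta == 2]), median(out$time_months[eta == 0]))
})
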