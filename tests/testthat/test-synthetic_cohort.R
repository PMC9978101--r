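test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(n_per_group = c(HC = 1, SD = 5, MDD = 5)),
               "at least 2")
  expect_error(cohort_spec(g = 2), "at least 3")
  expect_error(cohort_spec(n_volumes = 10), "exceed 20")
  expect_error(cohort_spec(tr_seconds = 0), "positive")
  expect_error(cohort_spec(ar_coefficient = 1), "0, 1")
  expect_error(effect_spec("MDD", 5, 10, 1.2), "delta_r")
  expect_error(cohort_spec(g = 20,
                           effects = list(effect_spec("MDD", 30, 5, 0.2))),
               "hub_node")
})

test_that("group covariances follow the planted-effect construction", {
  # no effects: all groups share the base matrix exactly
  spec0 <- cohort_spec(n_per_group = c(HC = 3, SD = 3, MDD = 3), g = 30,
                       seed = 7)
  covs <- lapply(c("HC", "SD", "MDD"),
                 function(gr) build_group_covariance(spec0, gr))
  expect_identical(covs[[1]]$cor, covs[[2]]$cor)
  expect_identical(covs[[1]]$cor, covs[[3]]$cor)
  expect_identical(covs[[1]]$cor, covs[[1]]$base)
  expect_length(covs[[1]]$affected_nodes, 0)

  # delta_r = 0: equal to base up to the projection tolerance
  spec_zero <- cohort_spec(n_per_group = c(HC = 3, SD = 3, MDD = 3), g = 30,
                           effects = list(effect_spec("MDD", 4, 8, 0)),
                           seed = 7)
  cz <- build_group_covariance(spec_zero, "MDD")
  expect_equal(cz$cor, cz$base, tolerance = 1e-6)
  expect_equal(cz$affected_nodes, 4L)

  # delta_r = +0.3, 20 partners: entry-wise +0.3 before projection
  spec3 <- cohort_spec(n_per_group = c(HC = 3, SD = 3, MDD = 3), g = 60,
                       effects = list(effect_spec("MDD", 10, 20, 0.3)),
                       seed = 7)
  c3 <- build_group_covariance(spec3, "MDD")
  partners <- setdiff(((10 - 1 + 1:20) %% 60) + 1, 10)
  expect_equal(c3$raw[10, partners], c3$base[10, partners] + 0.3)
  expect_equal(mean(c3$raw[10, partners]) - mean(c3$base[10, partners]), 0.3)
  # unaffected group untouched
  chc <- build_group_covariance(spec3, "HC")
  expect_identical(chc$cor, chc$base)
  # result is a positive-definite correlation matrix
  expect_equal(diag(c3$cor), rep(1, 60))
  expect_true(min(eigen(c3$cor, symmetric = TRUE,
                        only.values = TRUE)$values) > 0)
  expect_equal(c3$cor, t(c3$cor))
})

test_that("an effect driving |r| past 1 is rejected with a diagnostic", {
  spec <- cohort_spec(n_per_group = c(HC = 3, SD = 3, MDD = 3), g = 30,
                      effects = list(effect_spec("SD", 2, 5, 0.95)),
                      seed = 1)
  expect_error(build_group_covariance(spec, "SD"), "hub 2.*0\\.95|0\\.95.*hub 2")
})

test_that("generation is reproducible and respects the stated world", {
  spec <- cohort_spec(n_per_group = c(HC = 2, SD = 2, MDD = 2), g = 15,
                      n_volumes = 60, seed = 11)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$subjects, c2$subjects)

  s <- c1$subjects[[1]]
  expect_equal(dim(s$series), c(60, 15))
  expect_equal(dim(s$realignment), c(60, 6))
  expect_false(any(!is.finite(s$series)))
  expect_true(all(sapply(c1$subjects, function(x) x$group) ==
                    rep(c("HC", "SD", "MDD"), each = 2)))
  # clinical scores attach to the right groups
  expect_true(all(is.na(sapply(c1$subjects[5:6], `[[`, "bdi"))))
  expect_true(all(!is.na(sapply(c1$subjects[5:6], `[[`, "hamd"))))
})

test_that("a subject's draw does not depend on other groups' sizes", {
  s1 <- generate_cohort(cohort_spec(n_per_group = c(HC = 2, SD = 2, MDD = 2),
                                    g = 12, n_volumes = 40, seed = 5))
  s2 <- generate_cohort(cohort_spec(n_per_group = c(HC = 4, SD = 2, MDD = 2),
                                    g = 12, n_volumes = 40, seed = 5))
  mdd1 <- s1$subjects[[which(sapply(s1$subjects, `[[`, "group") == "MDD")[1]]]
  mdd2 <- s2$subjects[[which(sapply(s2$subjects, `[[`, "group") == "MDD")[1]]]
  expect_identical(mdd1$series, mdd2$series)
})

test_that("ar_coefficient = 0 gives white-noise lag-1 autocorrelation", {
  spec <- cohort_spec(n_per_group = c(HC = 2, SD = 2, MDD = 2), g = 40,
                      n_volumes = 2000, ar_coefficient = 0, seed = 3)
  s <- generate_cohort(spec)$subjects[[1]]$series
  ac1 <- apply(s, 2, function(x) stats::cor(x[-1], x[-length(x)]))
  expect_lt(abs(mean(ac1)), 0.02)
})

test_that("ar_coefficient is recovered in sample autocorrelation", {
  spec <- cohort_spec(n_per_group = c(HC = 2, SD = 2, MDD = 2), g = 40,
                      n_volumes = 4000, ar_coefficient = 0.5, seed = 3)
  s <- generate_cohort(spec)$subjects[[1]]$series
  ac1 <- apply(s, 2, function(x) stats::cor(x[-1], x[-length(x)]))
  expect_equal(mean(ac1), 0.5, tolerance = 0.05)
})

test_that("sample correlations converge to the group matrix as T grows", {
  dev_at <- function(tt) {
    spec <- cohort_spec(n_per_group = c(HC = 2, SD = 2, MDD = 2), g = 20,
                        n_volumes = tt, ar_coefficient = 0, seed = 9)
    target <- build_group_covariance(spec, "HC")$cor
    s <- generate_cohort(spec)$subjects[[1]]$series
    max(abs(stats::cor(s) - target))
  }
  devs <- vapply(c(100, 1000, 10000), dev_at, numeric(1))
  expect_true(devs[2] < devs[1] && devs[3] < devs[2])
  expect_lt(devs[3], 0.06)
})

test_that("motion spikes are Poisson-consistent and trigger exclusions", {
  # spike count across many subjects matches the configured rate
  spec <- cohort_spec(n_per_group = c(HC = 30, SD = 30, MDD = 30), g = 3,
                      n_volumes = 100,
                      motion_model = list(spike_rate = 0.05,
                                          spike_amplitude = 3,
                                          drift_scale = 0.001),
                      seed = 21)
  coh <- generate_cohort(spec)
  # count FD excursions well above the drift floor
  n_spikes <- sum(sapply(coh$subjects, function(s)
    sum(compute_fd(s$realignment) > 1)))
  # each single-volume spike produces two large FD values
  lambda <- 0.05 * 100 * 90 * 2
  expect_gt(stats::ppois(n_spikes, lambda), 0.005)
  expect_lt(stats::ppois(n_spikes, lambda), 0.995)

  # 3 mm spikes at high rate: at least one subject fails the exclusion rules
  prep <- prep_cohort(coh)
  expect_gt(sum(prep$qc$excluded), 0)
})
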