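make_pheno <- function(n_per_group, seed = 1) {
  set.seed(seed)
  n <- sum(n_per_group)
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = rep(c("HC", "SD", "MDD"), n_per_group),
    age = rnorm(n, 20, 2),
    sex = sample(c("female", "male"), n, replace = TRUE),
    education = rnorm(n, 13, 1),
    mean_fd = abs(rnorm(n, 0.1, 0.03)),
    stringsAsFactors = FALSE)
}

test_that("nodewise ANOVA handles degenerate and null nodes correctly", {
  ph <- make_pheno(c(12, 12, 12), seed = 2)
  set.seed(3)
  dc <- matrix(rnorm(36 * 5, 100, 10), 36, 5,
               dimnames = list(ph$subject_id, paste0("n", 1:5)))
  dc[, 3] <- 50  # identical DC across all subjects

  res <- nodewise_anova(dc, ph)
  expect_equal(res$f_statistic[3], 0)
  expect_equal(res$p_raw[3], 1)
  expect_equal(res$p_bonf, pmin(1, res$p_raw * 5))
  expect_identical(res$significant, res$p_bonf < 0.05)
  # Bonferroni is monotone (up to ties from capping at 1)
  expect_true(all(diff(res$p_bonf[order(res$p_raw)]) >= 0))
})

test_that("ANOVA F reduces to the classical statistic without covariates", {
  ph <- make_pheno(c(10, 10, 10), seed = 5)
  set.seed(6)
  y <- rnorm(30, 10, 2) + (ph$group == "MDD") * 3
  dc <- matrix(y, 30, 1, dimnames = list(ph$subject_id, "n1"))

  res <- nodewise_anova(dc, ph, covariates = character(0))
  ref <- stats::anova(stats::lm(y ~ factor(ph$group)))
  expect_equal(res$f_statistic, ref$`F value`[1])
  expect_equal(res$p_raw, ref$`Pr(>F)`[1])
})

test_that("post-hoc t equals the pooled two-sample t without covariates", {
  ph <- make_pheno(c(10, 10, 10), seed = 7)
  set.seed(8)
  y <- rnorm(30)
  dc <- matrix(y, 30, 1, dimnames = list(ph$subject_id, "n1"))

  res <- posthoc_pairwise(dc, ph, c("MDD", "HC"), "n1",
                          covariates = character(0))
  sel <- ph$group %in% c("MDD", "HC")
  ref <- stats::t.test(y[sel][ph$group[sel] == "MDD"],
                       y[sel][ph$group[sel] == "HC"], var.equal = TRUE)
  expect_equal(res$t_statistic, unname(ref$statistic))
  expect_equal(res$p_raw, ref$p.value)
  # one node tested: adjusted p equals raw p
  expect_equal(res$p_bonf, res$p_raw)
})

test_that("post-hoc records direction and respects the Bonferroni family", {
  ph <- make_pheno(c(15, 15, 15), seed = 9)
  set.seed(10)
  dc <- matrix(rnorm(45 * 4, 50, 4), 45, 4,
               dimnames = list(ph$subject_id, paste0("n", 1:4)))
  dc[ph$group == "MDD", 2] <- dc[ph$group == "MDD", 2] + 15

  res <- posthoc_pairwise(dc, ph, c("MDD", "HC"), paste0("n", 1:4))
  expect_equal(res$p_bonf, pmin(1, res$p_raw * 4))
  expect_true(res$significant[2])
  expect_equal(res$direction[2], "MDD > HC")

  rev_res <- posthoc_pairwise(dc, ph, c("HC", "MDD"), "n2")
  expect_equal(rev_res$direction, "MDD > HC")

  empty <- suppressMessages(posthoc_pairwise(dc, ph, c("MDD", "HC"),
                                             character(0)))
  expect_equal(nrow(empty), 0)
})

test_that("covariate adjustment removes a planted mean-FD confound", {
  # mean_fd couples to group and additively to DC: the adjusted test must
  # stay calibrated while the unadjusted test inflates
  n_rep <- 150
  set.seed(11)
  p_adj <- p_un <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    ph <- make_pheno(c(12, 12, 12), seed = 1000 + r)
    ph$mean_fd <- abs(rnorm(36, 0.1, 0.02)) +
      0.12 * (ph$group == "MDD")      # motion differs by group
    y <- rnorm(36, 0, 1) + 40 * ph$mean_fd  # DC driven by motion only
    dc <- matrix(y, 36, 1, dimnames = list(ph$subject_id, "n1"))
    p_adj[r] <- nodewise_anova(dc, ph, covariates = "mean_fd")$p_raw
    p_un[r] <- nodewise_anova(dc, ph, covariates = character(0))$p_raw
  }
  expect_lt(mean(p_adj < 0.05), 0.12)
  expect_gt(mean(p_un < 0.05), 0.5)
})

test_that("null pairwise comparisons stay within the Bonferroni budget", {
  # identical group distributions: expected false-positive count per
  # replicate after Bonferroni is <= alpha
  n_rep <- 120
  n_nodes <- 20
  set.seed(12)
  fp <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    ph <- make_pheno(c(10, 10, 10), seed = 2000 + r)
    dc <- matrix(rnorm(30 * n_nodes, 60, 5), 30, n_nodes,
                 dimnames = list(ph$subject_id, paste0("n", 1:n_nodes)))
    res <- posthoc_pairwise(dc, ph, c("MDD", "HC"), paste0("n", 1:n_nodes))
    fp[r] <- sum(res$significant)
  }
  # mean FP count <= alpha, allowing Monte-Carlo slack (binomial upper bound)
  expect_lt(mean(fp), 0.05 + 2 * sqrt(0.05 / n_rep))
})

test_that("a constant covariate is dropped with a warning, not an error", {
  ph <- make_pheno(c(8, 8, 8), seed = 13)
  ph$education <- 13
  set.seed(14)
  dc <- matrix(rnorm(24 * 2), 24, 2,
               dimnames = list(ph$subject_id, c("n1", "n2")))
  expect_warning(res <- nodewise_anova(dc, ph), "education")
  expect_equal(nrow(res), 2)
})

test_that("demographic tests match independent computations", {
  # sex counts (16/17, 16/10, 27/11): chi-squared cross-checked by hand
  sex <- c(rep(c("female", "male"), c(16, 17)),
           rep(c("female", "male"), c(16, 10)),
           rep(c("female", "male"), c(27, 11)))
  grp <- rep(c("HC", "SD", "MDD"), c(33, 26, 38))
  set.seed(15)
  ph <- data.frame(subject_id = sprintf("s%02d", 1:97), group = grp,
                   sex = sex, age = rnorm(97, 20, 2),
                   education = rnorm(97, 13, 1),
                   bdi = ifelse(grp == "MDD", NA,
                                ifelse(grp == "SD", rnorm(97, 22.46, 7.73),
                                       rnorm(97, 1.55, 1.44))))
  res <- demographic_tests(ph)

  tab <- table(sex, grp)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - expected)^2 / expected)
  p_hand <- stats::pchisq(x2, df = 2, lower.tail = FALSE)
  expect_equal(res$statistic[res$variable == "sex"], x2)
  expect_equal(res$p_value[res$variable == "sex"], p_hand)
  # plausibility against the published table for these counts (p = 0.150)
  expect_gt(res$p_value[res$variable == "sex"], 0.10)
  expect_lt(res$p_value[res$variable == "sex"], 0.20)

  # BDI-II separation (means 1.55 vs 22.46) is overwhelming
  expect_lt(res$p_value[res$variable == "bdi"], 0.001)

  # identical group compositions: nothing significant
  ph_null <- make_pheno(c(20, 20, 20), seed = 19)
  res_null <- demographic_tests(ph_null)
  expect_true(all(res_null$p_value > 0.05))
})
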