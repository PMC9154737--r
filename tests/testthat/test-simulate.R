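test_that("identical config and seed give identical datasets", {
  cfg <- sim_config(n_pn = 40, n_control = 40,
                    qc_violation_rates = list(ei_bmr = 0.05,
                                              energy_discrepancy = 0.03,
                                              unfeasible = 0.03))
  a <- simulate_trial(cfg, seed = 12345)
  b <- simulate_trial(cfg, seed = 12345)
  expect_identical(a, b)
  c <- simulate_trial(cfg, seed = 54321)
  expect_false(identical(a$cohort$visits, c$cohort$visits))
})

test_that("generated intakes round-trip through the scoring engine", {
  base <- generate_baseline(sim_config(n_pn = 25, n_control = 25), seed = 2)
  for (pid in sample(base$cohort$participants$participant_id, 10)) {
    prof <- maheitrial:::cohort_profile(base$cohort, pid, "ffq1")
    sc <- score_profile(prof)
    expect_equal(unname(sc$component_scores[colnames(base$scores)]),
                 unname(base$scores[pid, ]), tolerance = 1e-6)
  }
})

test_that("baseline score draws hit the configured moments", {
  mom <- baseline_score_moments()
  cfg <- sim_config(n_pn = 10000, n_control = 1)
  set.seed(77)
  # overall-score generator: control arm targets mean 58.9, sd 12.3
  d <- simulate_overall_trial(n_pn = 1, n_control = 10000, seed = 77)
  ctl <- d$baseline[d$group == "control"]
  expect_equal(mean(ctl), 58.9, tolerance = 0.02 * 58.9)
  expect_equal(sd(ctl), 12.3, tolerance = 0.04 * 12.3)  # truncation shaves a little

  # degenerate SD: every draw at the configured mean
  d0 <- simulate_overall_trial(n_pn = 0, n_control = 50, control_sd = 1e-9,
                               change_sd = 1e-9, seed = 1)
  expect_equal(d0$baseline, rep(58.9, 50), tolerance = 1e-6)
})

test_that("fair-coin allocation stays within binomial bounds", {
  cfg <- sim_config(n_pn = 5000, n_control = 5000, allocation = "random")
  base <- generate_baseline(cfg, seed = 4)
  n <- nrow(base$cohort$participants)
  p_pn <- mean(base$cohort$participants$group == "pn")
  expect_lt(abs(p_pn - 0.5), 3 * sqrt(0.25 / n))
})

test_that("zero effects and zero noise leave endpoint equal to baseline", {
  cfg <- sim_config(n_pn = 15, n_control = 15, component_change_sd = 0,
                    shared_change_sd = 0, regression_to_mean = 0)
  base <- generate_baseline(cfg, seed = 9)
  iv <- apply_intervention(base, cfg, seed = 9)
  expect_equal(iv$scores, base$scores, tolerance = 1e-12)
  expect_equal(iv$n_clamped, 0)
  expect_false(any(iv$targeted))
})

test_that("an injected overall effect appears as the PN-control change gap", {
  cfg <- sim_config(n_pn = 4000, n_control = 4000, overall_effect = 3.5,
                    component_change_sd = 5, shared_change_sd = 2)
  base <- generate_baseline(cfg, seed = 21)
  iv <- apply_intervention(base, cfg, seed = 22)
  grp <- base$cohort$participants$group
  chg <- rowMeans(iv$scores) - rowMeans(base$scores)
  gap <- mean(chg[grp == "pn"]) - mean(chg[grp == "control"])
  expect_equal(gap, 3.5, tolerance = 0.35)
  expect_true(all(iv$targeted[grp == "pn", ]))
})

test_that("component-targeted effects land only on selected components", {
  eff <- setNames(rep(10, 11), fix_criteria$name)
  cfg <- sim_config(n_pn = 20, n_control = 20, component_effects = as.list(eff),
                    component_change_sd = 0, shared_change_sd = 0,
                    regression_to_mean = 0)
  base <- generate_baseline(cfg, seed = 33)
  iv <- apply_intervention(base, cfg, seed = 33)
  grp <- base$cohort$participants$group
  delta <- iv$scores - base$scores
  # noise-free: change is exactly 10 on targeted cells, 0 elsewhere
  # (up to clamping at 100)
  for (i in which(grp == "pn")) {
    sel <- select_advice_components(base$scores[i, ], 3)$component
    expect_true(all(iv$targeted[i, sel]))
    expect_equal(sum(iv$targeted[i, ]), 3)
    untouched <- setdiff(colnames(delta), sel)
    expect_equal(unname(delta[i, untouched]), rep(0, 8))
  }
  expect_false(any(iv$targeted[grp == "control", ]))
})

test_that("dropout and visit schedule honour the study protocol", {
  cfg0 <- sim_config(n_pn = 40, n_control = 40, dropout_rate = 0, p_all3 = 1)
  sim0 <- simulate_trial(cfg0, seed = 3)
  nv <- table(sim0$cohort$visits$participant_id)
  expect_true(all(nv == 3))
  # FFQ 2/3 dates respect the 41- and 83-day availability gates
  v <- sim0$cohort$visits
  expect_true(all(v$day[v$visit == "ffq2"] >= 41))
  expect_true(all(v$day[v$visit == "ffq3"] >= 83))
  expect_true(all(abs(v$day[v$visit == "ffq3"] - 84) <= 7 + 1))

  # 35.4% dropout on n=325: completers within binomial bounds of 210
  cfg1 <- sim_config(n_pn = 163, n_control = 162, dropout_rate = 0.354)
  sim1 <- simulate_trial(cfg1, seed = 8)
  completers <- sum(!sim1$truth$dropout)
  expect_lt(abs(completers - 325 * 0.646), 3 * sqrt(325 * 0.354 * 0.646))
})

test_that("planted violation counts follow the configured rates", {
  rates <- list(ei_bmr = 0.05, energy_discrepancy = 0.02, unfeasible = 0.03)
  cfg <- sim_config(n_pn = 500, n_control = 500, dropout_rate = 0,
                    qc_violation_rates = rates)
  sim <- simulate_trial(cfg, seed = 55)
  counts <- table(factor(sim$truth$qc_labels$planted,
                         c("ei_bmr", "energy_discrepancy", "unfeasible_intake")))
  n <- 1000
  exp_n <- c(0.05, 0.02, 0.03) * n
  for (i in 1:3) {
    expect_lt(abs(counts[i] - exp_n[i]),
              3 * sqrt(exp_n[i] * (1 - exp_n[i] / n)) + 1)
  }
  # all-zero rates leave the cohort untouched
  cfg0 <- sim_config(n_pn = 30, n_control = 30, dropout_rate = 0)
  sim0 <- simulate_trial(cfg0, seed = 56)
  expect_true(all(sim0$truth$qc_labels$planted == "none"))
})

test_that("generated cohorts satisfy the schema invariants", {
  sim <- simulate_trial(sim_config(n_pn = 30, n_control = 30), seed = 61)
  expect_s3_class(sim$cohort, "mahei_cohort")
  expect_true(all(sim$cohort$intakes$amount >= 0))
  expect_true(all(sim$cohort$foods$contribution >= 0))
  expect_true(all(sim$truth$baseline_scores >= 0 &
                  sim$truth$baseline_scores <= 100))
  # profile invariants enforceable per participant-visit
  prof <- maheitrial:::cohort_profile(sim$cohort, "P0001", "ffq1")
  expect_s3_class(prof, "intake_profile")
})
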