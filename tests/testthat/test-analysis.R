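test_that("D'Agostino-Pearson omnibus matches independently computed values", {
  # frozen oracle values computed once with an independent implementation
  # of the same published approximations
  x <- c(2.3, 4.1, 3.3, 5.0, 2.2, 6.1, 3.7, 4.4, 2.9, 5.5, 3.1, 4.8, 2.6,
         3.9, 4.2, 5.9, 3.0, 4.6, 2.8, 5.2)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 2.063892639081445, tolerance = 1e-12)
  expect_equal(r$p_value, 0.35631278670683086, tolerance = 1e-12)

  y <- c(0.12, 0.45, 0.89, 1.7, 2.6, 0.33, 0.05, 4.2, 0.77, 1.1, 0.25, 3.3,
         0.6, 0.18, 2.1, 0.95, 5.6, 0.4, 1.45, 0.08, 0.7, 2.9, 0.22, 1.9, 0.5)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 13.01329011920724, tolerance = 1e-12)
  expect_equal(r2$p_value, 0.0014934818700721977, tolerance = 1e-12)

  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
  expect_error(dagostino_pearson(rep(1, 20)), "constant")
})

test_that("normality_check calibrates on normal and flags skewed samples", {
  set.seed(42)
  norm <- normality_check(rnorm(500))
  expect_true(all(norm$p_value > 0.05))
  skew <- normality_check(rexp(500))
  expect_true(all(skew$p_value < 0.05))
  expect_warning(small <- normality_check(rnorm(6)), "omitted")
  expect_true(is.na(small$p_value[small$test == "dagostino_pearson"]))
  expect_warning(normality_check(rep(2, 30)), "degenerate")
})

test_that("transforms apply as declared and refuse negatives under sqrt", {
  v <- c(0, 1, 4, 9)
  expect_equal(apply_transform(v, outcome_spec("x", "identity")), v)
  expect_equal(apply_transform(v, outcome_spec("x", "sqrt")), c(0, 1, 2, 3))
  scores <- runif(20, 0, 100)
  expect_true(all(apply_transform(scores, "sqrt") <= 10))
  expect_error(apply_transform(c(-1, 4), "sqrt"), "non-negative")
})

test_that("ANCOVA coefficient equals the closed-form normal-equations solution", {
  # 6-participant worked fixture
  change <- c(1.2, 0.8, 2.0, 3.1, 2.5, 3.9)
  group <- c("control", "control", "control", "pn", "pn", "pn")
  covar <- c(5.0, 6.2, 5.5, 5.1, 6.8, 5.9)

  fit <- ancova_effect(change, group, covar)

  X <- cbind(1, as.numeric(group == "pn"), covar)
  beta <- solve(t(X) %*% X, t(X) %*% change)    # independent OLS oracle
  expect_equal(fit$effect, as.numeric(beta[2, 1]), tolerance = 1e-8)

  # CI brackets the estimate
  expect_lte(fit$ci[1], fit$effect); expect_gte(fit$ci[2], fit$effect)
})

test_that("ANCOVA reduces to the two-sample mean difference without covariate", {
  set.seed(7)
  group <- rep(c("control", "pn"), each = 25)
  change <- rnorm(50, 1) + 2 * (group == "pn")

  raw_diff <- mean(change[group == "pn"]) - mean(change[group == "control"])
  f0 <- ancova_effect(change, group)
  expect_equal(f0$effect, raw_diff, tolerance = 1e-8)
  # constant covariate carries no information: same reduction
  fc <- ancova_effect(change, group, covariate = rep(3, 50))
  expect_equal(fc$effect, raw_diff, tolerance = 1e-8)
  # and the interval matches the equal-variance two-sample t oracle
  tt <- t.test(change[group == "pn"], change[group == "control"],
               var.equal = TRUE)
  expect_equal(unname(f0$ci), as.numeric(tt$conf.int), tolerance = 1e-8)

  # identical change vectors in both arms -> zero effect
  same <- rep(c(1, 2, 3, 4), 2)
  expect_equal(ancova_effect(same, rep(c("control", "pn"), each = 4))$effect, 0)

  expect_error(ancova_effect(change, rep("pn", 50)), "two groups")
  expect_error(ancova_effect(change[1:5], group[c(1, 2, 26, 27, 28)]), "n >= 3")
})

test_that("mahei_ancova methods expose the fit", {
  set.seed(8)
  group <- rep(c("control", "pn"), each = 20)
  covar <- rnorm(40, 8000, 1000)
  change <- 0.001 * covar + rnorm(40) + 1.5 * (group == "pn")
  fit <- ancova_effect(change, group, covar)
  expect_named(coef(fit), "effect_pn")
  expect_equal(unname(confint(fit)), fit$ci)
  expect_length(residuals(fit), 40)
  expect_equal(nrow(fit$adjusted), 2)
  # adjusted per-arm deltas differ by the effect
  expect_equal(diff(fit$adjusted$adj_change), fit$effect, tolerance = 1e-8)
  expect_output(print(fit), "effect pn - control")
})

test_that("power calculation reproduces the recruitment target arithmetic", {
  ps <- power_sample_size(49.58, 9.51, 0.065, alpha = 0.05, power = 0.8)
  expect_equal(ps$total, 274)
  expect_equal(ps$per_arm, 137)
  expect_equal(ps$absolute_effect, 0.065 * 49.58)

  # doubling the SD quadruples the per-arm n (up to ceiling)
  p1 <- power_sample_size(50, 5, 0.1)$per_arm
  p2 <- power_sample_size(50, 10, 0.1)$per_arm
  expect_true(abs(p2 - 4 * p1) <= 4)

  # power 0.5 closed-form limit: z_power = 0
  p3 <- power_sample_size(50, 10, 0.1, alpha = 0.05, power = 0.5)$per_arm
  expect_equal(p3, ceiling(2 * qnorm(0.975)^2 * 10^2 / 5^2))

  # monotone: bigger effect -> no more n; more power/sd -> no less n
  expect_lte(power_sample_size(50, 10, 0.2)$per_arm,
             power_sample_size(50, 10, 0.1)$per_arm)
  expect_gte(power_sample_size(50, 12, 0.1)$per_arm,
             power_sample_size(50, 10, 0.1)$per_arm)
  expect_gte(power_sample_size(50, 10, 0.1, power = 0.9)$per_arm,
             power_sample_size(50, 10, 0.1, power = 0.8)$per_arm)
  expect_error(power_sample_size(50, 10, 0), "zero effect")
})

test_that("dropout inflation reports both conventions", {
  expect_equal(inflate_for_dropout(100, 0)$inflated, 100)
  expect_equal(inflate_for_dropout(100, 0.2)$inflated, 120)
  d <- inflate_for_dropout(274, 0.2)
  expect_equal(d$multiplicative, ceiling(274 * 1.2))  # 329
  expect_equal(d$divisor, ceiling(274 / 0.8))         # 343
  expect_error(inflate_for_dropout(100, 1), "dropout_rate")
})

test_that("message frequency totals equal 3 messages per participant", {
  sim <- simulate_trial(sim_config(n_pn = 40, n_control = 35, dropout_rate = 0),
                        seed = 31)
  ds <- trial_dataset(sim$cohort)
  tab <- message_frequency_table(ds)
  tot <- attr(tab, "totals")
  expect_equal(sum(tab$n_control), 3 * 35)
  expect_equal(sum(tab$n_pn), 3 * 40)
  expect_equal(unname(tot["total"]), 3 * 75)
  expect_equal(sum(tab$n_total), unname(tot["total"]))
})

test_that("matched subgroup reduces to the whole cohort when universal", {
  sim <- simulate_trial(sim_config(n_pn = 30, n_control = 30, dropout_rate = 0),
                        seed = 17)
  ds <- trial_dataset(sim$cohort)
  # force one component into everyone's lowest three
  ds$alcohol_baseline <- 0
  sub <- matched_subgroup_effect(ds, "alcohol")
  expect_true(sub$estimable)
  expect_equal(sum(sub$membership$n), nrow(ds))
  whole <- trial_effects(ds, default_outcome_specs()["alcohol"])
  expect_equal(sub$fit$effect, whole$fits$alcohol$effect, tolerance = 1e-10)

  # and flags non-estimable when (almost) no one selects the component
  ds2 <- trial_dataset(sim$cohort)
  ds2$dairy_baseline <- 100
  ds2[, setdiff(paste0(fix_criteria$name, "_baseline"), "dairy_baseline")] <- 1
  sub2 <- matched_subgroup_effect(ds2, "dairy")
  expect_false(sub2$estimable)
  expect_null(sub2$fit)
})

test_that("membership is invariant to participant ordering", {
  sim <- simulate_trial(sim_config(n_pn = 20, n_control = 20, dropout_rate = 0),
                        seed = 23)
  ds <- trial_dataset(sim$cohort)
  m1 <- baseline_selections(ds)
  perm <- sample(nrow(ds))
  m2 <- baseline_selections(ds[perm, ])
  expect_equal(m2[rownames(m1), ], m1)
})

test_that("BMI outcomes: unchanged weights give zero effects", {
  sim <- simulate_trial(sim_config(n_pn = 25, n_control = 25, dropout_rate = 0),
                        seed = 13)
  ds <- trial_dataset(sim$cohort)
  ds$weight_endpoint <- ds$weight_baseline
  bo <- bmi_outcomes(ds)
  expect_equal(bo$bmi$effect, 0, tolerance = 1e-10)
  expect_equal(bo$distance$effect, 0, tolerance = 1e-10)

  # a participant exactly at the ideal midpoint has distance 0 at both visits
  h <- ds$height_m[1]
  ds$weight_baseline[1] <- ds$weight_endpoint[1] <- 21.75 * h^2
  expect_equal(abs(ds$weight_baseline[1] / h^2 - 21.75), 0)

  # synthetic pull toward 21.75 in the intervention arm -> negative effect
  pn <- ds$group == "pn"
  bmi_b <- ds$weight_baseline / ds$height_m^2
  target <- 21.75 + 0.8 * (bmi_b - 21.75)   # move 20% toward ideal
  ds$weight_endpoint[pn] <- target[pn] * ds$height_m[pn]^2
  bo2 <- bmi_outcomes(ds)
  expect_lt(bo2$distance$effect, 0)

  ds$weight_endpoint[2] <- NA
  expect_warning(bmi_outcomes(ds), "dropped")
})
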