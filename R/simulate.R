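#' Baseline m-AHEI component score moments, by arm
#'
#' Per-arm baseline mean (SD) of each component score and of the overall
#' score, used to calibrate the synthetic cohort generator to the trial's
#' observed baseline distributions (control overall 58.9 SD 12.3,
#' intervention 56.3 SD 11.5).
#'
#' @return Named list (`control`, `pn`) of data frames
#'   `component`, `mean`, `sd`.
#' @export
baseline_score_moments <- function() {
  comp <- c("vegetables", "fruit", "whole_grains", "dairy", "nuts_legumes",
            "healthy_fats", "oily_fish", "free_sugars", "red_processed_meat",
            "salt", "alcohol")
  list(
    control = data.frame(component = comp,
      mean = c(68.0, 67.0, 43.5, 87.7, 47.3, 53.4, 63.0, 44.3, 27.5, 55.9, 90.2),
      sd = c(26.0, 31.0, 35.4, 27.8, 38.3, 17.7, 41.7, 27.7, 36.6, 34.4, 27.2),
      stringsAsFactors = FALSE),
    pn = data.frame(component = comp,
      mean = c(61.2, 60.6, 35.5, 95.0, 26.7, 50.8, 69.2, 50.5, 24.4, 57.0, 88.7),
      sd = c(28.3, 34.8, 33.9, 18.1, 33.1, 16.7, 38.0, 26.8, 36.1, 30.7, 27.8),
      stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Defaults reproduce the trial's observed conditions: arm sizes 96
#' (intervention) and 91 (control), per-arm baseline component score
#' distributions, 35.4% post-baseline dropout, per-arm energy-intake
#' changes (intervention -1316 SD 2315 kJ/day, control -726 SD 2549), and
#' visit dates jittered around the 42- and 84-day targets while honouring
#' the 41/83-day FFQ availability gates.
#'
#' @param n_pn,n_control arm sizes.
#' @param baseline_moments per-arm component score moments
#'   ([baseline_score_moments()]).
#' @param overall_effect true additive intervention effect on the overall
#'   score change (spread uniformly over all 11 components); `NULL` for
#'   none.
#' @param component_effects named vector of per-component true effects,
#'   injected only into each intervention participant's 3 lowest baseline
#'   components ("component-targeted" mode); `NULL` for none.
#' @param component_change_sd SD of the independent per-component change
#'   noise (score points).
#' @param shared_change_sd SD of the participant-level change component
#'   shared across all 11 components; together with `component_change_sd`
#'   this sets the overall-score change SD at about
#'   `sqrt(shared^2 + comp^2/11)` (~8 points at the defaults, matching the
#'   precision of the trial's printed overall-effect CI).
#' @param regression_to_mean pull strength r in
#'   `change = mu - r (sd_c/sd_b) (baseline - mu_b) + noise`.
#' @param energy_mean,energy_sd baseline energy intake, kJ/day.
#' @param energy_change per-arm list `c(mean, sd)` of the endpoint energy
#'   change, kJ/day.
#' @param dropout_rate probability of no post-baseline FFQ.
#' @param p_all3 probability, among completers, of completing all 3 FFQs.
#' @param qc_violation_rates list with `ei_bmr`, `energy_discrepancy`,
#'   `unfeasible` planting rates.
#' @param female_ratio,age_mean,age_sd,bmi_mean,bmi_sd demographics.
#' @param allocation `"fixed"` (exact arm sizes) or `"random"` (fair-coin
#'   uniform draw with 0.5 threshold, as the deployed app randomized).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_pn = 96, n_control = 91,
                       baseline_moments = baseline_score_moments(),
                       overall_effect = NULL,
                       component_effects = NULL,
                       component_change_sd = 15,
                       shared_change_sd = 7,
                       regression_to_mean = 0.5,
                       energy_mean = 8500, energy_sd = 1500,
                       energy_change = list(pn = c(-1316, 2315),
                                            control = c(-726, 2549)),
                       dropout_rate = 0.354,
                       p_all3 = 0.55,
                       qc_violation_rates = list(ei_bmr = 0,
                                                 energy_discrepancy = 0,
                                                 unfeasible = 0),
                       female_ratio = 0.78,
                       age_mean = 43.2, age_sd = 15,
                       bmi_mean = 24.5, bmi_sd = 4.4,
                       allocation = c("fixed", "random")) {
  stopifnot(n_pn >= 1, n_control >= 1, energy_sd > 0,
            dropout_rate >= 0, dropout_rate < 1,
            all(unlist(qc_violation_rates) >= 0),
            all(unlist(qc_violation_rates) < 1))
  structure(list(n_pn = n_pn, n_control = n_control,
                 baseline_moments = baseline_moments,
                 overall_effect = overall_effect,
                 component_effects = component_effects,
                 component_change_sd = component_change_sd,
                 shared_change_sd = shared_change_sd,
                 regression_to_mean = regression_to_mean,
                 energy_mean = energy_mean, energy_sd = energy_sd,
                 energy_change = energy_change,
                 dropout_rate = dropout_rate, p_all3 = p_all3,
                 qc_violation_rates = qc_violation_rates,
                 female_ratio = female_ratio,
                 age_mean = age_mean, age_sd = age_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 allocation = match.arg(allocation)),
            class = "sim_config")
}

# energy plausibility window for one participant: inside the EI/BMR cutoffs
# with margin, so only *planted* violations trip the QC filters
energy_bounds <- function(bmr, sex) {
  high <- if (sex == "male") 2.79 else 3.21
  c(lo = 0.8 * bmr, hi = 0.9 * high * bmr)
}

#' Generate a baseline cohort
#'
#' Demographics, allocation, baseline component scores drawn from truncated
#' normals on \[0, 100\] with the configured per-arm moments, then
#' inverse-mapped through the scoring criteria to intake amounts — so
#' [score_profile()] recovers the drawn scores exactly. Per-food records
#' are fabricated to sum to the component amounts. Baseline energy is drawn
#' within each participant's EI/BMR plausibility window.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param criteria a [mahei_criteria()] set.
#' @return List: `cohort` (a [mahei_cohort()], baseline visit only),
#'   `scores` (matrix of drawn baseline scores), `bmr` (per participant).
#' @export
generate_baseline <- function(config = sim_config(), seed = NULL,
                              criteria = mahei_criteria()) {
  if (!is.null(seed)) set.seed(seed)
  if (config$allocation == "fixed") {
    group <- c(rep("pn", config$n_pn), rep("control", config$n_control))
  } else {
    n <- config$n_pn + config$n_control
    group <- ifelse(stats::runif(n) < 0.5, "pn", "control")
  }
  n <- length(group)
  ids <- sprintf("P%04d", seq_len(n))
  sex <- ifelse(stats::runif(n) < config$female_ratio, "female", "male")
  age <- round(rtruncnorm(n, config$age_mean, config$age_sd, 18, 85))
  height <- ifelse(sex == "female",
                   rtruncnorm(n, 1.63, 0.065, 1.45, 1.85),
                   rtruncnorm(n, 1.77, 0.070, 1.55, 1.95))
  bmi <- rtruncnorm(n, config$bmi_mean, config$bmi_sd, 17, 40)
  weight <- bmi * height^2
  bmr <- henry_bmr(sex, age, weight)

  # baseline scores: truncated normal per component, arm-specific moments
  scores <- matrix(NA_real_, n, nrow(criteria),
                   dimnames = list(ids, criteria$name))
  for (arm in c("pn", "control")) {
    idx <- which(group == arm)
    mom <- config$baseline_moments[[arm]]
    for (j in seq_len(nrow(criteria))) {
      m <- mom$mean[mom$component == criteria$name[j]]
      s <- mom$sd[mom$component == criteria$name[j]]
      scores[idx, j] <- rtruncnorm(length(idx), m, s, 0, 100)
    }
  }

  energy <- vapply(seq_len(n), function(i) {
    b <- energy_bounds(bmr[i], sex[i])
    rtruncnorm(1, config$energy_mean, config$energy_sd, b["lo"], b["hi"])
  }, numeric(1))

  participants <- data.frame(participant_id = ids, group = group, sex = sex,
                             age_years = age, height_m = height,
                             stringsAsFactors = FALSE)
  visits <- data.frame(participant_id = ids, visit = "ffq1", day = 0,
                       weight_kg = round(weight, 1), energy_kj_day = energy,
                       stringsAsFactors = FALSE)
  intakes <- scores_to_intakes(scores, ids, "ffq1", criteria)
  foods <- fabricate_foods(intakes, criteria)
  list(cohort = mahei_cohort(participants, visits, intakes, foods),
       scores = scores, bmr = bmr)
}

# score -> intake via the criteria's inverse linear interpolation
scores_to_intakes <- function(scores, ids, visit, criteria) {
  long <- expand.grid(participant_id = ids, component = criteria$name,
                      stringsAsFactors = FALSE)
  j <- match(long$component, criteria$name)
  zero <- criteria$zero_score_intake[j]; full <- criteria$full_score_intake[j]
  sc <- scores[cbind(match(long$participant_id, ids), j)]
  long$visit <- visit
  long$amount <- zero + sc / 100 * (full - zero)
  long[, c("participant_id", "visit", "component", "amount")]
}

# two deterministic pseudo-foods per component covering the full amount;
# the lexicon includes the food groups with configured feasibility limits
food_lexicon <- function() {
  list(vegetables = c("carrots", "broccoli"),
       fruit = c("apples", "bananas"),
       whole_grains = c("porridge", "bread"),
       dairy = c("milk", "cheese"),
       nuts_legumes = c("nuts", "baked beans"),
       healthy_fats = c("olive oil", "sunflower spread"),
       oily_fish = c("salmon", "mackerel"),
       free_sugars = c("biscuits", "orange juice"),
       red_processed_meat = c("red meat", "bacon"),
       salt = c("crisps", "ready meals"),
       alcohol = c("wine", "beer"))
}

fabricate_foods <- function(intakes, criteria) {
  lex <- food_lexicon()
  pos <- intakes[intakes$amount > 0, , drop = FALSE]
  if (nrow(pos) == 0)
    return(data.frame(participant_id = character(), visit = character(),
                      food_id = character(), food_label = character(),
                      daily_amount = numeric(), component = character(),
                      contribution = numeric(), stringsAsFactors = FALSE))
  split1 <- stats::runif(nrow(pos), 0.5, 0.9)   # first food dominates
  f1 <- data.frame(participant_id = pos$participant_id, visit = pos$visit,
                   food_id = paste0(pos$component, "_1"),
                   food_label = vapply(pos$component, function(cmp) lex[[cmp]][1], ""),
                   daily_amount = pos$amount * split1,
                   component = pos$component,
                   contribution = pos$amount * split1,
                   stringsAsFactors = FALSE)
  f2 <- f1
  f2$food_id <- paste0(pos$component, "_2")
  f2$food_label <- vapply(pos$component, function(cmp) lex[[cmp]][2], "")
  f2$daily_amount <- pos$amount * (1 - split1)
  f2$contribution <- pos$amount * (1 - split1)
  out <- rbind(f1, f2)
  rownames(out) <- NULL
  out
}

#' Apply the intervention: endpoint scores with injected true effects
#'
#' Endpoint component scores are baseline plus a change composed of a
#' regression-to-the-mean pull, a shared participant-level shift, and
#' independent component noise; intervention participants additionally
#' receive the configured true effect — spread uniformly over all 11
#' components when `overall_effect` is set, or concentrated on each
#' participant's 3 lowest baseline components when `component_effects` is
#' set. Endpoint scores are clamped to \[0, 100\]; clamping events are
#' counted in the ground truth because they attenuate realised effects.
#'
#' @param baseline result of [generate_baseline()].
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @param criteria a [mahei_criteria()] set.
#' @return List: `scores` (endpoint score matrix), `targeted` (logical
#'   matrix of components that received injected effect), `n_clamped`.
#' @export
apply_intervention <- function(baseline, config = sim_config(), seed = NULL,
                               criteria = mahei_criteria()) {
  if (!is.null(seed)) set.seed(seed)
  sc <- baseline$scores
  group <- baseline$cohort$participants$group
  n <- nrow(sc); k <- ncol(sc)
  r <- config$regression_to_mean
  sigma_c <- config$component_change_sd

  targeted <- matrix(FALSE, n, k, dimnames = dimnames(sc))
  effect <- matrix(0, n, k, dimnames = dimnames(sc))
  is_pn <- group == "pn"
  if (!is.null(config$overall_effect)) {
    effect[is_pn, ] <- config$overall_effect
    targeted[is_pn, ] <- TRUE
  }
  if (!is.null(config$component_effects)) {
    for (i in which(is_pn)) {
      sel <- select_advice_components(sc[i, ], k = 3, criteria = criteria)
      for (comp in sel$component) {
        e <- config$component_effects[[comp]]
        if (!is.null(e) && !is.na(e)) {
          effect[i, comp] <- effect[i, comp] + e
          targeted[i, comp] <- TRUE
        }
      }
    }
  }

  # regression to the mean pulls toward the *population* component mean
  # (arms differ at baseline only by sampling), weighted by arm size so the
  # covariate-adjusted analysis model stays correctly specified
  w_pn <- config$n_pn / (config$n_pn + config$n_control)
  momp <- config$baseline_moments$pn; momc <- config$baseline_moments$control
  shared <- stats::rnorm(n, 0, config$shared_change_sd)
  change <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    comp <- colnames(sc)[j]
    mj <- w_pn * momp$mean[momp$component == comp] +
      (1 - w_pn) * momc$mean[momc$component == comp]
    sj <- w_pn * momp$sd[momp$component == comp] +
      (1 - w_pn) * momc$sd[momc$component == comp]
    pull <- -r * (sigma_c / sj) * (sc[, j] - mj)
    change[, j] <- pull + sqrt(1 - r^2) * stats::rnorm(n, 0, sigma_c)
  }
  change <- change + shared + effect
  raw <- sc + change
  clamped <- raw < 0 | raw > 100
  endpoint <- pmin(pmax(raw, 0), 100)
  list(scores = endpoint, targeted = targeted, n_clamped = sum(clamped))
}

#' Plant quality-control violations
#'
#' Randomly selected completers are modified to trip exactly one QC rule
#' each: reported energy pushed outside the sex-specific EI/BMR cutoffs, a
#' > 8000 kJ between-FFQ energy jump with flat weight, or a food amount
#' above its feasibility limit. Ground-truth labels are returned so the QC
#' pipeline can be checked against the plant.
#'
#' @param cohort a [mahei_cohort()] with baseline and endpoint visits.
#' @param bmr per-participant BMR (kJ/day), as from [generate_baseline()].
#' @param rates list `ei_bmr`, `energy_discrepancy`, `unfeasible`.
#' @param seed optional integer seed.
#' @return List: `cohort` (modified) and `labels` (data frame
#'   `participant_id`, `planted` — one rule name or `"none"`).
#' @export
plant_qc_violations <- function(cohort, bmr, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  parts <- cohort$participants
  # only participants with a post-baseline FFQ can be excluded by these rules
  eligible <- vapply(parts$participant_id, function(pid) {
    sum(cohort$visits$participant_id == pid & cohort$visits$day > 0) > 0
  }, logical(1))
  labels <- data.frame(participant_id = parts$participant_id,
                       planted = "none", stringsAsFactors = FALSE)
  u <- stats::runif(nrow(parts))
  r1 <- rates$ei_bmr %||% 0
  r2 <- rates$energy_discrepancy %||% 0
  r3 <- rates$unfeasible %||% 0
  pick <- ifelse(!eligible, "none",
          ifelse(u < r1, "ei_bmr",
          ifelse(u < r1 + r2, "energy_discrepancy",
          ifelse(u < r1 + r2 + r3, "unfeasible_intake", "none"))))
  labels$planted <- pick

  visits <- cohort$visits
  foods <- cohort$foods
  for (i in which(pick != "none")) {
    pid <- parts$participant_id[i]
    vb <- which(visits$participant_id == pid & visits$day == 0)
    pv_days <- visits$day[visits$participant_id == pid]
    ep <- select_endpoint(pv_days)
    ve <- which(visits$participant_id == pid)[ep$visit]
    if (pick[i] == "ei_bmr") {
      # EI well below the low cutoff for either sex, at both analysed FFQs
      # (flat, so the discrepancy rule is not tripped as a side effect)
      visits$energy_kj_day[vb] <- 0.3 * bmr[i]
      visits$energy_kj_day[ve] <- 0.3 * bmr[i]
    } else if (pick[i] == "energy_discrepancy") {
      visits$energy_kj_day[vb] <- 1.2 * bmr[i]
      visits$energy_kj_day[ve] <- 1.2 * bmr[i] + 8806
      visits$weight_kg[ve] <- visits$weight_kg[vb]   # flat weight
    } else {
      foods <- rbind(foods, data.frame(
        participant_id = pid, visit = visits$visit[vb],
        food_id = "planted_porridge", food_label = "porridge",
        daily_amount = 1300, component = "whole_grains", contribution = 0,
        stringsAsFactors = FALSE))
    }
  }
  cohort$visits <- visits
  cohort$foods <- foods
  list(cohort = cohort, labels = labels)
}

#' Simulate a complete labelled trial
#'
#' Full pipeline input: allocation, baseline generation, intervention with
#' injected true effects, visit schedule honouring the 41/83-day FFQ
#' gates (dates jittered uniformly around the 42/84-day targets), dropout
#' after baseline, planted QC violations, and a ground-truth sidecar.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the single source of randomness.
#' @param criteria a [mahei_criteria()] set.
#' @return List of class `mahei_sim`: `cohort` (a [mahei_cohort()]) and
#'   `truth` (allocation, baseline/endpoint score matrices, targeted
#'   components, clamp count, dropout flags, planted QC labels, config).
#' @export
simulate_trial <- function(config = sim_config(), seed = 1,
                           criteria = mahei_criteria()) {
  set.seed(seed)
  base <- generate_baseline(config, seed = NULL, criteria = criteria)
  iv <- apply_intervention(base, config, seed = NULL, criteria = criteria)
  cohort <- base$cohort
  parts <- cohort$participants
  n <- nrow(parts)

  dropout <- stats::runif(n) < config$dropout_rate
  all3 <- stats::runif(n) < config$p_all3
  which2 <- stats::runif(n) < 0.5          # single-extra-FFQ completers: which one
  day2 <- pmax(41, round(42 + stats::runif(n, -7, 7)))
  day3 <- pmax(83, round(84 + stats::runif(n, -7, 7)))

  ew <- config$energy_change
  d_w <- stats::rnorm(n, 0, 1.5)           # self-reported weight drift, kg

  visit_rows <- list(cohort$visits)
  intake_rows <- list(cohort$intakes)
  food_rows <- list(cohort$foods)
  bvis <- cohort$visits
  for (i in seq_len(n)) {
    if (dropout[i]) next
    pid <- parts$participant_id[i]
    arm <- parts$group[i]
    have <- if (all3[i]) c(2, 3) else if (which2[i]) 2 else 3
    b <- energy_bounds(base$bmr[i], parts$sex[i])
    e0 <- bvis$energy_kj_day[bvis$participant_id == pid]
    for (v in have) {
      dayv <- if (v == 2) day2[i] else day3[i]
      ev <- rtruncnorm(1, e0 + ew[[arm]][1], ew[[arm]][2],
                       max(b["lo"], e0 - 7500), min(b["hi"], e0 + 7500))
      visit_rows[[length(visit_rows) + 1]] <- data.frame(
        participant_id = pid, visit = paste0("ffq", v), day = dayv,
        weight_kg = round(bvis$weight_kg[bvis$participant_id == pid] + d_w[i], 1),
        energy_kj_day = ev, stringsAsFactors = FALSE)
      intake_rows[[length(intake_rows) + 1]] <-
        scores_to_intakes(iv$scores[i, , drop = FALSE], pid,
                          paste0("ffq", v), criteria)
    }
  }
  cohort$visits <- do.call(rbind, visit_rows)
  cohort$intakes <- do.call(rbind, intake_rows)
  # endpoint foods mirror baseline proportions at endpoint amounts
  post <- cohort$intakes[cohort$intakes$visit != "ffq1", , drop = FALSE]
  if (nrow(post)) {
    cohort$foods <- rbind(cohort$foods, fabricate_foods(post, criteria))
  }
  rownames(cohort$visits) <- rownames(cohort$intakes) <- NULL

  planted <- plant_qc_violations(cohort, base$bmr, config$qc_violation_rates,
                                 seed = NULL)
  structure(list(
    cohort = planted$cohort,
    truth = list(allocation = stats::setNames(parts$group, parts$participant_id),
                 baseline_scores = base$scores,
                 endpoint_scores = iv$scores,
                 targeted = iv$targeted,
                 n_clamped = iv$n_clamped,
                 dropout = stats::setNames(dropout, parts$participant_id),
                 qc_labels = planted$labels,
                 config = config)),
    class = "mahei_sim")
}

#' Lightweight overall-score trial simulation
#'
#' Draws only the overall m-AHEI score (baseline from the per-arm trial
#' moments, change with regression-to-the-mean pull and the configured
#' change SD, plus the injected true effect in the intervention arm). Used
#' for parameter-recovery studies where hundreds of replicate trials are
#' fitted and the full component-level machinery is unnecessary.
#'
#' @param n_pn,n_control arm sizes.
#' @param effect true additive intervention effect on the change score.
#' @param control_mean,control_sd,pn_mean,pn_sd baseline overall-score
#'   moments (defaults: the trial's 58.9/12.3 and 56.3/11.5).
#' @param change_sd overall change-score SD (default 8 points, matching the
#'   precision of the trial's printed overall-effect CI).
#' @param regression_to_mean pull strength (default 0.5).
#' @param seed optional integer seed.
#' @return Data frame `group`, `baseline`, `change`.
#' @export
simulate_overall_trial <- function(n_pn = 96, n_control = 91, effect = 0,
                                   control_mean = 58.9, control_sd = 12.3,
                                   pn_mean = 56.3, pn_sd = 11.5,
                                   change_sd = 8, regression_to_mean = 0.5,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  group <- c(rep("pn", n_pn), rep("control", n_control))
  mu <- ifelse(group == "pn", pn_mean, control_mean)
  sd_b <- ifelse(group == "pn", pn_sd, control_sd)
  baseline <- rtruncnorm(length(group), mu, sd_b, 0, 100)
  # regression to the mean pulls toward the population mean (size-weighted
  # across arms), keeping the baseline-adjusted analysis model well specified
  mu_pop <- (n_pn * pn_mean + n_control * control_mean) / (n_pn + n_control)
  sd_pop <- (n_pn * pn_sd + n_control * control_sd) / (n_pn + n_control)
  r <- regression_to_mean
  change <- -r * (change_sd / sd_pop) * (baseline - mu_pop) +
    sqrt(1 - r^2) * stats::rnorm(length(group), 0, change_sd) +
    effect * (group == "pn")
  data.frame(group = group, baseline = baseline, change = change,
             stringsAsFactors = FALSE)
}
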