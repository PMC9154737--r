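#' Henry weight-only basal metabolic rate
#'
#' BMR from the published sex- and age-band-specific weight-only linear
#' equations (coefficients in MJ/day), returned in kJ/day. The coefficient
#' table ships as an editable CSV (`system.file("extdata",
#' "henry_coefficients.csv", package = "maheitrial")`) so alternative
#' published variants can be swapped in.
#'
#' @param sex `"male"` or `"female"` (vectorised with `age_years`, `weight_kg`).
#' @param age_years age in years, >= 18 (the study population is adult).
#' @param weight_kg body weight in kg, > 0.
#' @param coefficients coefficient table: columns `sex`, `age_min`,
#'   `age_max`, `slope_mj_per_kg`, `intercept_mj`.
#' @return BMR in kJ/day.
#' @examples
#' henry_bmr("female", 30, 60)  # 0.0407*60 + 2.90 MJ/d = 5342 kJ/d
#' @export
henry_bmr <- function(sex, age_years, weight_kg,
                      coefficients = henry_coefficients()) {
  n <- max(length(sex), length(age_years), length(weight_kg))
  sex <- rep_len(sex, n); age_years <- rep_len(age_years, n)
  weight_kg <- rep_len(weight_kg, n)
  if (any(age_years < 18)) stop_input("Henry BMR: adult ages (>= 18) only")
  if (any(weight_kg <= 0)) stop_input("weight must be positive")
  if (!all(sex %in% c("male", "female"))) stop_input("sex must be 'male' or 'female'")
  vapply(seq_len(n), function(i) {
    row <- coefficients[coefficients$sex == sex[i] &
                        coefficients$age_min <= age_years[i] &
                        age_years[i] < coefficients$age_max, , drop = FALSE]
    if (nrow(row) != 1L)
      stop_input("no unique Henry coefficient row for sex=%s age=%.0f", sex[i], age_years[i])
    (row$slope_mj_per_kg * weight_kg[i] + row$intercept_mj) * 1000
  }, numeric(1))
}

#' @rdname henry_bmr
#' @export
henry_coefficients <- function() {
  path <- system.file("extdata", "henry_coefficients.csv", package = "maheitrial")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' QC configuration
#'
#' Defaults follow the study's data-handling rules: sex-specific EI/BMR
#' plausibility cutoffs (men kept in \[0.49, 2.79\], women in \[0.56, 3.21\],
#' strict inequalities excluded), the >8000 kJ between-FFQ energy
#' discrepancy rule, food-group feasibility limits, the 41/83-day FFQ
#' availability gates, 24-hour FFQ expiry, and the 84-day (12-week)
#' endpoint target.
#'
#' @param ei_bmr_cutoffs list with `male = c(low, high)`, `female = c(low, high)`.
#' @param energy_discrepancy_kj absolute between-FFQ energy change above
#'   which (without corresponding weight change) a participant is excluded.
#' @param weight_change_threshold_kg weight change below which a large
#'   energy change counts as unexplained; 1 kg by default, since
#'   sub-kilogram self-reported change is within reporting noise.
#' @param feasibility_limits data frame `food_group`, `max_daily_amount`.
#' @param ffq_gate_days days after baseline from which FFQ 2 and 3 unlock.
#' @param ffq_expiry_hours hours after which an incomplete FFQ expires.
#' @param target_day endpoint target, days since baseline.
#' @param ei_bmr_visits apply the EI/BMR filter to `"both"` analysed FFQs
#'   (exclude if either fails; the conservative reading) or `"baseline"` only.
#' @param missing_weight_action `"flag"` (retain with warning flag) or
#'   `"exclude"` when the endpoint weight needed by the discrepancy rule is
#'   missing.
#' @return List of class `qc_config`.
#' @export
qc_config <- function(ei_bmr_cutoffs = list(male = c(0.49, 2.79),
                                            female = c(0.56, 3.21)),
                      energy_discrepancy_kj = 8000,
                      weight_change_threshold_kg = 1.0,
                      feasibility_limits = default_feasibility_limits(),
                      ffq_gate_days = c(41, 83),
                      ffq_expiry_hours = 24,
                      target_day = 84,
                      ei_bmr_visits = c("both", "baseline"),
                      missing_weight_action = c("flag", "exclude")) {
  stopifnot(ei_bmr_cutoffs$male[1] < ei_bmr_cutoffs$male[2],
            ei_bmr_cutoffs$female[1] < ei_bmr_cutoffs$female[2],
            energy_discrepancy_kj > 0, weight_change_threshold_kg > 0)
  structure(list(ei_bmr_cutoffs = ei_bmr_cutoffs,
                 energy_discrepancy_kj = energy_discrepancy_kj,
                 weight_change_threshold_kg = weight_change_threshold_kg,
                 feasibility_limits = feasibility_limits,
                 ffq_gate_days = ffq_gate_days,
                 ffq_expiry_hours = ffq_expiry_hours,
                 target_day = target_day,
                 ei_bmr_visits = match.arg(ei_bmr_visits),
                 missing_weight_action = match.arg(missing_weight_action)),
            class = "qc_config")
}

#' @rdname qc_config
#' @export
default_feasibility_limits <- function() {
  path <- system.file("extdata", "feasibility_limits.csv", package = "maheitrial")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Energy-intake plausibility filter (EI/BMR)
#'
#' Implausible dietary reporting is flagged when the ratio of reported
#' energy intake to estimated basal metabolic rate falls outside standard
#' sex-specific cutoffs: men < 0.49 or > 2.79, women < 0.56 or > 3.21.
#' The inequalities are strict — a ratio exactly at a cutoff is kept.
#'
#' @param energy_kj_day reported energy intake, kJ/day.
#' @param bmr_kj_day estimated BMR, kJ/day (> 0).
#' @param sex `"male"` or `"female"`.
#' @param config a [qc_config()].
#' @return List with `keep` (logical) and `ratio`.
#' @export
ei_bmr_filter <- function(energy_kj_day, bmr_kj_day, sex, config = qc_config()) {
  if (any(bmr_kj_day <= 0)) stop_input("BMR must be positive")
  cuts <- config$ei_bmr_cutoffs[[sex]]
  if (is.null(cuts)) stop_input("no EI/BMR cutoffs for sex '%s'", sex)
  ratio <- energy_kj_day / bmr_kj_day
  list(keep = !(ratio < cuts[1] | ratio > cuts[2]), ratio = ratio)
}

#' Between-FFQ energy discrepancy filter
#'
#' A large difference in reported energy intake between the two analysed
#' FFQs (> 8000 kJ in absolute value) without a corresponding weight change
#' marks inconsistent reporting. "Corresponding weight change" is absolute
#' weight change at or above the configured threshold (default 1 kg). With
#' a missing endpoint weight the participant is retained and flagged (or
#' excluded, per `missing_weight_action`).
#'
#' @param ei_baseline,ei_endpoint energy intakes, kJ/day.
#' @param weight_baseline,weight_endpoint self-reported weights, kg
#'   (`weight_endpoint` may be `NA`).
#' @param config a [qc_config()].
#' @return List with `keep`, `delta_ei`, `delta_weight`, `flag`.
#' @export
energy_discrepancy_filter <- function(ei_baseline, ei_endpoint,
                                      weight_baseline, weight_endpoint,
                                      config = qc_config()) {
  d_ei <- ei_endpoint - ei_baseline
  big <- abs(d_ei) > config$energy_discrepancy_kj
  if (is.na(weight_endpoint)) {
    keep <- !(big && config$missing_weight_action == "exclude")
    return(list(keep = keep, delta_ei = d_ei, delta_weight = NA_real_,
                flag = big))
  }
  d_w <- weight_endpoint - weight_baseline
  keep <- !(big && abs(d_w) < config$weight_change_threshold_kg)
  list(keep = keep, delta_ei = d_ei, delta_weight = d_w, flag = FALSE)
}

#' Unfeasible food-group intake filter
#'
#' Reported daily intakes above configured maximum plausible adult amounts
#' (e.g. 10 eggs or 1.2 kg of porridge a day) mark the profile as
#' unfeasible. The comparison is strict: an amount exactly at its limit is
#' kept. Food groups without a configured limit pass.
#'
#' @param profile an [intake_profile()] whose `foods` carry `food_label`
#'   matched (case-insensitively) against `food_group` in the limits table,
#'   with `daily_amount` in the limit's unit.
#' @param limits data frame `food_group`, `max_daily_amount`.
#' @return List with `keep` and `offenders` (data frame of violations).
#' @export
feasibility_filter <- function(profile, limits = default_feasibility_limits()) {
  f <- profile$foods
  if (nrow(f) == 0)
    return(list(keep = TRUE, offenders = f))
  f <- unique(f[, c("food_id", "food_label", "daily_amount")])
  m <- match(tolower(f$food_label), tolower(limits$food_group))
  lim <- limits$max_daily_amount[m]
  bad <- !is.na(lim) & f$daily_amount > lim
  offenders <- f[bad, , drop = FALSE]
  if (nrow(offenders)) offenders$limit <- lim[bad]
  list(keep = !any(bad), offenders = offenders)
}

#' Select the endpoint FFQ visit
#'
#' Not every participant completed the follow-up questionnaires on the
#' target dates, so the analysis uses only two FFQs per participant:
#' baseline and the post-baseline completion closest to the 12-week target
#' (84 days). Ties go to the later visit. With no post-baseline visit the
#' participant has insufficient FFQs (an outcome, not an error).
#'
#' @param visit_days numeric vector of completion days since baseline
#'   (baseline itself = 0).
#' @param target_day target in days (default 84).
#' @return List `visit` (index into `visit_days`, or `NA` if none
#'   post-baseline) and `day`.
#' @export
select_endpoint <- function(visit_days, target_day = 84) {
  post <- which(visit_days > 0)
  if (length(post) == 0)
    return(list(visit = NA_integer_, day = NA_real_))
  d <- visit_days[post]
  dist <- abs(d - target_day)
  best <- post[order(dist, -d)][1]   # minimal distance; tie -> later day
  list(visit = best, day = visit_days[best])
}

#' FFQ availability gate
#'
#' The app releases the second FFQ only after 41 days (one day before week
#' 6) and the third only after 83 days, preventing completion too early.
#'
#' @param days_since_baseline days elapsed since the baseline FFQ.
#' @param ffq_index 2 or 3.
#' @param gate_days unlock days for FFQs 2 and 3.
#' @return Logical availability flag.
#' @export
ffq_available <- function(days_since_baseline, ffq_index, gate_days = c(41, 83)) {
  if (!ffq_index %in% c(2, 3)) stop_input("ffq_index must be 2 or 3")
  days_since_baseline >= gate_days[ffq_index - 1]
}

#' Run the full participant-level QC pipeline
#'
#' Applies the study's data-handling rules to a cohort: endpoint-FFQ
#' selection, then — on the two analysed FFQs — the EI/BMR plausibility
#' filter, the energy-discrepancy rule, and the food-group feasibility
#' filter. Reasons accumulate per participant; the inclusion verdict is the
#' conjunction (so it does not depend on filter order). A CONSORT-style
#' accounting table reports counts and percentages (rounded half-up to one
#' decimal) at each stage.
#'
#' @param cohort a `mahei_cohort` (see [read_cohort()] / [simulate_trial()]).
#' @param config a [qc_config()].
#' @return List of class `qc_result`: `results` (one row per participant:
#'   `participant_id`, `included`, `exclusion_reasons`, `endpoint_visit`,
#'   `endpoint_day`, `flags`) and `accounting` (stage, n, pct).
#' @export
run_qc <- function(cohort, config = qc_config()) {
  parts <- cohort$participants
  visits <- cohort$visits
  res <- lapply(parts$participant_id, function(pid) {
    pv <- visits[visits$participant_id == pid & !is.na(visits$energy_kj_day), ]
    pv <- pv[order(pv$day), ]
    reasons <- character(0); flags <- character(0)
    base <- pv[pv$day == 0, ]
    ep <- select_endpoint(pv$day, config$target_day)
    if (nrow(base) == 0 || is.na(ep$visit)) {
      return(data.frame(participant_id = pid, included = FALSE,
                        exclusion_reasons = "insufficient_ffqs",
                        endpoint_visit = NA_character_, endpoint_day = NA_real_,
                        flags = "", stringsAsFactors = FALSE))
    }
    epv <- pv[ep$visit, ]
    p <- parts[parts$participant_id == pid, ]

    # EI/BMR on the analysed FFQs (weight from the same visit where present)
    check_visits <- if (config$ei_bmr_visits == "both") list(base, epv) else list(base)
    for (v in check_visits) {
      w <- if (!is.na(v$weight_kg)) v$weight_kg else base$weight_kg
      bmr <- henry_bmr(p$sex, p$age_years, w)
      if (!ei_bmr_filter(v$energy_kj_day, bmr, p$sex, config)$keep) {
        reasons <- c(reasons, "ei_bmr"); break
      }
    }

    disc <- energy_discrepancy_filter(base$energy_kj_day, epv$energy_kj_day,
                                      base$weight_kg, epv$weight_kg, config)
    if (!disc$keep) reasons <- c(reasons, "energy_discrepancy")
    if (disc$flag) flags <- c(flags, "missing_endpoint_weight")

    for (v in list(base, epv)) {
      prof <- cohort_profile(cohort, pid, v$visit)
      if (!is.null(prof) && !feasibility_filter(prof, config$feasibility_limits)$keep) {
        reasons <- c(reasons, "unfeasible_intake"); break
      }
    }

    data.frame(participant_id = pid, included = length(reasons) == 0,
               exclusion_reasons = paste(unique(reasons), collapse = ";"),
               endpoint_visit = epv$visit, endpoint_day = epv$day,
               flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res)

  n0 <- nrow(results)
  has_ep <- results$exclusion_reasons != "insufficient_ffqs"
  stages <- data.frame(
    stage = c("baseline_completers", "with_postbaseline_ffq",
              "after_ei_bmr", "after_energy_discrepancy", "after_feasibility",
              "included"),
    n = c(n0, sum(has_ep),
          sum(has_ep & !grepl("ei_bmr", results$exclusion_reasons)),
          sum(has_ep & !grepl("ei_bmr|energy_discrepancy", results$exclusion_reasons)),
          sum(has_ep & !grepl("ei_bmr|energy_discrepancy|unfeasible_intake",
                              results$exclusion_reasons)),
          sum(results$included)),
    stringsAsFactors = FALSE)
  stages$pct <- round_half_up(100 * stages$n / n0, 1)
  structure(list(results = results, accounting = stages), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Cohort QC\n")
  print(x$accounting, row.names = FALSE)
  invisible(x)
}

# intake_profile for one participant-visit from the cohort's long tables;
# NULL if no intake rows for that visit
cohort_profile <- function(cohort, pid, visit) {
  ii <- cohort$intakes[cohort$intakes$participant_id == pid &
                       cohort$intakes$visit == visit, ]
  if (nrow(ii) == 0) return(NULL)
  vv <- cohort$visits[cohort$visits$participant_id == pid &
                      cohort$visits$visit == visit, ]
  ff <- cohort$foods[cohort$foods$participant_id == pid &
                     cohort$foods$visit == visit, , drop = FALSE]
  intake_profile(stats::setNames(ii$amount, ii$component),
                 energy_kj_day = vv$energy_kj_day,
                 foods = if (nrow(ff)) ff[, c("food_id", "food_label",
                                              "daily_amount", "component",
                                              "contribution")] else NULL)
}
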