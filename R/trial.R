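#' Cohort container
#'
#' A trial cohort is four tidy tables: `participants` (`participant_id`,
#' `group` — `"control"`/`"pn"` —, `sex`, `age_years`, `height_m`),
#' `visits` (`participant_id`, `visit`, `day` since baseline, `weight_kg`,
#' `energy_kj_day`), `intakes` (long: `participant_id`, `visit`,
#' `component`, `amount`) and `foods` (per-food contribution records).
#'
#' @param participants,visits,intakes,foods data frames as described.
#' @return Object of class `mahei_cohort`.
#' @export
mahei_cohort <- function(participants, visits, intakes, foods = NULL) {
  if (is.null(foods))
    foods <- data.frame(participant_id = character(), visit = character(),
                        food_id = character(), food_label = character(),
                        daily_amount = numeric(), component = character(),
                        contribution = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("participant_id", "group", "sex", "age_years", "height_m")
                %in% names(participants)),
            all(c("participant_id", "visit", "day", "weight_kg",
                  "energy_kj_day") %in% names(visits)),
            all(c("participant_id", "visit", "component", "amount")
                %in% names(intakes)))
  if (!all(participants$group %in% c("control", "pn")))
    stop_input("group must be 'control' or 'pn'")
  structure(list(participants = participants, visits = visits,
                 intakes = intakes, foods = foods),
            class = "mahei_cohort")
}

#' @export
print.mahei_cohort <- function(x, ...) {
  cat(sprintf("m-AHEI trial cohort: %d participants (%d pn / %d control), %d visits\n",
              nrow(x$participants), sum(x$participants$group == "pn"),
              sum(x$participants$group == "control"), nrow(x$visits)))
  invisible(x)
}

#' Build the analysis dataset (baseline + endpoint scores, wide)
#'
#' Scores each participant's baseline and endpoint FFQs with the criteria
#' set and assembles one row per analysable participant: group, baseline
#' energy, overall score at both visits, per-component scores at both
#' visits (`<component>_baseline` / `<component>_endpoint`), and weights.
#' Participants without a post-baseline FFQ — or excluded by a supplied QC
#' result — are dropped.
#'
#' @param cohort a [mahei_cohort()].
#' @param criteria a [mahei_criteria()] set.
#' @param qc optional [run_qc()] result; only its included participants are
#'   kept and its endpoint choice is honoured.
#' @return Data frame, one row per analysed participant.
#' @export
trial_dataset <- function(cohort, criteria = mahei_criteria(), qc = NULL) {
  parts <- cohort$participants
  if (!is.null(qc)) {
    res <- qc$results
    keep_ids <- res$participant_id[res$included]
    ep_map <- stats::setNames(res$endpoint_visit, res$participant_id)
  } else {
    keep_ids <- parts$participant_id
    ep_map <- NULL
  }
  rows <- lapply(parts$participant_id, function(pid) {
    if (!pid %in% keep_ids) return(NULL)
    pv <- cohort$visits[cohort$visits$participant_id == pid &
                        !is.na(cohort$visits$energy_kj_day), ]
    base <- pv[pv$day == 0, ]
    if (nrow(base) != 1) return(NULL)
    ep_visit <- if (!is.null(ep_map)) ep_map[[pid]] else {
      sel <- select_endpoint(pv$day)
      if (is.na(sel$visit)) NA_character_ else pv$visit[sel$visit]
    }
    if (is.na(ep_visit)) return(NULL)
    epv <- pv[pv$visit == ep_visit, ]
    pb <- cohort_profile(cohort, pid, base$visit)
    pe <- cohort_profile(cohort, pid, ep_visit)
    if (is.null(pb) || is.null(pe)) return(NULL)
    sb <- score_profile(pb, criteria); se <- score_profile(pe, criteria)
    p <- parts[parts$participant_id == pid, ]
    row <- data.frame(participant_id = pid, group = p$group,
                      sex = p$sex, age_years = p$age_years,
                      height_m = p$height_m,
                      energy_baseline = base$energy_kj_day,
                      weight_baseline = base$weight_kg,
                      weight_endpoint = epv$weight_kg,
                      endpoint_day = epv$day,
                      overall_baseline = sb$overall,
                      overall_endpoint = se$overall,
                      stringsAsFactors = FALSE)
    for (comp in criteria$name) {
      row[[paste0(comp, "_baseline")]] <- unname(sb$component_scores[comp])
      row[[paste0(comp, "_endpoint")]] <- unname(se$component_scores[comp])
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop_input("no analysable participants (baseline + endpoint FFQ required)")
  rownames(out) <- NULL
  out
}

#' Default per-outcome model specifications
#'
#' The overall score and every component enter the model with baseline
#' energy as covariate; the three right-skewed components (whole grains,
#' nuts and legumes, red and processed meat) are square-root transformed.
#'
#' @param criteria a [mahei_criteria()] set.
#' @param sqrt_components components square-root transformed by default.
#' @param component_energy_covariate if `FALSE`, only the overall score
#'   gets the energy covariate.
#' @return Named list of [outcome_spec()]s (`overall` plus one per component).
#' @export
default_outcome_specs <- function(criteria = mahei_criteria(),
                                  sqrt_components = c("whole_grains",
                                                      "nuts_legumes",
                                                      "red_processed_meat"),
                                  component_energy_covariate = TRUE) {
  specs <- list(overall = outcome_spec("overall", "identity", "baseline_energy"))
  for (comp in criteria$name) {
    specs[[comp]] <- outcome_spec(
      comp,
      transform = if (comp %in% sqrt_components) "sqrt" else "identity",
      covariate = if (component_energy_covariate) "baseline_energy" else "none")
  }
  specs
}

# change scores + covariate for one outcome from a trial_dataset row set
outcome_changes <- function(ds, spec) {
  b <- ds[[paste0(spec$name, "_baseline")]]
  e <- ds[[paste0(spec$name, "_endpoint")]]
  if (is.null(b) || is.null(e)) stop_input("outcome '%s' not in dataset", spec$name)
  chg <- apply_transform(e, spec) - apply_transform(b, spec)
  cov <- switch(spec$covariate,
                baseline_energy = ds$energy_baseline,
                baseline_value = apply_transform(b, spec),
                none = NULL)
  list(change = chg, covariate = cov, baseline = b)
}

#' Treatment effects for the overall score and all 11 components
#'
#' Runs the change-score ANCOVA for each declared outcome and collects the
#' table the trial reports: per-arm baseline mean (SD), adjusted change
#' mean (SD), treatment effect (intervention minus control) with 95% CI
#' and p-value.
#'
#' @param ds a [trial_dataset()].
#' @param specs named list of [outcome_spec()]s
#'   (default [default_outcome_specs()]).
#' @return List of class `trial_effects`: `table` (one row per outcome) and
#'   `fits` (the `mahei_ancova` objects).
#' @export
trial_effects <- function(ds, specs = default_outcome_specs()) {
  fits <- list(); rows <- list()
  for (spec in specs) {
    oc <- outcome_changes(ds, spec)
    fit <- ancova_effect(oc$change, ds$group, oc$covariate, outcome = spec$name)
    fits[[spec$name]] <- fit
    ctl <- ds$group == "control"
    adj <- fit$adjusted
    rows[[spec$name]] <- data.frame(
      outcome = spec$name, transform = spec$transform,
      baseline_control_mean = mean(oc$baseline[ctl]),
      baseline_control_sd = stats::sd(oc$baseline[ctl]),
      baseline_pn_mean = mean(oc$baseline[!ctl]),
      baseline_pn_sd = stats::sd(oc$baseline[!ctl]),
      adj_change_control = adj$adj_change[adj$group == "control"],
      adj_change_control_sd = adj$adj_sd[adj$group == "control"],
      adj_change_pn = adj$adj_change[adj$group == "pn"],
      adj_change_pn_sd = adj$adj_sd[adj$group == "pn"],
      effect = fit$effect, ci_low = fit$ci[1], ci_high = fit$ci[2],
      p_value = fit$p_value, n_control = fit$n[1], n_pn = fit$n[2],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "trial_effects")
}

#' @export
print.trial_effects <- function(x, ...) {
  tab <- x$table
  cat("Treatment effects (pn - control), 95% CI, p\n")
  show <- data.frame(outcome = tab$outcome,
                     effect = round_half_up(tab$effect, 1),
                     ci = sprintf("(%.2f to %.2f)", tab$ci_low, tab$ci_high),
                     p = signif(tab$p_value, 2))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Baseline advice-component membership per participant
#'
#' For every analysed participant (either arm), the three components their
#' baseline m-AHEI scores select for advice — actually delivered in the
#' intervention arm, hypothetical ("matched") in the control arm.
#'
#' @param ds a [trial_dataset()].
#' @param criteria a [mahei_criteria()] set.
#' @return Logical matrix, participants x components; `TRUE` = component in
#'   that participant's lowest 3.
#' @export
baseline_selections <- function(ds, criteria = mahei_criteria()) {
  m <- matrix(FALSE, nrow(ds), nrow(criteria),
              dimnames = list(ds$participant_id, criteria$name))
  for (i in seq_len(nrow(ds))) {
    scores <- stats::setNames(
      as.numeric(ds[i, paste0(criteria$name, "_baseline")]), criteria$name)
    sel <- select_advice_components(scores, k = 3, criteria = criteria)
    m[i, sel$component] <- TRUE
  }
  m
}

#' Frequency of healthy-eating messages per component
#'
#' How often each component falls in a participant's lowest 3 — i.e. how
#' often its message was presented (intervention arm) or would have been
#' (matched control). Percentages are reported per arm, per full cohort,
#' and of the total message count (3 x cohort size).
#'
#' @param ds a [trial_dataset()].
#' @param criteria a [mahei_criteria()] set.
#' @return Data frame: `component`, `n_control`, `n_pn`, `n_total`,
#'   `pct_arm_control`, `pct_arm_pn`, `pct_cohort_control`, `pct_cohort_pn`,
#'   `pct_total`, sorted by descending `n_total`; plus a `totals` attribute.
#' @export
message_frequency_table <- function(ds, criteria = mahei_criteria()) {
  sel <- baseline_selections(ds, criteria)
  ctl <- ds$group == "control"
  n_ctl_arm <- sum(ctl); n_pn_arm <- sum(!ctl); n_all <- nrow(ds)
  n_ctl <- colSums(sel[ctl, , drop = FALSE])
  n_pn <- colSums(sel[!ctl, , drop = FALSE])
  total_messages <- 3 * n_all
  out <- data.frame(component = criteria$name,
                    n_control = as.integer(n_ctl), n_pn = as.integer(n_pn),
                    n_total = as.integer(n_ctl + n_pn),
                    pct_arm_control = round_half_up(100 * n_ctl / n_ctl_arm, 1),
                    pct_arm_pn = round_half_up(100 * n_pn / n_pn_arm, 1),
                    pct_cohort_control = round_half_up(100 * n_ctl / n_all, 1),
                    pct_cohort_pn = round_half_up(100 * n_pn / n_all, 1),
                    pct_total = round_half_up(100 * (n_ctl + n_pn) / total_messages, 1),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_total, out$component), ]
  rownames(out) <- NULL
  attr(out, "totals") <- c(control = sum(out$n_control), pn = sum(out$n_pn),
                           total = total_messages)
  out
}

#' Matched-control subgroup treatment effect for one component
#'
#' The effect of actually receiving a component's message: intervention
#' participants whose lowest-3 baseline components include it, versus
#' control participants who would also have received advice on that
#' component had they been in the intervention arm. The outcome's declared
#' transform and covariate are applied within the subgroup.
#'
#' @param ds a [trial_dataset()].
#' @param component component name.
#' @param criteria a [mahei_criteria()] set.
#' @param specs outcome specs (the component's spec is looked up here).
#' @return List of class `matched_subgroup`: `component`, `membership`
#'   (per-arm counts and percentages), `estimable`, and `fit` (a
#'   `mahei_ancova`, or `NULL` when a side is empty or too small).
#' @export
matched_subgroup_effect <- function(ds, component,
                                    criteria = mahei_criteria(),
                                    specs = default_outcome_specs(criteria)) {
  if (!component %in% criteria$name) stop_input("unknown component '%s'", component)
  sel <- baseline_selections(ds, criteria)[, component]
  sub <- ds[sel, , drop = FALSE]
  ctl <- ds$group == "control"
  membership <- data.frame(
    group = c("control", "pn"),
    n = c(sum(sel & ctl), sum(sel & !ctl)),
    arm_n = c(sum(ctl), sum(!ctl)))
  membership$pct_arm <- round_half_up(100 * membership$n / membership$arm_n, 1)
  estimable <- all(membership$n >= 3)
  fit <- NULL
  if (estimable) {
    spec <- specs[[component]]
    oc <- outcome_changes(sub, spec)
    fit <- ancova_effect(oc$change, sub$group, oc$covariate,
                         outcome = paste0(component, " (matched subgroup)"))
  }
  structure(list(component = component, membership = membership,
                 estimable = estimable, fit = fit),
            class = "matched_subgroup")
}

#' @export
print.matched_subgroup <- function(x, ...) {
  cat(sprintf("Matched-subgroup analysis — %s\n", x$component))
  print(x$membership, row.names = FALSE)
  if (x$estimable) print(x$fit) else cat("  not estimable (empty or tiny subgroup)\n")
  invisible(x)
}

#' Secondary BMI outcomes
#'
#' Two baseline-adjusted ANCOVAs: absolute BMI, and the absolute distance
#' from current BMI to the ideal BMI of 21.75 kg/m2 (did the advice move
#' participants toward the healthy-range midpoint?). Participants with a
#' missing endpoint weight are dropped from these outcomes with a warning.
#'
#' @param ds a [trial_dataset()].
#' @return List with `bmi` and `distance` (`mahei_ancova` fits).
#' @export
bmi_outcomes <- function(ds) {
  ok <- !is.na(ds$weight_baseline) & !is.na(ds$weight_endpoint)
  if (any(!ok))
    warning(sprintf("%d participant(s) without endpoint weight dropped from BMI outcomes",
                    sum(!ok)))
  d <- ds[ok, ]
  bmi_b <- d$weight_baseline / d$height_m^2
  bmi_e <- d$weight_endpoint / d$height_m^2
  dist_b <- abs(bmi_b - 21.75); dist_e <- abs(bmi_e - 21.75)
  list(bmi = ancova_effect(bmi_e - bmi_b, d$group, bmi_b, outcome = "BMI (kg/m2)"),
       distance = ancova_effect(dist_e - dist_b, d$group, dist_b,
                                outcome = "distance to ideal BMI (kg/m2)"))
}
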