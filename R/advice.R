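#' Select the components to target with personalized advice
#'
#' The decision engine targets the `k` (default 3) components with the
#' lowest m-AHEI scores. Ties are broken by the fixed criteria order, so the
#' selection is deterministic and independent of how the scores happen to be
#' stored. Output is ordered by ascending score, then criteria order.
#'
#' @param score a `mahei_score` (from [score_profile()]) or a named numeric
#'   vector of the 11 component scores.
#' @param k number of components to select, 1-11 (default 3).
#' @param criteria the [mahei_criteria()] set defining the canonical order.
#' @return A data frame of class `advice_selection` with columns
#'   `component` and `score`, `k` rows.
#' @export
select_advice_components <- function(score, k = 3, criteria = mahei_criteria()) {
  scores <- if (inherits(score, "mahei_score")) score$component_scores else score
  if (k < 1 || k > 11) stop_input("k must be between 1 and 11")
  missing_comp <- setdiff(criteria$name, names(scores))
  if (length(missing_comp))
    stop_input("score lacks component(s): %s", paste(missing_comp, collapse = ", "))
  # reindex into criteria order so ties resolve by position in the set
  s <- scores[criteria$name]
  ord <- order(s, seq_along(s))
  sel <- data.frame(component = criteria$name[ord][seq_len(k)],
                    score = unname(s[ord][seq_len(k)]),
                    stringsAsFactors = FALSE)
  class(sel) <- c("advice_selection", "data.frame")
  sel
}

#' Default message templates for the 11 m-AHEI components
#'
#' Template text is deliberately generic — the deployed wording is an
#' editorial asset, not an algorithmic one. `{foods}` is replaced with the
#' participant's top contributing foods, `{amount}` with the current daily
#' amount.
#'
#' @return Named character vector, component -> template.
#' @export
default_templates <- function() {
  crit <- mahei_criteria()
  dirword <- ifelse(crit$direction == "positive", "more", "less")
  stats::setNames(sprintf(
    "Your %s score can improve: aim for %s (currently {amount} %s). Foods that matter most in your diet: {foods}.",
    gsub("_", " ", crit$name), dirword, crit$metric), crit$name)
}

#' Build the three personalized diet messages
#'
#' Each selected component yields one message carrying the filled template
#' and up to `n_foods` top contributor foods from the participant's own FFQ.
#' A component with no recorded contributors still gets a message, with an
#' empty contributor list.
#'
#' @param selection an `advice_selection` from [select_advice_components()].
#' @param profile the participant's [intake_profile()].
#' @param templates named character vector component -> template text;
#'   a template must exist for every selected component.
#' @param n_foods number of contributor foods to include (default 3).
#' @return List of message objects (`component`, `text`, `foods`).
#' @export
build_diet_messages <- function(selection, profile,
                                templates = default_templates(), n_foods = 3) {
  missing_tpl <- setdiff(selection$component, names(templates))
  if (length(missing_tpl))
    stop_input("no message template for component(s): %s",
               paste(missing_tpl, collapse = ", "))
  lapply(seq_len(nrow(selection)), function(i) {
    comp <- selection$component[i]
    foods <- top_contributors(profile, comp, k = n_foods)
    txt <- templates[[comp]]
    txt <- gsub("{amount}", format(profile$component_amounts[[comp]], digits = 3),
                txt, fixed = TRUE)
    food_str <- if (nrow(foods)) paste(foods$food_label, collapse = ", ") else "none recorded"
    txt <- gsub("{foods}", food_str, txt, fixed = TRUE)
    list(component = comp, text = txt, foods = foods)
  })
}

#' BMI feedback with ideal-weight range
#'
#' The healthy BMI range is 18.5-25.0 kg/m2; the ideal weight shown to a
#' participant is the weight at the midpoint BMI of 21.75 kg/m2. Two
#' distance conventions are computed: `distance_to_midpoint` (absolute
#' difference from current BMI to 21.75 — the primary outcome convention)
#' and `distance_to_range` (0 anywhere inside the healthy range, else
#' distance to the nearest bound).
#'
#' @param height_m height in metres, > 0.
#' @param weight_kg self-reported weight in kg, > 0.
#' @return An object of class `bmi_feedback`.
#' @examples
#' fb <- bmi_feedback(1.7, 70)
#' fb$bmi; fb$ideal_weight_mid
#' @export
bmi_feedback <- function(height_m, weight_kg) {
  if (height_m <= 0 || weight_kg <= 0)
    stop_input("height and weight must be positive")
  bmi <- weight_kg / height_m^2
  lo <- 18.5; hi <- 25.0; mid <- (lo + hi) / 2   # 21.75
  structure(list(
    bmi = bmi,
    ideal_bmi_low = lo, ideal_bmi_high = hi, ideal_bmi_mid = mid,
    ideal_weight_range = c(lo, hi) * height_m^2,
    ideal_weight_mid = mid * height_m^2,
    distance_to_midpoint = abs(bmi - mid),
    distance_to_range = if (bmi < lo) lo - bmi else if (bmi > hi) bmi - hi else 0,
    in_range = bmi >= lo && bmi <= hi
  ), class = "bmi_feedback")
}

#' Baecke physical-activity feedback scores
#'
#' Habitual physical activity is summarised in three category indices —
#' work, sports and leisure — each built from items answered on 1-5 scales
#' (answers coded so that higher = more active). Each category index (the
#' mean of its items, range 1-5) is rescaled linearly so the instrument
#' minimum maps to 0 and the maximum to 100; the overall score is the
#' rescaled mean of the three category indices. Advice messages accompany
#' the sports and leisure categories only: participants rarely control the
#' nature of their work activity, so no personalized work message is given.
#'
#' @param answers named list with numeric vectors `work`, `sports`,
#'   `leisure`, each item in \[1, 5\], no missing values.
#' @param thresholds two cutpoints on the 0-100 scale splitting low /
#'   moderate / high activity messages (default `c(40, 70)`).
#' @return Object of class `pa_feedback`: `work_score`, `sports_score`,
#'   `leisure_score`, `overall_score` (each 0-100) and `messages` for
#'   sports and leisure only.
#' @export
baecke_scores <- function(answers, thresholds = c(40, 70)) {
  cats <- c("work", "sports", "leisure")
  if (!all(cats %in% names(answers)))
    stop_input("answers must contain 'work', 'sports' and 'leisure'")
  idx <- vapply(cats, function(cat) {
    a <- answers[[cat]]
    if (length(a) == 0 || anyNA(a))
      stop_input("incomplete answers in category '%s'", cat)
    if (any(a < 1 | a > 5))
      stop_input("answers must lie on the instrument's 1-5 scale ('%s')", cat)
    mean(a)
  }, numeric(1))
  rescaled <- (idx - 1) / 4 * 100
  lvl <- function(s) if (s < thresholds[1]) "low" else if (s < thresholds[2]) "moderate" else "high"
  msg <- function(cat, s) sprintf(
    "Your %s activity score is %.0f/100 (%s). %s", cat, s, lvl(s),
    if (lvl(s) == "high") "Keep it up." else "Consider adding regular activity.")
  structure(list(
    work_score = unname(rescaled["work"]),
    sports_score = unname(rescaled["sports"]),
    leisure_score = unname(rescaled["leisure"]),
    overall_score = mean(rescaled),
    messages = list(sports = msg("sports", rescaled["sports"]),
                    leisure = msg("leisure", rescaled["leisure"]))
  ), class = "pa_feedback")
}

#' Assemble the full personalized-nutrition report
#'
#' The report shown to an intervention participant after each FFQ: the
#' overall m-AHEI score, three diet messages targeted at the lowest-scoring
#' components (with the top contributing foods from their own diet), BMI
#' feedback with the ideal-weight range, and Baecke physical-activity
#' feedback.
#'
#' @param profile [intake_profile()].
#' @param height_m,weight_kg anthropometrics.
#' @param pa_answers Baecke answers, see [baecke_scores()]; optional.
#' @param criteria [mahei_criteria()] set.
#' @param templates message templates.
#' @return Object of class `pn_report`.
#' @export
pn_report <- function(profile, height_m, weight_kg, pa_answers = NULL,
                      criteria = mahei_criteria(),
                      templates = default_templates()) {
  sc <- score_profile(profile, criteria)
  sel <- select_advice_components(sc, k = 3, criteria = criteria)
  structure(list(
    overall_mahei = sc$overall,
    score = sc,
    selection = sel,
    diet_messages = build_diet_messages(sel, profile, templates),
    bmi_feedback = bmi_feedback(height_m, weight_kg),
    pa_feedback = if (!is.null(pa_answers)) baecke_scores(pa_answers) else NULL
  ), class = "pn_report")
}

#' @export
print.pn_report <- function(x, ...) {
  cat(sprintf("Personalized nutrition report — overall m-AHEI %.1f/100\n",
              x$overall_mahei))
  cat("Targeted components:", paste(x$selection$component, collapse = ", "), "\n")
  cat(sprintf("BMI %.1f kg/m2 (ideal weight %.1f kg)\n",
              x$bmi_feedback$bmi, x$bmi_feedback$ideal_weight_mid))
  invisible(x)
}

#' Generic (control-arm) report
#'
#' Control participants receive the same report structure but with fixed,
#' participant-independent healthy-eating messages: at baseline the
#' vegetables, free sugars and healthy (polyunsaturated) fats components;
#' at week 6 fruit, whole grains and red or processed meat; plus generic
#' weight and activity text.
#'
#' @param week `"baseline"` or `"week6"`.
#' @param templates named character vector component -> generic template.
#' @return Object of class `control_report` with 3 fixed messages.
#' @export
control_report <- function(week = c("baseline", "week6"),
                           templates = default_templates()) {
  week <- match.arg(week)
  comps <- switch(week,
    baseline = c("vegetables", "free_sugars", "healthy_fats"),
    week6 = c("fruit", "whole_grains", "red_processed_meat"))
  msgs <- lapply(comps, function(comp) {
    txt <- gsub("{amount}", "your usual", templates[[comp]], fixed = TRUE)
    txt <- gsub("{foods}", "typical UK sources", txt, fixed = TRUE)
    list(component = comp, text = txt)
  })
  structure(list(week = week, diet_messages = msgs,
                 weight_text = "Maintaining a healthy weight supports long-term health.",
                 pa_text = "Regular physical activity is recommended for all adults."),
            class = "control_report")
}
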