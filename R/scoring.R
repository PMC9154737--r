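#' Score a single m-AHEI component
#'
#' Intakes between the zero-score and full-score criteria are scored by
#' linear interpolation — a positive slope for healthy components, a
#' negative slope for unhealthy ones — and clamped to \[0, 100\], so higher
#' scores always mean better diet quality.
#'
#' @param amount daily intake in the criterion's metric; non-negative.
#'   Vectorised.
#' @param criterion one row of a [mahei_criteria()] table (a list or
#'   one-row data frame with `zero_score_intake` and `full_score_intake`).
#' @return Score(s) in \[0, 100\].
#' @examples
#' crit <- mahei_criteria()
#' veg <- crit[crit$name == "vegetables", ]
#' score_component(2.5, veg)  # halfway to the 5 servings/day criterion -> 50
#' @export
score_component <- function(amount, criterion) {
  if (any(is.na(amount)) || any(amount < 0))
    stop_input("intake amount must be non-negative and non-missing")
  zero <- criterion$zero_score_intake
  full <- criterion$full_score_intake
  if (identical(zero, full) || isTRUE(zero == full))
    stop_input("degenerate criterion: zero_score_intake equals full_score_intake")
  pmin(100, pmax(0, 100 * (amount - zero) / (full - zero)))
}

#' Construct an intake profile
#'
#' One FFQ result: daily amounts per m-AHEI component (in each component's
#' own metric), total energy intake, and optionally per-food contribution
#' records used to highlight the top contributors behind each component.
#'
#' @param component_amounts named numeric vector, component -> daily amount.
#' @param energy_kj_day total reported energy intake, kJ/day.
#' @param foods optional data frame with columns `food_id`, `food_label`,
#'   `daily_amount`, `component`, `contribution` (one row per food x
#'   component it contributes to). Per component, food contributions may
#'   under-cover the component amount but never exceed it.
#' @param completion_date optional `Date`.
#' @return An object of class `intake_profile`.
#' @export
intake_profile <- function(component_amounts, energy_kj_day, foods = NULL,
                           completion_date = NULL) {
  if (is.null(names(component_amounts)) || any(names(component_amounts) == ""))
    stop_input("component_amounts must be a fully named numeric vector")
  if (any(component_amounts < 0)) stop_input("component amounts must be >= 0")
  if (energy_kj_day < 0) stop_input("energy_kj_day must be >= 0")
  if (is.null(foods)) {
    foods <- data.frame(food_id = character(), food_label = character(),
                        daily_amount = numeric(), component = character(),
                        contribution = numeric(), stringsAsFactors = FALSE)
  } else {
    foods <- as.data.frame(foods)
    req <- c("food_id", "food_label", "daily_amount", "component", "contribution")
    if (!all(req %in% names(foods)))
      stop_input("foods must have columns: %s", paste(req, collapse = ", "))
    if (any(foods$daily_amount < 0) || any(foods$contribution < 0))
      stop_input("food amounts and contributions must be >= 0")
    covered <- tapply(foods$contribution, foods$component, sum)
    for (comp in names(covered)) {
      amt <- component_amounts[[comp]]
      if (!is.null(amt) && covered[[comp]] > amt + 1e-6)
        stop_input("food contributions over-cover component '%s' (%.3f > %.3f)",
                   comp, covered[[comp]], amt)
    }
  }
  structure(list(component_amounts = component_amounts,
                 energy_kj_day = energy_kj_day,
                 foods = foods,
                 completion_date = completion_date),
            class = "intake_profile")
}

#' Score a full intake profile
#'
#' Scores every component of the criteria set via [score_component()] and
#' averages the 11 equally weighted component scores into the overall
#' diet-quality score presented on the 0-100 percentage scale. The auxiliary
#' 0-110 pre-scaling sum (each component contributing up to 10 points, as in
#' the AHEI-2010 family the index derives from) is also reported.
#'
#' @param profile an [intake_profile()], or a bare named numeric vector of
#'   component amounts.
#' @param criteria a [mahei_criteria()] set.
#' @return An object of class `mahei_score` with elements
#'   `component_scores` (named, in criteria order), `overall` (mean, 0-100)
#'   and `scale110` (sum of component scores / 10, 0-110).
#' @examples
#' crit <- mahei_criteria()
#' amounts <- setNames(crit$full_score_intake, crit$name)
#' score_profile(amounts, crit)$overall  # 100
#' @export
score_profile <- function(profile, criteria = mahei_criteria()) {
  amounts <- if (inherits(profile, "intake_profile"))
    profile$component_amounts else profile
  missing_comp <- setdiff(criteria$name, names(amounts))
  if (length(missing_comp))
    stop_input("profile is missing amount(s) for component(s): %s",
               paste(missing_comp, collapse = ", "))
  scores <- vapply(seq_len(nrow(criteria)), function(i)
    score_component(amounts[[criteria$name[i]]], criteria[i, ]), numeric(1))
  names(scores) <- criteria$name
  structure(list(component_scores = scores,
                 overall = mean(scores),
                 scale110 = sum(scores) / 10),
            class = "mahei_score")
}

#' @export
print.mahei_score <- function(x, ...) {
  cat(sprintf("m-AHEI score: %.1f / 100 (%.1f / 110 before scaling)\n",
              x$overall, x$scale110))
  print(round(x$component_scores, 1))
  invisible(x)
}

#' Convert an overall 0-100 m-AHEI quantity to the 0-110 pre-scaling scale
#'
#' The index is presented to participants as a 0-100 percentage (the mean of
#' 11 components each scored 0-100); before that scaling the AHEI-family sum
#' runs 0-110 (11 components x 10 points). Score differences convert the
#' same way: a 3.5-point effect out of 100 is 3.85 (~3.9) out of 110.
#'
#' @param x overall score or score difference on the 0-100 scale.
#' @return The same quantity on the 0-110 scale (`x * 1.1`).
#' @export
to_scale110 <- function(x) x * 1.1

#' Rank the foods contributing most to a component
#'
#' The personalized advice highlights which foods in the participant's own
#' diet contribute most to each targeted component. Foods are ranked by
#' descending contribution; ties are broken by ascending `food_id` so the
#' ranking is fully deterministic; zero contributors are dropped.
#'
#' @param profile an [intake_profile()] with food records.
#' @param component component name.
#' @param k maximum number of foods to return (default 3).
#' @return Data frame with columns `food_id`, `food_label`, `contribution`,
#'   at most `k` rows.
#' @export
top_contributors <- function(profile, component, k = 3) {
  stopifnot(inherits(profile, "intake_profile"), k >= 1)
  if (!component %in% names(profile$component_amounts))
    stop_input("unknown component '%s'", component)
  f <- profile$foods
  f <- f[f$component == component & f$contribution > 0, , drop = FALSE]
  if (nrow(f) == 0)
    return(data.frame(food_id = character(), food_label = character(),
                      contribution = numeric(), stringsAsFactors = FALSE))
  f <- f[order(-f$contribution, f$food_id), , drop = FALSE]
  f <- utils::head(f, k)
  rownames(f) <- NULL
  f[, c("food_id", "food_label", "contribution")]
}
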