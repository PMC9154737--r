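#' m-AHEI scoring criteria
#'
#' The m-AHEI scores 11 food and drink components on 0-100 each. A component
#' criterion is a declarative rule: the intake at which the score is 0
#' (`zero_score_intake`), the intake at which it is 100 (`full_score_intake`),
#' and the direction of the slope — *positive* components (e.g. vegetables)
#' score higher with higher intake, *negative* components (e.g. red and
#' processed meat) score lower. Scores between the thresholds are linearly
#' interpolated and clamped to \[0, 100\].
#'
#' The exact cutpoints used by the original decision engine live in its
#' supplementary criteria table; the default set shipped here
#' (`mahei_criteria()`) is a documented stand-in adapted from the AHEI-2010
#' with UK-guideline units. All scoring logic is criteria-agnostic: supply
#' your own table via `read_criteria()` or a data frame with the same
#' columns.
#'
#' @param criteria a data frame with columns `name`, `direction`
#'   (`"positive"`/`"negative"`), `metric`, `zero_score_intake`,
#'   `full_score_intake`.
#' @param version a version label attached to the set.
#' @return An object of class `mahei_criteria`: a validated data frame of 11
#'   components whose row order is the canonical component order (used for
#'   deterministic tie-breaking when selecting advice components).
#' @examples
#' crit <- mahei_criteria()
#' crit$name
#' @export
mahei_criteria <- function() {
  as_mahei_criteria(data.frame(
    name = c("vegetables", "fruit", "whole_grains", "dairy",
             "nuts_legumes", "healthy_fats", "oily_fish",
             "free_sugars", "red_processed_meat", "salt", "alcohol"),
    direction = c(rep("positive", 7), rep("negative", 4)),
    metric = c("servings/day", "servings/day", "g/day", "servings/day",
               "servings/day", "%energy", "portions/week",
               "%energy", "servings/day", "g/day", "drinks/day"),
    zero_score_intake = c(0, 0, 0, 0, 0, 2, 0, 20, 1.5, 12, 3.5),
    full_score_intake = c(5, 4, 90, 3, 1, 10, 1, 5, 0, 6, 0.5),
    stringsAsFactors = FALSE
  ), version = "ahei2010-uk-standin-1")
}

#' @rdname mahei_criteria
#' @export
as_mahei_criteria <- function(criteria, version = "custom") {
  req <- c("name", "direction", "metric", "zero_score_intake", "full_score_intake")
  missing_cols <- setdiff(req, names(criteria))
  if (length(missing_cols))
    stop_input("criteria table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  criteria <- as.data.frame(criteria)[, req]
  if (nrow(criteria) != 11L)
    stop_input("a criteria set must have exactly 11 components, got %d", nrow(criteria))
  if (anyDuplicated(criteria$name))
    stop_input("duplicate component names in criteria set")
  if (!all(criteria$direction %in% c("positive", "negative")))
    stop_input("direction must be 'positive' or 'negative'")
  if (any(criteria$zero_score_intake == criteria$full_score_intake))
    stop_input("degenerate criterion: zero_score_intake equals full_score_intake")
  pos <- criteria$direction == "positive"
  if (any(pos & criteria$full_score_intake <= criteria$zero_score_intake) ||
      any(!pos & criteria$full_score_intake >= criteria$zero_score_intake))
    stop_input("direction inconsistent with thresholds (positive requires full > zero, negative full < zero)")
  rownames(criteria) <- NULL
  structure(criteria, version = version,
            class = c("mahei_criteria", "data.frame"))
}

#' Read a criteria set from JSON or YAML
#'
#' The file holds one record per component with fields `name`, `direction`,
#' `metric`, `zero_score_intake`, `full_score_intake`; it is validated on
#' load (11 unique components, consistent slopes).
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return A `mahei_criteria` object.
#' @export
read_criteria <- function(path) {
  if (!file.exists(path)) stop_input("criteria file not found: %s", path)
  recs <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  version <- "file"
  if (!is.null(recs$version)) {
    version <- recs$version
    recs <- recs$components
  }
  df <- do.call(rbind, lapply(recs, function(r)
    data.frame(name = r$name, direction = r$direction, metric = r$metric,
               zero_score_intake = as.numeric(r$zero_score_intake),
               full_score_intake = as.numeric(r$full_score_intake),
               stringsAsFactors = FALSE)))
  as_mahei_criteria(df, version = version)
}

#' @export
print.mahei_criteria <- function(x, ...) {
  cat(sprintf("m-AHEI criteria set '%s' (11 components)\n", attr(x, "version")))
  print.data.frame(x, ...)
  invisible(x)
}
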