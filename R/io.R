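#' Write a cohort to disk
#'
#' Four UTF-8, comma-separated, header-mandatory CSVs (`participants.csv`,
#' `visits.csv`, `intakes.csv`, `foods.csv`) under `dir`. Numbers use dot
#' decimals; the layout is exactly what [read_cohort()] consumes.
#'
#' @param cohort a [mahei_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mahei_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in c("participants", "visits", "intakes", "foods")) {
    utils::write.csv(cohort[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Reads the CSV bundle written by [write_cohort()] (or equivalent),
#' validates the schema (required columns, known component names, no
#' negative amounts) and reports row counts. An empty bundle yields an
#' empty cohort with a warning.
#'
#' @param dir directory holding `participants.csv`, `visits.csv`,
#'   `intakes.csv` and optionally `foods.csv`.
#' @param criteria criteria set whose component names are the valid ones.
#' @param quiet suppress the row-count message.
#' @return A [mahei_cohort()].
#' @export
read_cohort <- function(dir, criteria = mahei_criteria(), quiet = FALSE) {
  pth <- function(f) file.path(dir, f)
  for (f in c("participants.csv", "visits.csv", "intakes.csv"))
    if (!file.exists(pth(f))) stop_input("cohort file missing: %s", pth(f))
  participants <- utils::read.csv(pth("participants.csv"), stringsAsFactors = FALSE)
  visits <- utils::read.csv(pth("visits.csv"), stringsAsFactors = FALSE)
  intakes <- utils::read.csv(pth("intakes.csv"), stringsAsFactors = FALSE)
  foods <- if (file.exists(pth("foods.csv")))
    utils::read.csv(pth("foods.csv"), stringsAsFactors = FALSE) else NULL
  if (nrow(participants) == 0) {
    warning("empty cohort")
  } else {
    bad <- setdiff(unique(intakes$component), criteria$name)
    if (length(bad))
      stop_input("unknown component name(s) in intakes: %s",
                 paste(bad, collapse = ", "))
    if (any(intakes$amount < 0, na.rm = TRUE)) {
      row <- which(intakes$amount < 0)[1]
      stop_input("negative intake amount at intakes.csv row %d (field 'amount')", row)
    }
  }
  if (!quiet)
    message(sprintf("read cohort: %d participants, %d visits, %d intake rows",
                    nrow(participants), nrow(visits), nrow(intakes)))
  mahei_cohort(participants, visits, intakes, foods)
}

#' Write trial results
#'
#' The printed-table CSV uses the trial-report layout (baseline mean (SD)
#' per arm, adjusted change per arm, treatment effect with 95% CI, p),
#' rounded half-up to one decimal; the JSON bundle keeps full precision.
#'
#' @param effects a [trial_effects()] result.
#' @param dir output directory.
#' @return Paths of the files written, invisibly.
#' @export
write_results <- function(effects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- effects$table
  pretty <- data.frame(
    outcome = tab$outcome,
    baseline_control = sprintf("%.1f (%.1f)",
                               round_half_up(tab$baseline_control_mean, 1),
                               round_half_up(tab$baseline_control_sd, 1)),
    baseline_pn = sprintf("%.1f (%.1f)",
                          round_half_up(tab$baseline_pn_mean, 1),
                          round_half_up(tab$baseline_pn_sd, 1)),
    adj_change_control = sprintf("%.1f (%.1f)",
                                 round_half_up(tab$adj_change_control, 1),
                                 round_half_up(tab$adj_change_control_sd, 1)),
    adj_change_pn = sprintf("%.1f (%.1f)",
                            round_half_up(tab$adj_change_pn, 1),
                            round_half_up(tab$adj_change_pn_sd, 1)),
    treatment_effect = sprintf("%.1f (%.2f to %.2f)",
                               round_half_up(tab$effect, 1),
                               tab$ci_low, tab$ci_high),
    p_value = signif(tab$p_value, 3),
    stringsAsFactors = FALSE)
  csv_path <- file.path(dir, "treatment_effects.csv")
  json_path <- file.path(dir, "treatment_effects.json")
  utils::write.csv(pretty, csv_path, row.names = FALSE)
  jsonlite::write_json(tab, json_path, digits = NA, auto_unbox = TRUE)
  invisible(c(csv_path, json_path))
}

#' Write QC output
#'
#' Per-participant QC verdicts as CSV and the CONSORT-style accounting as
#' JSON.
#'
#' @param qc a [run_qc()] result.
#' @param dir output directory.
#' @return Paths written, invisibly.
#' @export
write_qc <- function(qc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(dir, "qc_results.csv")
  json_path <- file.path(dir, "qc_accounting.json")
  utils::write.csv(qc$results, csv_path, row.names = FALSE)
  jsonlite::write_json(qc$accounting, json_path, digits = NA)
  invisible(c(csv_path, json_path))
}
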