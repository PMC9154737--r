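# shared fixtures built in code

fix_criteria <- mahei_criteria()

# profile with every component at a given score (0-100), via the criteria's
# inverse interpolation
profile_at_score <- function(score, criteria = fix_criteria, energy = 8500) {
  amt <- criteria$zero_score_intake +
    score / 100 * (criteria$full_score_intake - criteria$zero_score_intake)
  intake_profile(stats::setNames(amt, criteria$name), energy_kj_day = energy)
}

# random valid criterion (either direction), thresholds >= 0
random_criterion <- function() {
  lo <- runif(1, 0, 10)
  hi <- lo + runif(1, 0.5, 10)
  if (runif(1) < 0.5) {
    list(name = "x", direction = "positive", metric = "u",
         zero_score_intake = lo, full_score_intake = hi)
  } else {
    list(name = "x", direction = "negative", metric = "u",
         zero_score_intake = hi, full_score_intake = lo)
  }
}

# minimal two-visit cohort for one participant, amounts given per visit as
# named vectors in criteria metrics
tiny_cohort <- function(amount_base, amount_end, energy = c(8000, 8200),
                        weight = c(70, 70), day_end = 84,
                        sex = "female", age = 35, height = 1.65,
                        group = "pn", pid = "P1", foods = NULL) {
  participants <- data.frame(participant_id = pid, group = group, sex = sex,
                             age_years = age, height_m = height,
                             stringsAsFactors = FALSE)
  visits <- data.frame(participant_id = pid, visit = c("ffq1", "ffq3"),
                       day = c(0, day_end), weight_kg = weight,
                       energy_kj_day = energy, stringsAsFactors = FALSE)
  intakes <- rbind(
    data.frame(participant_id = pid, visit = "ffq1",
               component = names(amount_base), amount = unname(amount_base),
               stringsAsFactors = FALSE),
    data.frame(participant_id = pid, visit = "ffq3",
               component = names(amount_end), amount = unname(amount_end),
               stringsAsFactors = FALSE))
  mahei_cohort(participants, visits, intakes, foods)
}
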