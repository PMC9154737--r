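test_that("advice targets the three lowest-scoring components", {
  crit <- fix_criteria
  scores <- setNames(rep(100, 11), crit$name)
  scores[c("salt", "fruit", "alcohol")] <- c(10, 20, 30)
  sel <- select_advice_components(scores, 3, crit)
  expect_equal(sel$component, c("salt", "fruit", "alcohol"))  # ascending score

  # all equal -> first three components in criteria order
  sel2 <- select_advice_components(setNames(rep(50, 11), crit$name), 3, crit)
  expect_equal(sel2$component, crit$name[1:3])

  # three-way tie among four low scores -> criteria order breaks it
  scores3 <- setNames(rep(100, 11), crit$name)
  scores3[c("fruit", "dairy", "salt")] <- 5       # criteria order: fruit < dairy < salt
  scores3["alcohol"] <- 50
  sel3 <- select_advice_components(scores3, 3, crit)
  expect_equal(sel3$component, c("fruit", "dairy", "salt"))
})

test_that("selection is consistent across k and input order", {
  set.seed(11)
  for (i in 1:20) {
    scores <- setNames(sample(c(0, 25, 25, 50, 50, 50, 75, 100), 11, replace = TRUE),
                       fix_criteria$name)
    all11 <- select_advice_components(scores, 11)
    top3 <- select_advice_components(scores, 3)
    expect_equal(all11$component[1:3], top3$component)
    expect_equal(nrow(all11), 11)
    # permuting storage order of the scores changes nothing
    perm <- sample(11)
    expect_equal(select_advice_components(scores[perm], 3)$component,
                 top3$component)
  }
  expect_error(select_advice_components(setNames(rep(1, 11), fix_criteria$name), 12))
})

test_that("diet messages carry component, filled template and top foods", {
  foods <- data.frame(food_id = "f1", food_label = "bacon", daily_amount = 1.4,
                      component = "red_processed_meat", contribution = 1.4,
                      stringsAsFactors = FALSE)
  amt <- setNames(fix_criteria$full_score_intake, fix_criteria$name)
  amt[c("red_processed_meat", "salt", "free_sugars")] <- c(1.4, 11.9, 19)
  p <- intake_profile(amt, 8000, foods = foods)
  sel <- select_advice_components(score_profile(p), 3)
  msgs <- build_diet_messages(sel, p)

  expect_length(msgs, 3)
  comps <- vapply(msgs, `[[`, "", "component")
  expect_equal(anyDuplicated(comps), 0)
  meat <- msgs[[which(comps == "red_processed_meat")]]
  expect_match(meat$text, "bacon")
  # component with no recorded contributors still gets a message
  salt <- msgs[[which(comps == "salt")]]
  expect_equal(nrow(salt$foods), 0)
  expect_match(salt$text, "none recorded")

  expect_error(build_diet_messages(sel, p, templates = c(salt = "x")),
               "template")
})

test_that("BMI feedback uses the 18.5-25 range and its 21.75 midpoint", {
  fb <- bmi_feedback(2.0, 87.0)
  expect_equal(fb$bmi, 21.75)
  expect_equal(fb$ideal_bmi_mid, 21.75)
  expect_equal(fb$distance_to_midpoint, 0)
  expect_equal(fb$distance_to_range, 0)

  fb2 <- bmi_feedback(1.0, 30.0)
  expect_equal(fb2$bmi, 30)
  expect_equal(fb2$distance_to_range, 5)       # to the 25.0 bound
  expect_equal(fb2$distance_to_midpoint, 8.25) # to 21.75

  set.seed(3)
  for (i in 1:25) {
    h <- runif(1, 1.4, 2.1); w <- runif(1, 40, 140)
    fb <- bmi_feedback(h, w)
    expect_equal(fb$ideal_weight_mid / h^2, 21.75)
    expect_gte(fb$distance_to_midpoint, 0)
    expect_gte(fb$distance_to_range, 0)
    expect_equal(fb$ideal_weight_range, c(18.5, 25) * h^2)
  }
  expect_error(bmi_feedback(0, 70), "positive")
})

test_that("Baecke scores rescale 1-5 category indices to 0-100", {
  lo <- list(work = rep(1, 8), sports = rep(1, 4), leisure = rep(1, 4))
  hi <- list(work = rep(5, 8), sports = rep(5, 4), leisure = rep(5, 4))
  mid <- list(work = rep(3, 8), sports = rep(3, 4), leisure = rep(3, 4))

  expect_equal(unlist(baecke_scores(lo)[c("work_score", "sports_score",
                                          "leisure_score", "overall_score")],
                      use.names = FALSE), rep(0, 4))
  expect_equal(baecke_scores(hi)$overall_score, 100)
  expect_equal(baecke_scores(mid)$sports_score, 50)

  # invariant to answer ordering, monotone in each answer
  a <- list(work = c(2, 4, 3, 1, 5, 2, 3, 4), sports = c(1, 3, 2, 4),
            leisure = c(2, 2, 3, 5))
  b <- lapply(a, rev)
  expect_equal(baecke_scores(a)$overall_score, baecke_scores(b)$overall_score)
  a2 <- a; a2$sports[1] <- 2
  expect_gt(baecke_scores(a2)$sports_score, baecke_scores(a)$sports_score)

  # messages for sports and leisure only, never work
  expect_named(baecke_scores(a)$messages, c("sports", "leisure"))
  expect_error(baecke_scores(list(work = c(1, NA), sports = 1, leisure = 1)),
               "incomplete")
})

test_that("control reports are fixed per week and deterministic", {
  b <- control_report("baseline")
  expect_equal(vapply(b$diet_messages, `[[`, "", "component"),
               c("vegetables", "free_sugars", "healthy_fats"))
  w6 <- control_report("week6")
  expect_equal(vapply(w6$diet_messages, `[[`, "", "component"),
               c("fruit", "whole_grains", "red_processed_meat"))
  expect_identical(control_report("week6"), w6)
  expect_error(control_report("week9"))
})

test_that("the full personalized report assembles all four elements", {
  p <- profile_at_score(60)
  rep <- pn_report(p, height_m = 1.7, weight_kg = 72,
                   pa_answers = list(work = rep(3, 8), sports = rep(2, 4),
                                     leisure = rep(4, 4)))
  expect_equal(rep$overall_mahei, 60, tolerance = 1e-9)
  expect_length(rep$diet_messages, 3)
  expect_s3_class(rep$bmi_feedback, "bmi_feedback")
  expect_s3_class(rep$pa_feedback, "pa_feedback")
})
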