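sspi_items <- function(mv = 0, u12 = 0, ef = 0, mult = 0, csam = 0) {
  data.frame(male_victim = mv, victim_under_12 = u12,
             extrafamilial_victim = ef, multiple_victims = mult,
             known_csam_offense = csam)
}

static_items <- function(partner = 1, viol = 0, pso = 0, sent = 0, nc = 0,
                         unrel = 0, stranger = 0, male = 0, pc = 0,
                         young2 = 0) {
  data.frame(lived_with_partner_2y = partner, prior_nonsexual_violence = viol,
             prior_sex_offenses = pso, prior_sentencing_dates = sent,
             noncontact_sexual_conviction = nc, unrelated_victim = unrel,
             stranger_victim = stranger, male_victim = male,
             prior_convictions = pc, two_or_more_young_victims = young2)
}

stable_items <- function(value = 0, ...) {
  cols <- c("significant_social_influences",
            "capacity_for_relationship_stability",
            "emotional_identification_with_children", "hostility_toward_women",
            "general_social_rejection", "lack_of_concern_for_others",
            "impulsive_acts", "poor_cognitive_problem_solving",
            "negative_emotionality", "sex_drive_preoccupation",
            "sex_as_coping", "deviant_sexual_interest",
            "cooperation_with_supervision")
  d <- as.data.frame(setNames(rep(list(value), length(cols)), cols))
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d
}

acute_items <- function(value = 0, ...) {
  cols <- c("access_to_victim", "hostility", "sexual_preoccupation",
            "rejection_of_supervision", "emotional_collapse",
            "change_in_social_support", "substance_abuse")
  d <- as.data.frame(setNames(rep(list(value), length(cols)), cols))
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d
}

test_that("SSPI-2 is the unweighted sum of five binary items", {
  expect_equal(score_sspi2(sspi_items()), 0L, ignore_attr = TRUE)
  expect_equal(score_sspi2(sspi_items(1, 1, 1, 1, 1)), 5L, ignore_attr = TRUE)
  expect_equal(score_sspi2(sspi_items(mv = 1, mult = 1)), 2L,
               ignore_attr = TRUE)
  withNA <- score_sspi2(sspi_items(mv = 1, u12 = NA))
  expect_true(is.na(withNA))
  expect_equal(attr(withNA, "n_items_present"), 4L)
  set.seed(61)
  many <- sspi_items(mv = rbinom(50, 1, 0.5), u12 = rbinom(50, 1, 0.5),
                     ef = rbinom(50, 1, 0.5), mult = rbinom(50, 1, 0.5),
                     csam = rbinom(50, 1, 0.5))
  expect_true(all(score_sspi2(many) <= 5))
})

test_that("adapted STATIC scoring reproduces factor definitions", {
  # age 24, never partnered, prior violence, stranger victim
  s <- score_static_dunkelfeld(
    static_items(partner = 0, viol = 1, stranger = 1), age_at_assessment = 24)
  expect_equal(s$static_ysa, 4L)

  # no convictions, no violence
  s2 <- score_static_dunkelfeld(static_items(), age_at_assessment = 40)
  expect_equal(s2$static_gc, 0L)

  # everything at maximum reaches the documented adapted total
  smax <- score_static_dunkelfeld(
    static_items(partner = 0, viol = 1, pso = 3, sent = 1, nc = 1, unrel = 1,
                 stranger = 1, male = 1, pc = 10, young2 = 1),
    age_at_assessment = 20)
  expect_equal(smax$static_sum, static_dunkelfeld_max())
  expect_equal(smax$static_paraphilia, 7L)
  expect_equal(smax$static_gc, 4L)  # conviction count capped at 3, plus violence

  # unknowns poison only the scores they enter
  s3 <- score_static_dunkelfeld(static_items(pso = NA, viol = 1, pc = 2),
                                age_at_assessment = 30)
  expect_true(is.na(s3$static_sum))
  expect_true(is.na(s3$static_paraphilia))
  expect_equal(s3$static_gc, 3L)
})

test_that("STABLE factors sum their constituent items with reversal", {
  z <- score_stable_factors(stable_items(0))
  # capacity-for-relationship-stability is reverse coded: all-zero items
  # still contribute 2 to antisociality
  expect_equal(z$stable_sum, 0L)
  expect_equal(z$stable_antisociality, 2L)
  expect_equal(z$stable_sexual_deviance, 0L)

  dev <- score_stable_factors(
    stable_items(0, emotional_identification_with_children = 2,
                 deviant_sexual_interest = 2))
  expect_equal(dev$stable_sexual_deviance, 4L)
  expect_equal(dev$stable_sum, 4L)

  allmax <- score_stable_factors(stable_items(2))
  expect_equal(allmax$stable_sum, 26L)
  expect_equal(allmax$stable_antisociality, 12L)
  expect_equal(allmax$stable_hypersexuality, 4L)
  expect_true(all(allmax$stable_sexual_deviance <= 4))

  nas <- score_stable_factors(stable_items(1, sex_as_coping = NA))
  expect_true(is.na(nas$stable_sum))
  expect_true(is.na(nas$stable_hypersexuality))
  expect_false(is.na(nas$stable_sexual_deviance))
})

test_that("ACUTE is the plain 0-14 item sum", {
  expect_equal(score_acute(acute_items(0)), 0L)
  expect_equal(score_acute(acute_items(2)), 14L)
  expect_equal(score_acute(acute_items(0, hostility = 2)), 2L)
  expect_true(is.na(score_acute(acute_items(1, substance_abuse = NA))))
  expect_error(score_acute(acute_items(3)), "0-2")
})

test_that("factor scores never exceed the total they are drawn from", {
  set.seed(67)
  n <- 60
  st <- stable_items(0)[rep(1, n), ]
  for (nm in names(st)) st[[nm]] <- sample(0:2, n, replace = TRUE)
  sc <- score_stable_factors(st)
  expect_true(all(sc$stable_sexual_deviance <= sc$stable_sum))
  expect_true(all(sc$stable_hypersexuality <= sc$stable_sum))
})
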