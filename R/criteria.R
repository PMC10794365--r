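#' @name criteria_scales
#' @title Scoring of external criterion instruments
#' @description
#' Scoring of the behavioral criterion instruments in their adaptation for
#' help-seeking, non-adjudicated ("Dunkelfeld") samples. All scorers are
#' vectorized over participants (one row per participant) and propagate
#' unknowns exactly: a sum or factor score is `NA` iff one of its
#' constituent items is unknown.
#'
#' Item ranges follow the published instruments (binary for SSPI-2 and most
#' adapted STATIC-99 items, 0-2 for STABLE-2007 and ACUTE-2007 items).
#' The STATIC-99 adaptation drops the index-offense violence item entirely
#' and replaces age at release by age at assessment; factor definitions are
#' adjusted accordingly (see [score_static_dunkelfeld()]).
NULL

.check_binary <- function(items, cols) {
  for (cl in cols) {
    v <- items[[cl]]
    if (is.null(v)) stop("missing item column '", cl, "'", call. = FALSE)
    if (!all(v %in% c(0, 1, NA))) {
      stop("item '", cl, "' must be binary 0/1 (NA = unknown)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

.check_0_2 <- function(items, cols) {
  for (cl in cols) {
    v <- items[[cl]]
    if (is.null(v)) stop("missing item column '", cl, "'", call. = FALSE)
    if (!all(v %in% c(0, 1, 2, NA))) {
      stop("item '", cl, "' must be scored 0-2 (NA = unknown)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

.sum_items <- function(items, cols) {
  m <- as.matrix(as.data.frame(lapply(items[cols], as.numeric)))
  as.integer(rowSums(m))  # NA whenever any constituent is NA
}

#' Score the SSPI-2 screening scale
#'
#' Five yes/no offense-history items: any male victim, any victim under 12,
#' any extrafamilial victim, multiple victims, any known CSAM offense.
#' The score is the unweighted sum (0-5).
#'
#' @param items Data frame with binary columns `male_victim`,
#'   `victim_under_12`, `extrafamilial_victim`, `multiple_victims`,
#'   `known_csam_offense`.
#' @return Integer vector 0-5 (`NA` where any item is unknown), with
#'   attribute `"n_items_present"` counting non-missing items per row.
#' @rdname criteria_scales
#' @export
score_sspi2 <- function(items) {
  cols <- c("male_victim", "victim_under_12", "extrafamilial_victim",
            "multiple_victims", "known_csam_offense")
  .check_binary(items, cols)
  out <- .sum_items(items, cols)
  attr(out, "n_items_present") <-
    as.integer(rowSums(!is.na(as.data.frame(items[cols]))))
  out
}

#' Maximum total of the adapted STATIC-99 scoring used here
#' @rdname criteria_scales
#' @export
static_dunkelfeld_max <- function() 11L

#' Score the Dunkelfeld adaptation of the STATIC-99
#'
#' Nine scored components (the index-offense violence item is dropped; age
#' at assessment replaces age at release): age-at-assessment < 25, never
#' lived with an intimate partner for two years, prior non-sexual violence,
#' prior sexual offenses (banded item score 0-3), four or more prior
#' sentencing dates, any non-contact sexual conviction, any unrelated
#' victim, any stranger victim, any male victim. Total range 0-11
#' ([static_dunkelfeld_max()]).
#'
#' Factor scores under the adaptation:
#' * *Paraphilia*: prior sexual offenses (0-3) + non-contact sexual
#'   conviction + male victim + two or more young victims + unrelated
#'   victim (0-7);
#' * *Youthful stranger aggression*: age < 25 + never lived with a partner
#'   two years + prior non-sexual violence + any unrelated-or-stranger
#'   victim (0-4; four components by construction, even though observed
#'   scores in the population the adaptation was built for ranged 0-3);
#' * *General criminality*: number of prior convictions (capped at 3) +
#'   prior non-sexual violence (0-4).
#'
#' @param items Data frame with columns `lived_with_partner_2y`,
#'   `prior_nonsexual_violence`, `prior_sex_offenses` (0-3),
#'   `prior_sentencing_dates` (binary: 4+), `noncontact_sexual_conviction`,
#'   `unrelated_victim`, `stranger_victim`, `male_victim`,
#'   `prior_convictions` (count), `two_or_more_young_victims`.
#' @param age_at_assessment Numeric vector of ages.
#' @return Data frame with `static_sum`, `static_paraphilia`,
#'   `static_ysa`, `static_gc`.
#' @rdname criteria_scales
#' @export
score_static_dunkelfeld <- function(items, age_at_assessment) {
  bin <- c("lived_with_partner_2y", "prior_nonsexual_violence",
           "prior_sentencing_dates", "noncontact_sexual_conviction",
           "unrelated_victim", "stranger_victim", "male_victim",
           "two_or_more_young_victims")
  .check_binary(items, bin)
  pso <- items$prior_sex_offenses
  if (is.null(pso) || !all(pso %in% c(0:3, NA))) {
    stop("'prior_sex_offenses' must be a banded item score 0-3", call. = FALSE)
  }
  pc <- items$prior_convictions
  if (is.null(pc) || any(!is.na(pc) & (pc < 0 | pc != round(pc)))) {
    stop("'prior_convictions' must be a non-negative count", call. = FALSE)
  }
  young <- as.numeric(age_at_assessment < 25)
  never_partner <- 1 - as.numeric(items$lived_with_partner_2y)
  viol <- as.numeric(items$prior_nonsexual_violence)
  unrel_or_stranger <- pmax(as.numeric(items$unrelated_victim),
                            as.numeric(items$stranger_victim))
  # NA handling for the OR: TRUE beats unknown, unknown beats FALSE
  both_na <- is.na(items$unrelated_victim) & is.na(items$stranger_victim)
  one_true <- (!is.na(items$unrelated_victim) & items$unrelated_victim == 1) |
    (!is.na(items$stranger_victim) & items$stranger_victim == 1)
  unrel_or_stranger[one_true] <- 1
  unrel_or_stranger[both_na] <- NA

  total <- young + never_partner + viol + as.numeric(pso) +
    as.numeric(items$prior_sentencing_dates) +
    as.numeric(items$noncontact_sexual_conviction) +
    as.numeric(items$unrelated_victim) +
    as.numeric(items$stranger_victim) +
    as.numeric(items$male_victim)
  paraphilia <- as.numeric(pso) +
    as.numeric(items$noncontact_sexual_conviction) +
    as.numeric(items$male_victim) +
    as.numeric(items$two_or_more_young_victims) +
    as.numeric(items$unrelated_victim)
  ysa <- young + never_partner + viol + unrel_or_stranger
  gc <- pmin(as.numeric(pc), 3) + viol
  data.frame(static_sum = as.integer(total),
             static_paraphilia = as.integer(paraphilia),
             static_ysa = as.integer(ysa),
             static_gc = as.integer(gc))
}

#' Score the STABLE-2007 total and empirical factors
#'
#' Thirteen items scored 0-2. The total is the plain item sum (0-26).
#' Factors: *Antisociality* = reversed capacity for relationship stability
#' (i.e. `2 - item`) + hostility toward women + general social rejection +
#' lack of concern for others + impulsive acts + poor cognitive problem
#' solving + negative emotionality (0-14); *Sexual deviance* = emotional
#' identification with children + deviant sexual interest (0-4);
#' *Hypersexuality* = sex drive/preoccupation + sex as coping (0-4).
#'
#' @param items Data frame with 0-2 columns `significant_social_influences`,
#'   `capacity_for_relationship_stability`,
#'   `emotional_identification_with_children`, `hostility_toward_women`,
#'   `general_social_rejection`, `lack_of_concern_for_others`,
#'   `impulsive_acts`, `poor_cognitive_problem_solving`,
#'   `negative_emotionality`, `sex_drive_preoccupation`, `sex_as_coping`,
#'   `deviant_sexual_interest`, `cooperation_with_supervision`.
#' @return Data frame with `stable_sum`, `stable_antisociality`,
#'   `stable_sexual_deviance`, `stable_hypersexuality`.
#' @rdname criteria_scales
#' @export
score_stable_factors <- function(items) {
  all13 <- c("significant_social_influences",
             "capacity_for_relationship_stability",
             "emotional_identification_with_children",
             "hostility_toward_women", "general_social_rejection",
             "lack_of_concern_for_others", "impulsive_acts",
             "poor_cognitive_problem_solving", "negative_emotionality",
             "sex_drive_preoccupation", "sex_as_coping",
             "deviant_sexual_interest", "cooperation_with_supervision")
  .check_0_2(items, all13)
  anti_items <- c("hostility_toward_women", "general_social_rejection",
                  "lack_of_concern_for_others", "impulsive_acts",
                  "poor_cognitive_problem_solving", "negative_emotionality")
  data.frame(
    stable_sum = .sum_items(items, all13),
    stable_antisociality = as.integer(
      (2 - as.numeric(items$capacity_for_relationship_stability)) +
        .sum_items(items, anti_items)),
    stable_sexual_deviance = .sum_items(
      items, c("emotional_identification_with_children",
               "deviant_sexual_interest")),
    stable_hypersexuality = .sum_items(
      items, c("sex_drive_preoccupation", "sex_as_coping"))
  )
}

#' Score the ACUTE-2007 sum
#'
#' Seven items scored 0-2: access to a potential victim, hostility, sexual
#' preoccupation, rejection of supervision, emotional collapse, change in
#' social support, substance abuse. Sum range 0-14.
#'
#' @param items Data frame with 0-2 columns `access_to_victim`, `hostility`,
#'   `sexual_preoccupation`, `rejection_of_supervision`,
#'   `emotional_collapse`, `change_in_social_support`, `substance_abuse`.
#' @return Integer vector 0-14 (`NA` where any item is unknown).
#' @rdname criteria_scales
#' @export
score_acute <- function(items) {
  cols <- c("access_to_victim", "hostility", "sexual_preoccupation",
            "rejection_of_supervision", "emotional_collapse",
            "change_in_social_support", "substance_abuse")
  .check_0_2(items, cols)
  .sum_items(items, cols)
}
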