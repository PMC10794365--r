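#' Default cohort calibration
#'
#' Returns the cohort configuration that reproduces the statistical structure
#' of the clinical study sample the pipeline was designed for: 282
#' participants (68 without and 214 with a clinical diagnosis of sexual
#' interest in minors), 10 stimulus categories x 8 trials, group-specific
#' per-category latency and attractiveness-rating means/SDs as published for
#' that sample, censoring of non-responses at 5000 ms, and subgroup
#' prevalences for prior child sexual offenses (CSO, 30%) and prior child
#' sexual abuse material use (CSAM, 72%).
#'
#' Only marginal prevalences are published; the joint (diagnosis, CSO, CSAM)
#' cell table used here is derived once from those marginals by
#' inclusion-exclusion (offense cells: neither 49, CSO-only 31, CSAM-only
#' 149, both 53) with the diagnosis rate applied proportionally within each
#' offense cell. Participant-level structure (random speed intercept, a
#' "child-shift" random effect shared by all Tanner 1-3 categories, Gaussian
#' trial noise at the published category SD) is likewise an explicit modeling
#' choice; see the package vignette.
#'
#' @param n_participants Cohort size (default 282).
#' @return A `vrt_cohort_config` list understood by [simulate_cohort()].
#'   Latency/rating calibration matrices have rows `no_interest` /
#'   `interest` and one column per category.
#' @export
default_calibration <- function(n_participants = 282L) {
  cats <- .vrt_all_categories()   # MT1..MT5, FT1..FT5

  lat_mean <- rbind(
    no_interest = c(1005, 994, 1098, 1126, 1161, 1154, 1217, 1379, 1999, 2201),
    interest    = c(1426, 1433, 1460, 1390, 1191, 1932, 2001, 2053, 2112, 1996)
  )
  lat_sd <- rbind(
    no_interest = c(429, 456, 490, 523, 572, 516, 568, 690, 651, 757),
    interest    = c(741, 786, 777, 691, 554, 743, 742, 759, 749, 722)
  )
  rating_mean <- rbind(
    no_interest = c(1.07, 1.09, 1.11, 1.21, 1.21, 1.08, 1.09, 1.14, 1.74, 2.26),
    interest    = c(1.36, 1.47, 1.41, 1.30, 1.12, 1.90, 2.01, 2.08, 2.23, 2.01)
  )
  colnames(lat_mean) <- colnames(lat_sd) <- colnames(rating_mean) <- cats

  # joint prevalence cells: pedohebephilia x CSO x CSAM, counts per 282
  cells <- data.frame(
    pedohebephilia = rep(c(FALSE, TRUE), times = 4L),
    cso  = rep(c(FALSE, FALSE, TRUE, TRUE), each = 2L),
    csam = rep(c(FALSE, TRUE, FALSE, TRUE), each = 2L)
  )
  cells <- cells[order(cells$cso, cells$csam, cells$pedohebephilia), ]
  #            neither   CSAM-only  CSO-only   both
  counts <- c(12, 37,   36, 113,   7, 24,    13, 40)
  cells$prob <- counts / sum(counts)
  rownames(cells) <- NULL

  structure(list(
    n_participants = as.integer(n_participants),
    trials_per_category = 8L,
    cells = cells,
    latency_mean = lat_mean,
    latency_sd = lat_sd,
    rating_mean = rating_mean,
    rating_sd = 0.7,
    speed_sd = 300,
    child_shift_sd = 550,
    noise = "gaussian",
    floor_ms = 150,
    censor_at = 5000,
    mcar_rate = 0.03,
    interval_range = c(0L, 28L),
    criterion_rho = 0.35,
    seed = NULL
  ), class = "vrt_cohort_config")
}

.check_cohort_config <- function(config) {
  stopifnot(inherits(config, "vrt_cohort_config") || is.list(config))
  with(config, {
    stopifnot(
      n_participants >= 0,
      trials_per_category >= 1,
      all(latency_sd > 0), rating_sd > 0,
      speed_sd >= 0, child_shift_sd >= 0,
      all(config$cells$prob >= 0), abs(sum(config$cells$prob) - 1) < 1e-8,
      mcar_rate >= 0, mcar_rate <= 1,
      censor_at > 0, floor_ms > 0,
      noise %in% c("gaussian", "lognormal")
    )
  })
  invisible(config)
}

#' Simulate a VRT cohort
#'
#' Draws a full synthetic cohort under `config`: each participant is assigned
#' a (diagnosis, CSO, CSAM) cell, a general-speed random intercept
#' `~ N(0, speed_sd)`, and a child-shift random effect `~ N(0,
#' child_shift_sd)` added to all pre-/peripubertal (Tanner 1-3) categories.
#' Trial latencies are the group/category mean plus these offsets plus trial
#' noise at the published category SD (Gaussian by default; a log-normal
#' option reflects the right skew of real response latencies), floored at
#' `floor_ms`. Latencies exceeding `censor_at` become non-response trials
#' (missing latency *and* rating) — the paradigm's own missingness mechanism,
#' missing-at-random by category. An additional completely-at-random masking
#' at `mcar_rate` is applied on top. Ratings are drawn from a rounded
#' Gaussian centered on the group/category rating mean, clamped to 1-4.
#'
#' @param config A `vrt_cohort_config`, see [default_calibration()].
#' @param seed Optional integer seed (overrides `config$seed`).
#' @return List with `trials` and `participants` tables. The participant
#'   table carries two generator-truth columns not part of the on-disk
#'   contract: `speed_offset` and `latent_deviance` (the participant's true
#'   noise-free child-minus-adult latency contrast in ms, used to calibrate
#'   criterion scales).
#' @export
simulate_cohort <- function(config = default_calibration(), seed = NULL) {
  .check_cohort_config(config)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)

  n <- config$n_participants
  cats <- .vrt_all_categories()
  ncat <- length(cats)
  tpc <- config$trials_per_category
  child <- vrt_categories()$is_child

  if (n == 0L) {
    trials <- data.frame(participant_id = character(0), sex = character(0),
                         tanner = integer(0), trial_index = integer(0),
                         latency_ms = numeric(0), rating = integer(0),
                         category = character(0), missing = logical(0),
                         stringsAsFactors = FALSE)
    participants <- data.frame(participant_id = character(0),
                               pedohebephilia = logical(0), cso = logical(0),
                               csam = logical(0),
                               days_interview_to_vrt = integer(0),
                               speed_offset = numeric(0),
                               latent_deviance = numeric(0),
                               stringsAsFactors = FALSE)
    return(list(trials = trials, participants = participants))
  }

  pid <- sprintf("P%04d", seq_len(n))
  cell <- sample.int(nrow(config$cells), n, replace = TRUE,
                     prob = config$cells$prob)
  pedo <- config$cells$pedohebephilia[cell]
  cso <- config$cells$cso[cell]
  csam <- config$cells$csam[cell]
  group <- ifelse(pedo, "interest", "no_interest")
  speed <- stats::rnorm(n, 0, config$speed_sd)
  shift <- stats::rnorm(n, 0, config$child_shift_sd)
  days <- sample(seq(config$interval_range[1], config$interval_range[2]),
                 n, replace = TRUE)

  # latent deviance: true child-minus-adult contrast incl. the child shift
  mu <- config$latency_mean[group, , drop = FALSE]
  max_child <- apply(mu[, child, drop = FALSE], 1L, max) + shift
  max_adult <- apply(mu[, !child, drop = FALSE], 1L, max)
  latent <- max_child - max_adult

  ntr <- n * ncat * tpc
  p_idx <- rep(seq_len(n), each = ncat * tpc)
  c_idx <- rep(rep(seq_len(ncat), each = tpc), times = n)
  mu_trial <- config$latency_mean[cbind(group[p_idx], cats[c_idx])] +
    speed[p_idx] + shift[p_idx] * child[c_idx]
  sd_trial <- config$latency_sd[cbind(group[p_idx], cats[c_idx])]

  if (config$noise == "gaussian") {
    lat <- stats::rnorm(ntr, mu_trial, sd_trial)
  } else {
    m <- pmax(mu_trial, config$floor_ms)
    sdlog <- sqrt(log1p((sd_trial / m)^2))
    lat <- stats::rlnorm(ntr, log(m) - sdlog^2 / 2, sdlog)
  }
  lat <- pmax(lat, config$floor_ms)

  miss <- lat > config$censor_at
  if (config$mcar_rate > 0) {
    miss <- miss | stats::runif(ntr) < config$mcar_rate
  }

  rating <- round(stats::rnorm(
    ntr, config$rating_mean[cbind(group[p_idx], cats[c_idx])],
    config$rating_sd))
  rating <- pmin(pmax(rating, 1L), 4L)
  lat[miss] <- NA_real_
  rating[miss] <- NA_integer_

  catinfo <- vrt_categories()
  trials <- data.frame(
    participant_id = pid[p_idx],
    sex = catinfo$sex[c_idx],
    tanner = catinfo$tanner[c_idx],
    trial_index = rep(seq_len(ncat * tpc) - 1L, times = n),
    latency_ms = round(lat, 1),
    rating = as.integer(rating),
    category = cats[c_idx],
    missing = miss,
    stringsAsFactors = FALSE
  )
  participants <- data.frame(
    participant_id = pid,
    pedohebephilia = pedo,
    cso = cso,
    csam = csam,
    days_interview_to_vrt = days,
    speed_offset = speed,
    latent_deviance = latent,
    stringsAsFactors = FALSE
  )
  list(trials = trials, participants = participants)
}

# integer score ranges of the external criterion instruments, as observed
# in the target population (used for binning simulated scores)
.criterion_ranges <- function() {
  list(
    sspi2                  = c(0L, 5L),
    static_sum             = c(0L, 8L),
    static_paraphilia      = c(0L, 6L),
    static_ysa             = c(0L, 3L),
    static_gc              = c(0L, 4L),
    stable_sum             = c(2L, 20L),
    stable_antisociality   = c(0L, 11L),
    stable_sexual_deviance = c(1L, 4L),
    stable_hypersexuality  = c(0L, 4L),
    acute_sum              = c(0L, 14L)
  )
}

#' Simulate external criterion-scale scores
#'
#' Generates ordinal criterion scores (SSPI-2, adapted STATIC-99 sum and
#' factors, STABLE-2007 sum and factors, ACUTE-2007 sum) whose population
#' Spearman correlation with the participant's latent deviance equals
#' `rho_target`. A Gaussian copula is used: the latent deviance ranks are
#' mapped to normal scores, each scale adds independent normal noise at
#' copula correlation `2*sin(pi*rho_target/6)` (the inverse of the
#' bivariate-normal Spearman relation), and the resulting uniform is binned
#' into the instrument's observed integer range. As in the study design,
#' scores are generated only for diagnosed participants with a prior CSO
#' history (`subset = "diagnosed_cso"`); all other participants receive `NA`.
#'
#' @param participants Participant table from [simulate_cohort()] (must carry
#'   `latent_deviance`).
#' @param rho_target Target Spearman correlation in (-1, 1).
#' @param seed Optional integer seed.
#' @param subset `"diagnosed_cso"` (default) or `"all"`.
#' @return The participant table with ten criterion-score columns appended.
#' @export
simulate_criteria <- function(participants, rho_target = 0.35, seed = NULL,
                              subset = c("diagnosed_cso", "all")) {
  subset <- match.arg(subset)
  if (!is.numeric(rho_target) || length(rho_target) != 1L ||
      is.na(rho_target) || abs(rho_target) >= 1) {
    stop("rho_target must lie strictly within (-1, 1)", call. = FALSE)
  }
  if (is.null(participants$latent_deviance)) {
    stop("participants table lacks the generator's 'latent_deviance' column",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  sel <- if (subset == "diagnosed_cso") {
    which(participants$pedohebephilia & participants$cso)
  } else {
    seq_len(nrow(participants))
  }
  n <- length(sel)
  ranges <- .criterion_ranges()
  for (nm in names(ranges)) {
    participants[[nm]] <- rep(NA_integer_, nrow(participants))
  }
  if (n == 0L) return(participants)

  rho_c <- 2 * sin(pi * rho_target / 6)  # copula correlation for target Spearman
  z_dev <- stats::qnorm((rank(participants$latent_deviance[sel],
                              ties.method = "average") - 0.5) / n)
  for (nm in names(ranges)) {
    z <- rho_c * z_dev + sqrt(1 - rho_c^2) * stats::rnorm(n)
    u <- stats::pnorm(z)
    lo <- ranges[[nm]][1]; hi <- ranges[[nm]][2]
    score <- lo + floor(u * (hi - lo + 1L))
    participants[[nm]][sel] <- as.integer(pmin(score, hi))
  }
  participants
}
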