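#' Assemble a full-analysis configuration
#'
#' Collects every tunable of the end-to-end analysis in one serializable
#' list. Defaults equal the values of the study design the pipeline
#' implements: 10% missing-trial threshold (strict), 28-day
#' interview-to-VRT window, within-person z-standardization, individual
#' category mean as the reference imputation, m = 5 / k = 5 for predictive
#' mean matching, alpha = 0.05 equivalence via 90% CIs, 2000 bootstrap
#' replicates for AUC intervals.
#'
#' Input data can be given as file paths (`trials_path`,
#' `participants_path`) or left `NULL`, in which case a synthetic cohort is
#' generated from `cohort_config` under `seed`.
#'
#' @param trials_path,participants_path Optional CSV paths.
#' @param cohort_config A `vrt_cohort_config` used when no paths are given.
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param threshold,max_interval_days Eligibility parameters.
#' @param methods Imputation methods of the sensitivity grid.
#' @param bases Index bases of the sensitivity grid.
#' @param m,k_donors PMM parameters.
#' @param alpha Equivalence/test level.
#' @param bootstrap_reps Bootstrap replicates for AUC CIs.
#' @return An `vrt_analysis_config` list.
#' @export
analysis_config <- function(trials_path = NULL, participants_path = NULL,
                            cohort_config = default_calibration(),
                            seed = 1L,
                            threshold = 0.10, max_interval_days = 28L,
                            methods = c("individual_mean", "regression",
                                        "pmm", "pmm_by_individual"),
                            bases = c("ipsatized", "raw"),
                            m = 5L, k_donors = 5L,
                            alpha = 0.05, bootstrap_reps = 2000L) {
  structure(list(
    trials_path = trials_path, participants_path = participants_path,
    cohort_config = cohort_config, seed = as.integer(seed),
    threshold = threshold, max_interval_days = as.integer(max_interval_days),
    methods = methods, bases = bases, m = as.integer(m),
    k_donors = as.integer(k_donors), alpha = alpha,
    bootstrap_reps = as.integer(bootstrap_reps)
  ), class = "vrt_analysis_config")
}

#' Run the full VRT analysis
#'
#' Orchestrates the pipeline end to end: load or simulate the cohort, apply
#' eligibility screening, run the hypothesis-1 interaction regression with
#' SESOI equivalence verdicts over the full sensitivity grid (every
#' imputation method crossed with ipsatized and raw index bases; multiple
#' imputations pooled by Rubin's rules), the hypothesis-2 subgroup ROC
#' comparison, and the hypothesis-3/4 criterion-validity Spearman table.
#' The primary analysis cell is individual-mean imputation on the ipsatized
#' basis. Every stage seed derives deterministically from `config$seed`, so
#' the report is bit-identical across runs of the same configuration.
#'
#' @param config An `vrt_analysis_config`, see [analysis_config()].
#' @return A `vrt_report` list with elements `meta`, `eligibility`, `h1`
#'   (one entry per grid cell), `h2`, `h3h4`.
#' @export
run_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "vrt_analysis_config"))
  seed <- config$seed

  if (!is.null(config$trials_path)) {
    trials <- read_trials(config$trials_path)
    participants <- read_participants(config$participants_path)
  } else {
    sim <- simulate_cohort(config$cohort_config, seed = seed)
    trials <- sim$trials
    participants <- simulate_criteria(
      sim$participants, rho_target = config$cohort_config$criterion_rho,
      seed = seed + 1L)
  }

  elig <- apply_eligibility(trials, participants,
                            threshold = config$threshold,
                            max_interval_days = config$max_interval_days)
  keep <- elig$participant_id[elig$eligible]
  if (length(keep) < 10L) {
    stop("analysis aborted: only ", length(keep),
         " eligible participant(s) after screening", call. = FALSE)
  }
  trials <- trials[trials$participant_id %in% keep, , drop = FALSE]
  participants <- participants[participants$participant_id %in% keep, ,
                               drop = FALSE]

  reason_tab <- table(unlist(lapply(elig$reasons, unique)))
  eligibility_summary <- list(
    n_input = nrow(elig), n_eligible = length(keep),
    exclusion_reasons = as.list(reason_tab)
  )

  # hypothesis 1 sensitivity grid
  h1 <- list()
  for (method in config$methods) {
    for (basis in config$bases) {
      idx <- compute_vrt_index(trials, basis = basis, impute_method = method,
                               m = config$m, k_donors = config$k_donors,
                               seed = seed + 2L)
      fit <- if (is.data.frame(idx)) {
        d <- merge(idx[, c("participant_id", "value")], participants,
                   by = "participant_id")
        fit_interaction_model(d)
      } else {
        fit_interaction_pooled(idx, participants)
      }
      rep1 <- h1_report(fit, alpha = config$alpha)
      cell <- paste(method, basis, sep = ".")
      h1[[cell]] <- list(
        method = method, basis = basis,
        coefficients = rep1$verdicts,
        bounds = rep1$bounds[c("lower", "upper", "degenerate")],
        diagnosis_effect = rep1$diagnosis_effect,
        interaction_negligible = as.list(rep1$interaction_negligible)
      )
    }
  }

  # primary index: individual-mean imputation, ipsatized basis
  idx_primary <- compute_vrt_index(trials, basis = "ipsatized",
                                   impute_method = "individual_mean")

  h2 <- roc_comparison(idx_primary, participants,
                       reps = config$bootstrap_reps, seed = seed + 3L)

  crit_cols <- intersect(names(.criterion_ranges()), names(participants))
  h3h4 <- NULL
  if (length(crit_cols)) {
    d <- merge(idx_primary[, c("participant_id", "value")],
               participants[, c("participant_id", crit_cols)],
               by = "participant_id")
    cols <- d[, c("value", crit_cols)]
    names(cols)[1] <- "vrt_index"
    have <- vapply(cols, function(v) sum(!is.na(v)) >= 3L, logical(1))
    if (sum(have) >= 2L) {
      ct <- suppressWarnings(spearman_matrix(cols[, have, drop = FALSE]))
      h3h4 <- list(rho = ct$rho, n = ct$n, p = ct$p)
    }
  }

  structure(list(
    meta = list(schema = "vrt-report/1", seed = seed,
                n_participants = length(keep),
                methods = config$methods, bases = config$bases,
                alpha = config$alpha, bootstrap_reps = config$bootstrap_reps),
    eligibility = eligibility_summary,
    h1 = h1,
    h2 = h2,
    h3h4 = h3h4
  ), class = "vrt_report")
}

#' Serialize an analysis report to JSON
#'
#' Writes the report deterministically (full double precision, stable key
#' order) so identical configurations yield byte-identical files.
#'
#' @param report A `vrt_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  json <- report_json(report)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @return `report_json()` returns the JSON as a single string.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = NA, na = "null", pretty = TRUE))
}
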