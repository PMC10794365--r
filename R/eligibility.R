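#' Eligibility screening of a VRT cohort
#'
#' Applies the data-quality inclusion criteria for the VRT analysis.
#' A participant is excluded when any of the following holds (reasons are not
#' mutually exclusive and all that apply are recorded):
#'
#' * `NO_VRT_DATA` — no trial rows at all;
#' * `MISSING_GT_THRESHOLD` — the fraction of missing (non-response) trials
#'   is *strictly greater* than `threshold` (default 10%; a participant at
#'   exactly 10% is retained);
#' * `EMPTY_CATEGORY` — at least one of the 10 age-by-sex stimulus categories
#'   has zero non-missing trials, leaving its category mean undefined;
#' * `INTERVAL_GT_4W` — VRT testing took place more than `max_interval_days`
#'   (default 28) days apart from the clinical interview; an unknown interval
#'   is treated as eligible by default (`exclude_unknown_interval = TRUE`
#'   reverses this);
#' * `UNKNOWN_DIAGNOSIS` — the clinical diagnosis flag is unknown, which
#'   bars the participant from any inference on diagnosis.
#'
#' An optional anticipatory-response floor can be imposed through
#' `min_latency_ms`: latencies at or below the floor are counted as missing
#' for screening purposes. It is off (`NULL`) by default, as the paradigm
#' itself imposes no lower cutoff.
#'
#' @param trials Validated trial table ([validate_trials()]).
#' @param participants Validated participant table.
#' @param threshold Maximum tolerated missing-trial fraction (exclusive).
#' @param max_interval_days Maximum tolerated interview-to-VRT interval.
#' @param exclude_unknown_interval Exclude participants whose interval is
#'   unknown? Default `FALSE`.
#' @param min_latency_ms Optional lower latency floor; `NULL` disables it.
#' @return A data frame (one row per participant) with columns `n_trials`,
#'   `n_missing`, `missing_fraction`, `empty_categories` (comma-separated
#'   labels, `""` if none), `interval_violation`, `eligible`, and `reasons`
#'   (list column of reason codes, empty iff eligible).
#' @export
apply_eligibility <- function(trials, participants,
                              threshold = 0.10,
                              max_interval_days = 28L,
                              exclude_unknown_interval = FALSE,
                              min_latency_ms = NULL) {
  stopifnot(threshold >= 0, threshold <= 1, max_interval_days >= 0)
  unknown_pid <- setdiff(unique(trials$participant_id),
                         participants$participant_id)
  if (length(unknown_pid)) {
    stop("trial rows reference participant(s) absent from the participant ",
         "table: ", paste(utils::head(unknown_pid, 5L), collapse = ", "),
         call. = FALSE)
  }

  all_cats <- .vrt_all_categories()
  miss <- trials$missing
  if (!is.null(min_latency_ms)) {
    miss <- miss | (!is.na(trials$latency_ms) &
                      trials$latency_ms <= min_latency_ms)
  }

  pid <- participants$participant_id
  n_trials <- n_missing <- integer(length(pid))
  empty_cats <- character(length(pid))
  tr_split <- split(seq_len(nrow(trials)), trials$participant_id)

  for (i in seq_along(pid)) {
    idx <- tr_split[[pid[i]]]
    n_trials[i] <- length(idx)
    if (!length(idx)) next
    n_missing[i] <- sum(miss[idx])
    valid_cats <- unique(trials$category[idx][!miss[idx]])
    empties <- setdiff(all_cats, valid_cats)
    empty_cats[i] <- paste(empties, collapse = ",")
  }

  missing_fraction <- ifelse(n_trials > 0, n_missing / n_trials, NA_real_)
  interval <- participants$days_interview_to_vrt
  interval_violation <- !is.na(interval) & interval > max_interval_days
  if (exclude_unknown_interval) {
    interval_violation <- interval_violation | is.na(interval)
  }

  reasons <- vector("list", length(pid))
  for (i in seq_along(pid)) {
    r <- character(0)
    if (n_trials[i] == 0L) r <- c(r, "NO_VRT_DATA")
    if (n_trials[i] > 0L && missing_fraction[i] > threshold) {
      r <- c(r, "MISSING_GT_THRESHOLD")
    }
    if (n_trials[i] > 0L && nzchar(empty_cats[i])) r <- c(r, "EMPTY_CATEGORY")
    if (interval_violation[i]) r <- c(r, "INTERVAL_GT_4W")
    if (is.na(participants$pedohebephilia[i])) r <- c(r, "UNKNOWN_DIAGNOSIS")
    reasons[[i]] <- r
  }

  out <- data.frame(
    participant_id = pid,
    n_trials = n_trials,
    n_missing = n_missing,
    missing_fraction = missing_fraction,
    empty_categories = empty_cats,
    interval_violation = interval_violation,
    eligible = lengths(reasons) == 0L,
    stringsAsFactors = FALSE
  )
  out$reasons <- reasons
  out
}

#' Restrict a cohort to eligible participants
#'
#' Convenience wrapper: runs [apply_eligibility()] and returns the trial and
#' participant tables restricted to eligible participants, together with the
#' report.
#'
#' @inheritParams apply_eligibility
#' @param ... Passed on to [apply_eligibility()].
#' @return List with elements `trials`, `participants`, `report`.
#' @export
filter_eligible <- function(trials, participants, ...) {
  report <- apply_eligibility(trials, participants, ...)
  keep <- report$participant_id[report$eligible]
  list(
    trials = trials[trials$participant_id %in% keep, , drop = FALSE],
    participants = participants[participants$participant_id %in% keep, ,
                                drop = FALSE],
    report = report
  )
}
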