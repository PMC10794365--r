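#' Read trial-level viewing reaction time records
#'
#' Reads a comma-separated file with one row per stimulus presentation.
#' Required columns: `participant_id`, `sex` (`M`/`F`), `tanner` (1-5),
#' `trial_index` (integer >= 0), `latency_ms`, `rating`. A non-response
#' trial (stimulus timed out after 5000 ms) records neither a latency nor a
#' rating; both cells are empty (or equal to `na`). The paradigm removes the
#' stimulus at 5000 ms, so an observed latency above `max_latency_ms` is a
#' hard error rather than a value to be cleaned.
#'
#' @param path Path to the CSV file.
#' @param na Strings to treat as missing (default empty cell and `"NA"`).
#' @param max_latency_ms Response deadline of the paradigm in milliseconds.
#' @return A validated data frame of trial records with an added `category`
#'   label column and logical `missing` column.
#' @seealso [write_trials()], [read_participants()]
#' @export
read_trials <- function(path, na = c("", "NA"), max_latency_ms = 5000) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, na.strings = na, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character"))
  validate_trials(raw, max_latency_ms = max_latency_ms)
}

#' Validate a trial table
#'
#' Enforces the invariants of the paradigm: Tanner stages in 1-5, sex codes
#' `M`/`F`, latencies in (0, `max_latency_ms`], ratings in 1-4, and the
#' coupling that a trial is missing its latency if and only if it is missing
#' its rating. Violations raise errors naming the offending row.
#'
#' @param trials Data frame with the columns documented in [read_trials()].
#' @param max_latency_ms Response deadline in milliseconds.
#' @return The trial table with `category` and `missing` columns added.
#' @export
validate_trials <- function(trials, max_latency_ms = 5000) {
  required <- c("participant_id", "sex", "tanner", "trial_index",
                "latency_ms", "rating")
  miss <- setdiff(required, names(trials))
  if (length(miss)) {
    stop("trial table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  trials$participant_id <- as.character(trials$participant_id)
  trials$sex <- toupper(as.character(trials$sex))
  trials$tanner <- as.integer(trials$tanner)

  .fail_rows <- function(bad, what) {
    if (any(bad)) {
      stop(what, " in row(s): ",
           paste(utils::head(which(bad), 5L), collapse = ", "),
           if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L) else "",
           call. = FALSE)
    }
  }
  .fail_rows(is.na(trials$participant_id) | trials$participant_id == "",
             "empty participant_id")
  .fail_rows(is.na(trials$sex) | !trials$sex %in% c("M", "F"),
             "unknown stimulus sex code")
  .fail_rows(is.na(trials$tanner) | !trials$tanner %in% 1:5,
             "Tanner stage outside 1-5")
  .fail_rows(!is.na(trials$latency_ms) & trials$latency_ms <= 0,
             "non-positive latency")
  .fail_rows(!is.na(trials$latency_ms) & trials$latency_ms > max_latency_ms,
             sprintf("latency above the %d ms response deadline", max_latency_ms))
  .fail_rows(!is.na(trials$rating) & !trials$rating %in% 1:4,
             "attractiveness rating outside 1-4")
  # non-response trials record neither latency nor rating
  .fail_rows(xor(is.na(trials$latency_ms), is.na(trials$rating)),
             "latency/rating missingness mismatch")

  trials$category <- category_label(trials$sex, trials$tanner)
  trials$missing <- is.na(trials$latency_ms)
  trials
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trials()]: missing latencies/ratings are written as empty
#' cells. Derived columns (`category`, `missing`) are dropped on write and
#' recomputed on read, so write-then-read round-trips.
#'
#' @param trials Trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  keep <- c("participant_id", "sex", "tanner", "trial_index",
            "latency_ms", "rating")
  utils::write.csv(trials[keep], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read participant metadata
#'
#' One row per participant: `participant_id`, `pedohebephilia` (clinical
#' diagnosis of sexual interest in pre-/early-pubescent minors), `cso` (any
#' prior child sexual offense), `csam` (any prior use of child sexual abuse
#' material), `days_interview_to_vrt` (interval between clinical interview
#' and VRT testing). Flags are coded 0/1 with empty cells for unknown; an
#' unknown diagnosis later excludes the participant from inference. Optional
#' further columns (criterion scale scores) are carried through untouched.
#'
#' @inheritParams read_trials
#' @return Validated participant data frame with logical flag columns.
#' @export
read_participants <- function(path, na = c("", "NA")) {
  if (!file.exists(path)) stop("participant file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, na.strings = na, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character"))
  validate_participants(raw)
}

#' Validate a participant table
#'
#' @param participants Data frame with the columns documented in
#'   [read_participants()].
#' @return The validated table with flags as logical (`NA` = unknown).
#' @export
validate_participants <- function(participants) {
  required <- c("participant_id", "pedohebephilia", "cso", "csam",
                "days_interview_to_vrt")
  miss <- setdiff(required, names(participants))
  if (length(miss)) {
    stop("participant table lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  participants$participant_id <- as.character(participants$participant_id)
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicated participant_id in participant table", call. = FALSE)
  }
  for (fl in c("pedohebephilia", "cso", "csam")) {
    v <- participants[[fl]]
    if (!is.logical(v)) {
      if (!all(v %in% c(0, 1, NA))) {
        stop("flag column '", fl, "' must be coded 0/1 (empty = unknown)",
             call. = FALSE)
      }
      v <- as.logical(v)
    }
    participants[[fl]] <- v
  }
  d <- participants$days_interview_to_vrt
  if (any(!is.na(d) & d < 0)) {
    stop("negative interview-to-VRT interval", call. = FALSE)
  }
  participants
}

#' Write a participant table to CSV
#'
#' @param participants Participant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  out <- participants
  for (fl in c("pedohebephilia", "cso", "csam")) {
    out[[fl]] <- as.integer(out[[fl]])
  }
  # internal simulator columns are not part of the on-disk contract
  out$latent_deviance <- NULL
  out$speed_offset <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
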