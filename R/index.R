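#' Ipsatize latencies within participant
#'
#' Standardizes each participant's response latencies relative to their own
#' distribution, removing individual differences in general response speed:
#' `z = (latency - participant mean) / participant SD`, with mean and SD
#' (n-1 denominator) taken over *all* of the participant's non-missing
#' trials pooled across stimulus categories. Missing trials stay missing.
#' A centering-only variant (`center_only = TRUE`) subtracts the mean
#' without dividing by the SD.
#'
#' @param trials Validated trial table (typically after imputation, so that
#'   category means downstream are defined for all 10 categories).
#' @param center_only If `TRUE`, mean-center without scaling.
#' @return The trial table with a `latency_z` column added.
#' @export
ipsatize <- function(trials, center_only = FALSE) {
  lat <- trials$latency_ms
  pid <- factor(trials$participant_id, levels = unique(trials$participant_id))
  n_obs <- tapply(!is.na(lat), pid, sum)
  if (any(n_obs < 2L)) {
    stop("participant ", names(n_obs)[which(n_obs < 2L)[1]],
         ": fewer than 2 valid trials, cannot ipsatize", call. = FALSE)
  }
  mu <- tapply(lat, pid, mean, na.rm = TRUE)
  s <- tapply(lat, pid, stats::sd, na.rm = TRUE)
  if (!center_only && any(s == 0)) {
    stop("participant ", names(s)[which(s == 0)[1]],
         ": degenerate latencies (zero spread)", call. = FALSE)
  }
  i <- as.integer(pid)
  trials$latency_z <- as.numeric(
    if (center_only) lat - mu[i] else (lat - mu[i]) / s[i])
  trials
}

#' Per-participant per-category latency summaries
#'
#' Computes, for every participant and each of the 10 stimulus categories,
#' the arithmetic mean of non-missing latencies on the raw scale and (when
#' present) on the ipsatized scale, along with valid/missing trial counts.
#' An empty category yields an `NA` mean; eligibility screening flags such
#' participants upstream.
#'
#' @param trials Trial table; if it carries a `latency_z` column the
#'   ipsatized means are filled, otherwise they are `NA`.
#' @return Data frame with one row per participant x category:
#'   `participant_id`, `category`, `mean_raw`, `mean_ipsatized`, `n_valid`,
#'   `n_missing`.
#' @export
category_means <- function(trials) {
  cats <- .vrt_all_categories()
  pids <- unique(trials$participant_id)
  np <- length(pids); nc <- length(cats)
  pi <- match(trials$participant_id, pids)
  ci <- match(trials$category, cats)
  cell <- (pi - 1L) * nc + ci  # 1 .. np*nc
  obs <- !is.na(trials$latency_ms)

  acc <- function(x) {
    out <- numeric(np * nc)
    s <- rowsum(x, cell)
    out[as.integer(rownames(s))] <- s
    out
  }
  n_valid <- acc(as.numeric(obs))
  n_total <- acc(rep(1, nrow(trials)))
  sum_raw <- acc(ifelse(obs, trials$latency_ms, 0))
  has_z <- "latency_z" %in% names(trials)
  if (has_z) sum_z <- acc(ifelse(obs, trials$latency_z, 0))

  grid <- data.frame(
    participant_id = rep(pids, each = nc),
    category = rep(cats, times = np),
    mean_raw = ifelse(n_valid > 0, sum_raw / n_valid, NA_real_),
    mean_ipsatized = if (has_z) {
      ifelse(n_valid > 0, sum_z / n_valid, NA_real_)
    } else NA_real_,
    n_valid = as.integer(n_valid),
    n_missing = as.integer(n_total - n_valid),
    stringsAsFactors = FALSE
  )
  grid
}

#' The max-difference VRT index
#'
#' For each participant, the index is the maximum mean latency toward any
#' pre-/peripubertal category (Tanner stages 1-3, either sex) minus the
#' maximum mean latency toward any postpubertal category (Tanner 4-5). Taking
#' per-sex maxima rather than pooling avoids attenuation from the target-sex
#' orientation of the participant: longer viewing of sexually salient stimuli
#' shows up in the preferred sex only. Positive values indicate relatively
#' longer viewing of child stimuli.
#'
#' Ties between category means are broken deterministically: males before
#' females, ascending Tanner stage within sex (the canonical order of
#' [vrt_categories()]); the winning categories are recorded.
#'
#' @param profile Output of [category_means()].
#' @param basis `"ipsatized"` (default) or `"raw"`.
#' @return Data frame with one row per participant: `participant_id`,
#'   `value`, `basis`, `argmax_child`, `argmax_adult`.
#' @export
vrt_index <- function(profile, basis = c("ipsatized", "raw")) {
  basis <- match.arg(basis)
  col <- if (basis == "ipsatized") "mean_ipsatized" else "mean_raw"
  child_cats <- .vrt_child_categories()
  adult_cats <- .vrt_adult_categories()

  pids <- unique(profile$participant_id)
  M <- matrix(NA_real_, nrow = length(pids), ncol = 10L,
              dimnames = list(pids, .vrt_all_categories()))
  M[cbind(match(profile$participant_id, pids),
          match(profile$category, colnames(M)))] <- profile[[col]]
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1L, ]
    stop("participant ", pids[bad[1]], ": undefined ", basis,
         " mean for category ", colnames(M)[bad[2]],
         " - run eligibility screening and/or imputation first",
         call. = FALSE)
  }
  # columns already in canonical order: first max wins ties
  Mc <- M[, child_cats, drop = FALSE]
  Ma <- M[, adult_cats, drop = FALSE]
  ic <- max.col(Mc, ties.method = "first")
  ia <- max.col(Ma, ties.method = "first")
  data.frame(
    participant_id = pids,
    value = Mc[cbind(seq_along(pids), ic)] - Ma[cbind(seq_along(pids), ia)],
    basis = basis,
    argmax_child = child_cats[ic],
    argmax_adult = adult_cats[ia],
    stringsAsFactors = FALSE
  )
}

#' Score a trial table into VRT indices
#'
#' Convenience pipeline for one completed (or complete-enough) trial table:
#' optional imputation of missing latencies, ipsatization, category means,
#' and the max-difference index. With a multiple-imputation method the index
#' is computed on each completed dataset and all are returned.
#'
#' @param trials Validated trial table.
#' @param basis `"ipsatized"` or `"raw"`.
#' @param impute_method `"none"`, `"individual_mean"`, `"regression"`,
#'   `"pmm"` or `"pmm_by_individual"`.
#' @param m,k_donors,seed Passed to [impute_pmm()] for the PMM methods.
#' @param center_only Passed to [ipsatize()].
#' @return For simple methods a single index data frame (with an
#'   `n_imputed` attribute); for PMM a list of `m` index data frames.
#' @export
compute_vrt_index <- function(trials, basis = c("ipsatized", "raw"),
                              impute_method = c("individual_mean", "none",
                                                "regression", "pmm",
                                                "pmm_by_individual"),
                              m = 5L, k_donors = 5L, seed = NULL,
                              center_only = FALSE) {
  basis <- match.arg(basis)
  impute_method <- match.arg(impute_method)
  imp <- switch(impute_method,
    none = list(method = "none", m = 1L, datasets = list(trials)),
    individual_mean = impute_individual_mean(trials),
    regression = impute_regression(trials),
    pmm = impute_pmm(trials, m = m, k_donors = k_donors, classes = "none",
                     seed = seed),
    pmm_by_individual = impute_pmm(trials, m = m, k_donors = k_donors,
                                   classes = "by_individual", seed = seed)
  )
  score_one <- function(tr) {
    if (basis == "ipsatized") tr <- ipsatize(tr, center_only = center_only)
    idx <- vrt_index(category_means(tr), basis = basis)
    idx$n_imputed <- as.integer(
      tapply(trials$missing, trials$participant_id, sum)[idx$participant_id])
    idx
  }
  res <- lapply(imp$datasets, score_one)
  if (length(res) == 1L) res[[1L]] else res
}
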