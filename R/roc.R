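#' Empirical ROC curve and AUC
#'
#' Builds the empirical ROC of a continuous score against a binary label
#' with the orientation "higher score predicts the positive class".
#' Thresholds are the midpoints between adjacent distinct observed scores,
#' flanked by -Inf/Inf; a case is called positive when its score exceeds the
#' threshold. The AUC equals the Mann-Whitney probability (ties counted
#' one-half), identical to the trapezoidal area.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels (logical or 0/1); `TRUE`/1 is the positive
#'   class.
#' @return A `vrt_roc` object: list with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `n_pos`, `n_neg`, and the data (`scores`,
#'   `labels`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  u <- sort(unique(scores))
  thresholds <- c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  sens <- vapply(thresholds, function(t) mean(scores[labels] > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(scores[!labels] <= t), numeric(1))
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc,
                 n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels),
            class = "vrt_roc")
}

#' @export
print.vrt_roc <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

# fast AUC on raw vectors (used inside the bootstrap)
.auc_fast <- function(scores, labels) {
  n_pos <- sum(labels)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * (length(labels) - n_pos))
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile bootstrap with resampling stratified within class (cases and
#' controls resampled separately), so every resample retains both classes by
#' construction.
#'
#' @param scores,labels As in [roc_auc()].
#' @param level Confidence level (default 0.95).
#' @param reps Number of bootstrap replicates (default 2000).
#' @param seed Optional integer seed.
#' @return Numeric `c(lower, upper)` with attribute `"reps"`.
#' @export
bootstrap_auc_ci <- function(scores, labels, level = 0.95, reps = 2000L,
                             seed = NULL) {
  stopifnot(reps >= 100L)
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pos <- scores[labels]; neg <- scores[!labels]
  np <- length(pos); nn <- length(neg)
  lab <- c(rep(TRUE, np), rep(FALSE, nn))
  stat <- vapply(seq_len(reps), function(i) {
    .auc_fast(c(pos[sample.int(np, np, replace = TRUE)],
                neg[sample.int(nn, nn, replace = TRUE)]), lab)
  }, numeric(1))
  ci <- unname(stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2)))
  attr(ci, "reps") <- reps
  ci
}

# DeLong placement values: X for cases, Y for controls, theta = AUC
.delong_placements <- function(roc) {
  s <- roc$scores; l <- roc$labels
  pos <- s[l]; neg <- s[!l]
  X <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), numeric(1))
  Y <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), numeric(1))
  list(X = X, Y = Y, theta = roc$auc)
}

#' Unpaired DeLong comparison of two AUCs
#'
#' Compares the AUCs of two ROC curves built on disjoint participant sets.
#' Each AUC's variance is estimated from DeLong placement values
#' (`var(X)/n_cases + var(Y)/n_controls`); the statistic is
#' `D = (AUC_a - AUC_b) / sqrt(var_a + var_b)`, referred to a t distribution
#' with Welch-Satterthwaite degrees of freedom computed from the two
#' variance components (total sample size minus one per curve), giving the
#' fractional df characteristic of this test.
#'
#' @param roc_a,roc_b `vrt_roc` objects from disjoint samples.
#' @return List with `D`, `df`, `p` (two-sided), `auc_a`, `auc_b`.
#' @export
delong_unpaired <- function(roc_a, roc_b) {
  for (r in list(roc_a, roc_b)) {
    if (r$n_pos < 2L || r$n_neg < 2L) {
      stop("each curve needs at least 2 cases and 2 controls", call. = FALSE)
    }
  }
  va <- .delong_placements(roc_a)
  vb <- .delong_placements(roc_b)
  Sa <- stats::var(va$X) / roc_a$n_pos + stats::var(va$Y) / roc_a$n_neg
  Sb <- stats::var(vb$X) / roc_b$n_pos + stats::var(vb$Y) / roc_b$n_neg
  D <- (va$theta - vb$theta) / sqrt(Sa + Sb)
  na <- roc_a$n_pos + roc_a$n_neg
  nb <- roc_b$n_pos + roc_b$n_neg
  df <- (Sa + Sb)^2 / (Sa^2 / (na - 1) + Sb^2 / (nb - 1))
  p <- 2 * stats::pt(abs(D), df, lower.tail = FALSE)
  list(D = D, df = df, p = p, auc_a = va$theta, auc_b = vb$theta)
}

#' Optimal cutoff by the Youden method
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the ROC curve's
#' thresholds (midpoints between adjacent observed scores). Ties in J are
#' resolved toward the threshold with higher specificity.
#'
#' @param roc A `vrt_roc` object.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1L) {
    best <- best[which.max(roc$specificity[best])]
  }
  list(cutoff = roc$thresholds[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       j = j[best])
}

#' Confidence-interval encompassment rule
#'
#' Equivalence rule for two AUCs: the (outer) 95% interval of one group must
#' fully contain the (inner) 90% interval of the other. Closed-interval
#' convention: equal endpoints count as contained.
#'
#' @param outer_95,inner_90 Numeric `c(lower, upper)` intervals.
#' @return `TRUE` iff `inner_90` lies within `outer_95`.
#' @export
ci_encompassment <- function(outer_95, inner_90) {
  stopifnot(length(outer_95) == 2L, length(inner_90) == 2L,
            outer_95[1] <= outer_95[2], inner_90[1] <= inner_90[2])
  outer_95[1] <= inner_90[1] && inner_90[2] <= outer_95[2]
}

#' Subgroup ROC equivalence analysis
#'
#' The full hypothesis-2 machinery: within each of two participant
#' subgroups (offense history vs none), a ROC of the VRT index against the
#' clinical diagnosis is built; AUCs receive stratified bootstrap CIs; the
#' AUCs are compared by the unpaired DeLong test; equivalence is assessed by
#' whether the 95% CI of the offense-history subgroup encompasses the 90% CI
#' of the no-history subgroup; and a Youden-optimal cutoff is determined on
#' the overall sample.
#'
#' @param index Index data frame (`participant_id`, `value`).
#' @param participants Participant table with `pedohebephilia`, `cso`,
#'   `csam` flags.
#' @param reps Bootstrap replicates per interval.
#' @param seed Integer seed for the bootstrap.
#' @return List with per-subgroup AUCs and CIs, `delong`, `encompassed`,
#'   and `youden` (overall-sample cutoff).
#' @export
roc_comparison <- function(index, participants, reps = 2000L, seed = NULL) {
  d <- merge(index[, c("participant_id", "value")], participants,
             by = "participant_id")
  history <- d$cso | d$csam
  sub_a <- d[history, ]   # any prior CSO/CSAM
  sub_b <- d[!history, ]  # neither
  roc_a <- roc_auc(sub_a$value, sub_a$pedohebephilia)
  roc_b <- roc_auc(sub_b$value, sub_b$pedohebephilia)
  if (!is.null(seed)) set.seed(seed)
  ci95_a <- bootstrap_auc_ci(sub_a$value, sub_a$pedohebephilia, 0.95, reps)
  ci95_b <- bootstrap_auc_ci(sub_b$value, sub_b$pedohebephilia, 0.95, reps)
  ci90_b <- bootstrap_auc_ci(sub_b$value, sub_b$pedohebephilia, 0.90, reps)
  dl <- delong_unpaired(roc_a, roc_b)
  roc_all <- roc_auc(d$value, d$pedohebephilia)
  list(
    auc_history = roc_a$auc, ci95_history = ci95_a,
    n_history = nrow(sub_a),
    auc_no_history = roc_b$auc, ci95_no_history = ci95_b,
    ci90_no_history = ci90_b, n_no_history = nrow(sub_b),
    delong = dl,
    encompassed = ci_encompassment(ci95_a, ci90_b),
    auc_overall = roc_all$auc,
    youden = youden_cutoff(roc_all)
  )
}
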