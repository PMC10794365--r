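#' Pairwise Spearman correlation table
#'
#' Spearman's rho for every pair of columns, using average ranks for ties
#' and pairwise-complete observations (sample sizes typically differ per
#' pair when the instruments were assessed in overlapping subsamples).
#' Two-sided p-values come from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' Pairs involving a constant column get `NA` with a warning.
#'
#' @param data Data frame or matrix of numeric (ordinal) columns.
#' @param pairwise Use pairwise-complete observations (default `TRUE`);
#'   otherwise listwise deletion.
#' @return A `vrt_cortable` object: list of matrices `rho`, `n`, `p`.
#' @export
spearman_matrix <- function(data, pairwise = TRUE) {
  data <- as.data.frame(data)
  stopifnot(ncol(data) >= 2L)
  if (!pairwise) data <- data[stats::complete.cases(data), , drop = FALSE]
  k <- ncol(data)
  nm <- colnames(data)
  rho <- n <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  constant_seen <- FALSE
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    n[i, i] <- sum(!is.na(data[[i]]))
    for (j in seq_len(i - 1L)) {
      ok <- !is.na(data[[i]]) & !is.na(data[[j]])
      nn <- sum(ok)
      n[i, j] <- n[j, i] <- nn
      if (nn < 3L) next
      x <- data[[i]][ok]; y <- data[[j]][ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        constant_seen <- TRUE
        next
      }
      r <- stats::cor(x, y, method = "spearman")
      rho[i, j] <- rho[j, i] <- r
      if (abs(r) < 1) {
        tt <- r * sqrt((nn - 2) / (1 - r^2))
        p[i, j] <- p[j, i] <- 2 * stats::pt(abs(tt), nn - 2, lower.tail = FALSE)
      } else {
        p[i, j] <- p[j, i] <- 0
      }
    }
  }
  if (constant_seen) {
    warning("constant column(s): rho undefined for the affected pairs",
            call. = FALSE)
  }
  structure(list(rho = rho, n = n, p = p), class = "vrt_cortable")
}

#' @export
print.vrt_cortable <- function(x, digits = 3, ...) {
  cat("Spearman correlation table (pairwise-complete n in parentheses)\n")
  print(round(x$rho, digits))
  invisible(x)
}

#' Yates-corrected 2x2 chi-square test
#'
#' Continuity-corrected chi-square for a 2x2 contingency table given as four
#' cell counts `a, b, c, d` (rows = groups, columns = outcome):
#' `chi2 = N * (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`, with the
#' correction floored so the statistic is never negative. Delegates to
#' [stats::chisq.test()]; set `correct = FALSE` for the uncorrected
#' statistic.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param correct Apply the Yates continuity correction (default `TRUE`).
#' @return List with `chi2`, `df` (= 1), `p`.
#' @export
chisq_yates <- function(a, b, c, d, correct = TRUE) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  m <- matrix(counts, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal total: chi-square undefined", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Welch's two-sample t test from summaries or raw vectors
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#' Accepts either group summaries (`mean_a`, `sd_a`, `n_a`, ...) or two raw
#' vectors via `x` and `y`.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summary statistics.
#' @param x,y Optional raw data vectors (override the summaries).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b, x = NULL, y = NULL) {
  if (!is.null(x) || !is.null(y)) {
    stopifnot(!is.null(x), !is.null(y))
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mean_a <- mean(x); sd_a <- stats::sd(x); n_a <- length(x)
    mean_b <- mean(y); sd_b <- stats::sd(y); n_b <- length(y)
  }
  stopifnot(sd_a > 0 || sd_b > 0, n_a >= 2, n_b >= 2)
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' The "classical" single-rater ICC from a one-way ANOVA of items (targets)
#' rated by `k` raters: `ICC(1) = (MSB - MSW) / (MSB + (k - 1) * MSW)`, with
#' an F-based 95% confidence interval. Items with any missing rating are
#' dropped (with a message) so the ANOVA is balanced. When ratings show no
#' between-item variance the ICC is not calculable and `NA` is returned.
#'
#' @param ratings Numeric matrix or data frame, items in rows, raters in
#'   columns.
#' @param level Confidence level for the interval (default 0.95).
#' @return List with `icc`, `ci` (`c(lower, upper)`), `n_items`,
#'   `n_raters`, `msb`, `msw`; `icc` is `NA` when not calculable.
#' @export
icc_oneway <- function(ratings, level = 0.95) {
  m <- as.matrix(ratings)
  keep <- stats::complete.cases(m)
  if (!all(keep)) {
    message(sum(!keep), " item(s) dropped for missing ratings")
    m <- m[keep, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("need at least 2 items and 2 raters with complete ratings",
         call. = FALSE)
  }
  row_means <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((m - row_means)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0) {
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                n_items = n, n_raters = k, msb = msb, msw = msw,
                note = "not calculable due to zero variance"))
  }
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - level
  if (msw == 0) {
    ci <- c(icc, icc)
  } else {
    Fobs <- msb / msw
    FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    FU <- Fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  }
  list(icc = icc, ci = ci, n_items = n, n_raters = k, msb = msb, msw = msw)
}
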