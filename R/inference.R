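#' t-distribution confidence interval from summary statistics
#'
#' @param estimate Point estimate.
#' @param se Standard error.
#' @param df Degrees of freedom.
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
t_ci <- function(estimate, se, df, level = 0.95) {
  halfw <- stats::qt(1 - (1 - level) / 2, df) * se
  c(estimate - halfw, estimate + halfw)
}

#' Fit the dummy-coded interaction regression of the VRT index
#'
#' Ordinary least squares of the VRT index on 0/1 dummies for the clinical
#' diagnosis (`pedohebephilia`), prior child sexual offenses (`cso`), prior
#' CSAM use (`csam`), and all their two- and three-way interactions (8 terms
#' including the intercept). Confidence intervals use the t distribution on
#' the residual degrees of freedom; externally studentized residuals are
#' returned for outlier inspection. The intercept estimates the mean index of
#' undiagnosed participants with neither offense history; the
#' `pedohebephilia` term is the simple effect of the diagnosis in that
#' offense-free stratum.
#'
#' @param data Data frame with columns `value` (VRT index),
#'   `pedohebephilia`, `cso`, `csam` (logical or 0/1; must be non-missing).
#' @return A `vrt_h1_fit` object: list with `coefficients` (term, beta, se,
#'   t, p, ll90/ul90, ll95/ul95, identifiable), `residual_df`, `sigma`,
#'   `r2`, `r2_adj`, `F`, `p_F`, `n`, `studentized`, and the underlying
#'   `lm` object.
#' @export
fit_interaction_model <- function(data) {
  stopifnot(all(c("value", "pedohebephilia", "cso", "csam") %in% names(data)))
  if (anyNA(data$pedohebephilia) || anyNA(data$cso) || anyNA(data$csam)) {
    stop("predictor flags must be complete; exclude unknown-diagnosis ",
         "participants upstream", call. = FALSE)
  }
  if (anyNA(data$value) || any(!is.finite(data$value))) {
    stop("VRT index contains non-finite values", call. = FALSE)
  }
  d <- data.frame(value = as.numeric(data$value),
                  pedohebephilia = as.integer(data$pedohebephilia),
                  cso = as.integer(data$cso),
                  csam = as.integer(data$csam))
  fit <- stats::lm(value ~ pedohebephilia * cso * csam, data = d,
                   singular.ok = TRUE)
  sm <- summary(fit)
  all_terms <- c("(Intercept)", "pedohebephilia", "cso", "csam",
                 "pedohebephilia:cso", "pedohebephilia:csam", "cso:csam",
                 "pedohebephilia:cso:csam")
  cf <- stats::coef(fit)[all_terms]
  est <- sm$coefficients
  tab <- data.frame(term = all_terms,
                    beta = as.numeric(cf),
                    se = NA_real_, t = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  hit <- match(all_terms, rownames(est))
  tab$se <- est[hit, "Std. Error"]
  tab$t <- est[hit, "t value"]
  tab$p <- est[hit, "Pr(>|t|)"]
  rdf <- fit$df.residual
  ci90 <- t(mapply(t_ci, tab$beta, tab$se, MoreArgs = list(df = rdf, level = 0.90)))
  ci95 <- t(mapply(t_ci, tab$beta, tab$se, MoreArgs = list(df = rdf, level = 0.95)))
  tab$ll90 <- ci90[, 1]; tab$ul90 <- ci90[, 2]
  tab$ll95 <- ci95[, 1]; tab$ul95 <- ci95[, 2]
  tab$identifiable <- !is.na(tab$beta)
  if (any(!tab$identifiable)) {
    warning("empty design cell(s): term(s) not identifiable: ",
            paste(tab$term[!tab$identifiable], collapse = ", "),
            call. = FALSE)
  }
  fstat <- sm$fstatistic
  structure(list(
    coefficients = tab,
    residual_df = rdf,
    sigma = sm$sigma,
    r2 = sm$r.squared,
    r2_adj = sm$adj.r.squared,
    F = if (!is.null(fstat)) unname(fstat[1]) else NA_real_,
    p_F = if (!is.null(fstat)) {
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    } else NA_real_,
    n = nrow(d),
    studentized = stats::rstudent(fit),
    model = fit
  ), class = "vrt_h1_fit")
}

#' @export
print.vrt_h1_fit <- function(x, ...) {
  cat(sprintf("VRT index interaction regression (n = %d, residual df = %d)\n",
              x$n, x$residual_df))
  print(x$coefficients[, c("term", "beta", "se", "ll90", "ul90", "p")],
        row.names = FALSE, digits = 4)
  cat(sprintf("R2 = %.4f (adj. %.4f), F = %.2f, p = %.3g\n",
              x$r2, x$r2_adj, x$F, x$p_F))
  invisible(x)
}

#' Pool interaction-regression fits across imputed datasets
#'
#' Fits [fit_interaction_model()] on each completed dataset's index values
#' and pools per-term estimates by [pool_rubin()]. Confidence intervals use
#' the Barnard-Rubin degrees of freedom per term.
#'
#' @param index_list List of per-dataset index data frames (as returned by
#'   [compute_vrt_index()] with a PMM method).
#' @param participants Participant table with complete diagnosis/offense
#'   flags.
#' @return A `vrt_h1_fit`-like object with pooled `coefficients` (plus `W`,
#'   `B`, `df` columns) and `m`.
#' @export
fit_interaction_pooled <- function(index_list, participants) {
  stopifnot(is.list(index_list), length(index_list) >= 2L)
  fits <- lapply(index_list, function(idx) {
    d <- merge(idx[, c("participant_id", "value")], participants,
               by = "participant_id")
    fit_interaction_model(d)
  })
  terms <- fits[[1]]$coefficients$term
  dfcom <- fits[[1]]$residual_df
  tab <- data.frame(term = terms, beta = NA_real_, se = NA_real_,
                    W = NA_real_, B = NA_real_, df = NA_real_,
                    t = NA_real_, p = NA_real_,
                    ll90 = NA_real_, ul90 = NA_real_,
                    ll95 = NA_real_, ul95 = NA_real_,
                    identifiable = TRUE, stringsAsFactors = FALSE)
  for (i in seq_along(terms)) {
    est <- vapply(fits, function(f) f$coefficients$beta[i], numeric(1))
    v <- vapply(fits, function(f) f$coefficients$se[i]^2, numeric(1))
    if (anyNA(est)) { tab$identifiable[i] <- FALSE; next }
    p90 <- pool_rubin(est, v, dfcom, level = 0.90)
    p95 <- pool_rubin(est, v, dfcom, level = 0.95)
    tab$beta[i] <- p95$estimate
    tab$se[i] <- p95$se
    tab$W[i] <- p95$W; tab$B[i] <- p95$B; tab$df[i] <- p95$df
    tab$t[i] <- p95$estimate / p95$se
    tab$p[i] <- 2 * stats::pt(abs(tab$t[i]), p95$df, lower.tail = FALSE)
    tab$ll90[i] <- p90$ci[1]; tab$ul90[i] <- p90$ci[2]
    tab$ll95[i] <- p95$ci[1]; tab$ul95[i] <- p95$ci[2]
  }
  structure(list(coefficients = tab, residual_df = dfcom,
                 m = length(fits), n = fits[[1]]$n, fits = fits),
            class = c("vrt_h1_pooled", "vrt_h1_fit"))
}

#' SESOI equivalence bounds from the diagnosis simple effect
#'
#' The smallest-effect-size-of-interest region for the offense-history
#' interaction terms is anchored on the diagnosis effect itself: an
#' interaction is non-negligible if it could cancel the diagnosis effect
#' (lower scenario) or increase it (upper scenario). The lower bound is the
#' negative of the lower limit of the 95% CI of the diagnosis coefficient;
#' the upper bound is the conservative value zero. If that 95% CI does not
#' exclude zero the region is empty (degenerate) and a warning is issued.
#'
#' @param fit A `vrt_h1_fit`, or alternatively pass `beta`, `se`, `df`
#'   directly.
#' @param beta,se,df Summary statistics of the diagnosis coefficient
#'   (ignored when `fit` is supplied).
#' @return List with `lower`, `upper` (= 0), `ll95_diagnosis`,
#'   `degenerate`.
#' @export
sesoi_bounds <- function(fit = NULL, beta = NULL, se = NULL, df = NULL) {
  if (!is.null(fit)) {
    cf <- fit$coefficients
    i <- match("pedohebephilia", cf$term)
    if (is.na(i) || !cf$identifiable[i]) {
      stop("diagnosis coefficient not estimated", call. = FALSE)
    }
    ll95 <- cf$ll95[i]
  } else {
    stopifnot(!is.null(beta), !is.null(se), !is.null(df))
    ll95 <- t_ci(beta, se, df, 0.95)[1]
  }
  lower <- -ll95
  degenerate <- lower >= 0
  if (degenerate) {
    warning("equivalence region empty: the 95% CI of the diagnosis effect ",
            "does not exclude zero", call. = FALSE)
  }
  list(lower = lower, upper = 0, ll95_diagnosis = ll95,
       degenerate = degenerate)
}

#' Equivalence verdicts for regression terms
#'
#' Applies the composite-null equivalence rule to each supplied term, using
#' the term's 90% confidence interval at alpha = 0.05: the upper scenario is
#' violated when the CI's upper limit exceeds zero (strict), the lower
#' scenario when the CI's lower limit is less than or equal to the SESOI
#' lower bound (equivalently, `ll90 + ll95_diagnosis <= 0`). A term is
#' negligible iff neither scenario is violated.
#'
#' @param coefs Data frame with columns `term`, `ll90`, `ul90` (e.g. the
#'   `coefficients` table of a `vrt_h1_fit`, or published values).
#' @param bounds Output of [sesoi_bounds()].
#' @return `coefs` with logical columns `violates_upper`, `violates_lower`,
#'   `negligible` and a display `marks` column (`"+"` for a lower violation,
#'   `"#"` for an upper violation) appended.
#' @export
equivalence_verdicts <- function(coefs, bounds) {
  stopifnot(all(c("term", "ll90", "ul90") %in% names(coefs)))
  out <- coefs
  out$violates_upper <- out$ul90 > bounds$upper
  out$violates_lower <- out$ll90 <= bounds$lower
  out$negligible <- !out$violates_upper & !out$violates_lower
  out$marks <- paste0(ifelse(out$violates_lower, "+", ""),
                      ifelse(out$violates_upper, "#", ""))
  out
}

#' Structured hypothesis-1 report
#'
#' Emits the conjoint-hypothesis decision structure: the two-sided test of a
#' null diagnosis effect, and the three equivalence verdicts for the
#' interactions of the diagnosis with prior CSO, prior CSAM, and both.
#'
#' @param fit A `vrt_h1_fit` (single or pooled).
#' @param alpha Significance level for the diagnosis effect test.
#' @return List with `fit` (coefficient table), `bounds`, `verdicts` (all 8
#'   terms), `diagnosis_effect` (beta, p, significant), and
#'   `interaction_negligible` (named logical for the three diagnosis
#'   interactions).
#' @export
h1_report <- function(fit, alpha = 0.05) {
  bounds <- sesoi_bounds(fit)
  verdicts <- equivalence_verdicts(fit$coefficients, bounds)
  cf <- fit$coefficients
  i <- match("pedohebephilia", cf$term)
  inter <- c("pedohebephilia:cso", "pedohebephilia:csam",
             "pedohebephilia:cso:csam")
  neg <- verdicts$negligible[match(inter, verdicts$term)]
  names(neg) <- inter
  list(fit = cf, bounds = bounds, verdicts = verdicts,
       diagnosis_effect = list(beta = cf$beta[i], p = cf$p[i],
                               significant = !is.na(cf$p[i]) && cf$p[i] < alpha),
       interaction_negligible = neg)
}
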