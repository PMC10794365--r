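#' @name imputation
#' @title Missing-latency imputation schemes
#' @description
#' Non-response trials leave missing latencies that must be filled before
#' the VRT index can be computed. Three schemes are provided, all operating
#' on raw (pre-ipsatization) latencies within age-by-sex stimulus category:
#'
#' * **individual category mean** ([impute_individual_mean()]) — the
#'   reference method: each missing latency is replaced by the participant's
#'   own mean of observed latencies in the same category (simple, single
#'   imputation, deterministic);
#' * **whole-sample regression** ([impute_regression()]) — per category, a
#'   least-squares model over the whole sample predicts a participant's
#'   category mean from their other observed category means; missing trials
#'   take the model prediction (single imputation, deterministic);
#' * **predictive mean matching** ([impute_pmm()]) — per category, the same
#'   predictive model ranks observed values by closeness of their prediction
#'   to the recipient's prediction (type-1 matching); one of the `k_donors`
#'   nearest observed values is drawn per missing trial. With
#'   `classes = "by_individual"` the donor pool is restricted to the
#'   recipient's own observed trials in that category. PMM is a multiple
#'   imputation, yielding `m` completed datasets whose analyses are pooled
#'   with [pool_rubin()].
#'
#' Each function returns a `vrt_imputation` object: a list with `method`,
#' `m`, `datasets` (completed trial tables with an `imputed` flag column;
#' no missing latencies remain) and `seed`.
NULL

.as_imputation <- function(method, datasets, seed = NA_integer_) {
  structure(list(method = method, m = length(datasets), datasets = datasets,
                 seed = seed),
            class = "vrt_imputation")
}

#' @export
print.vrt_imputation <- function(x, ...) {
  cat("VRT imputation: method =", x$method, ", m =", x$m, "completed dataset(s)\n")
  invisible(x)
}

.complete_one <- function(trials, fill) {
  # fill: numeric vector aligned with rows of `trials`, NA where untouched
  out <- trials
  out$imputed <- !is.na(fill)
  out$latency_ms[out$imputed] <- fill[out$imputed]
  out$missing <- is.na(out$latency_ms)
  if (any(out$missing)) {
    stop("internal error: completed dataset still contains missing latencies",
         call. = FALSE)
  }
  out
}

#' Impute missing latencies by the individual category mean
#'
#' @param trials Validated trial table.
#' @return A `vrt_imputation` with `m = 1`.
#' @rdname imputation
#' @export
impute_individual_mean <- function(trials) {
  fill <- rep(NA_real_, nrow(trials))
  mi <- which(is.na(trials$latency_ms))
  if (length(mi)) {
    key <- paste(trials$participant_id, trials$category, sep = "\r")
    means <- tapply(trials$latency_ms, key, mean, na.rm = TRUE)
    fill[mi] <- as.numeric(means[key[mi]])
    if (anyNA(fill[mi])) {
      bad <- unique(key[mi][is.na(fill[mi])])
      stop("no observed latency to average for participant/category: ",
           paste(gsub("\r", "/", utils::head(bad, 5L)), collapse = ", "),
           " - eligibility screening (EMPTY_CATEGORY) was bypassed",
           call. = FALSE)
    }
  }
  .as_imputation("individual_mean", list(.complete_one(trials, fill)))
}

# participant-by-category matrix of observed raw category means
.mean_matrix <- function(trials) {
  cm <- category_means(trials)
  cats <- .vrt_all_categories()
  pids <- unique(trials$participant_id)
  M <- matrix(NA_real_, nrow = length(pids), ncol = length(cats),
              dimnames = list(pids, cats))
  M[cbind(match(cm$participant_id, pids), match(cm$category, cats))] <- cm$mean_raw
  M
}

# fit the per-category predictive model and return predictions;
# shared by regression imputation and PMM
.predict_category <- function(M, k, rows_predict) {
  resp <- M[, k]
  pred_cols <- setdiff(colnames(M), k)
  train <- which(!is.na(resp) & rowSums(is.na(M[, pred_cols, drop = FALSE])) == 0L)
  if (length(train) < 2L) {
    stop("fewer than 2 complete rows to fit the predictive model for ",
         "category ", k, call. = FALSE)
  }
  df_train <- as.data.frame(M[train, pred_cols, drop = FALSE])
  df_train$.y <- resp[train]
  fit <- stats::lm(.y ~ ., data = df_train, singular.ok = TRUE)
  if (anyNA(stats::coef(fit))) {
    message("predictive model for category ", k,
            " is rank-deficient; aliased predictors dropped")
  }
  pr <- function(rows) {
    newd <- as.data.frame(M[rows, pred_cols, drop = FALSE])
    out <- numeric(length(rows))
    complete <- rowSums(is.na(newd)) == 0L
    if (any(complete)) {
      out[complete] <- suppressWarnings(
        as.numeric(stats::predict(fit, newdata = newd[complete, , drop = FALSE])))
    }
    for (j in which(!complete)) {
      # available-predictor submodel for rows missing some predictors
      avail <- pred_cols[!is.na(newd[j, ])]
      if (!length(avail)) {
        out[j] <- mean(resp[train])
        next
      }
      df_sub <- df_train[, c(avail, ".y"), drop = FALSE]
      sub <- stats::lm(.y ~ ., data = df_sub, singular.ok = TRUE)
      out[j] <- suppressWarnings(
        as.numeric(stats::predict(sub, newdata = newd[j, avail, drop = FALSE])))
    }
    out
  }
  list(train = train, y_train = resp[train],
       yhat_train = pr(train),
       yhat_predict = if (length(rows_predict)) pr(rows_predict) else numeric(0))
}

#' Impute missing latencies by whole-sample per-category regression
#'
#' @rdname imputation
#' @export
impute_regression <- function(trials) {
  fill <- rep(NA_real_, nrow(trials))
  mi_all <- which(is.na(trials$latency_ms))
  if (length(mi_all)) {
    M <- .mean_matrix(trials)
    pids <- rownames(M)
    for (k in unique(trials$category[mi_all])) {
      mi <- mi_all[trials$category[mi_all] == k]
      rec <- match(unique(trials$participant_id[mi]), pids)
      pm <- .predict_category(M, k, rec)
      fill[mi] <- pm$yhat_predict[match(match(trials$participant_id[mi], pids), rec)]
    }
  }
  .as_imputation("regression", list(.complete_one(trials, fill)))
}

#' Impute missing latencies by predictive mean matching
#'
#' @param m Number of imputed datasets (default 5).
#' @param k_donors Size of the donor pool (default 5).
#' @param classes `"none"` (whole-sample donors) or `"by_individual"`
#'   (donor pool restricted to the recipient's own observed trials in the
#'   category).
#' @param seed Integer seed for reproducible donor draws.
#' @rdname imputation
#' @export
impute_pmm <- function(trials, m = 5L, k_donors = 5L,
                       classes = c("none", "by_individual"), seed = NULL) {
  classes <- match.arg(classes)
  stopifnot(m >= 1L, k_donors >= 1L)
  if (!is.null(seed)) set.seed(seed)

  mi_all <- which(is.na(trials$latency_ms))
  if (!length(mi_all)) {
    return(.as_imputation(paste0("pmm_", classes),
                          rep(list(.complete_one(trials, rep(NA_real_, nrow(trials)))), m),
                          seed %||% NA_integer_))
  }

  M <- .mean_matrix(trials)
  pids <- rownames(M)
  # per missing trial: donor candidate values and matching distances
  donor_values <- vector("list", length(mi_all))
  small_pool <- FALSE
  for (k in unique(trials$category[mi_all])) {
    sel <- which(trials$category[mi_all] == k)
    mi <- mi_all[sel]
    rec_pid <- trials$participant_id[mi]
    rec_rows <- match(unique(rec_pid), pids)
    pm <- tryCatch(.predict_category(M, k, rec_rows), error = function(e) {
      if (classes == "by_individual") NULL else stop(e)
    })
    yhat_rec <- if (is.null(pm)) {
      # too few complete rows to fit the cross-participant model; within
      # individual classes the participant's own category mean is the
      # natural prediction target for matching
      M[match(rec_pid, pids), k]
    } else {
      pm$yhat_predict[match(match(rec_pid, pids), rec_rows)]
    }
    for (j in seq_along(mi)) {
      if (classes == "none") {
        pool_vals <- pm$y_train
        dist <- abs(pm$yhat_train - yhat_rec[j])
      } else {
        own <- trials$latency_ms[trials$participant_id == rec_pid[j] &
                                   trials$category == k]
        pool_vals <- own[!is.na(own)]
        if (!length(pool_vals)) {
          stop("participant ", rec_pid[j], " has no observed trials in ",
               "category ", k, " to serve as within-individual donors",
               call. = FALSE)
        }
        dist <- abs(pool_vals - yhat_rec[j])
      }
      kk <- min(k_donors, length(pool_vals))
      if (kk < k_donors) small_pool <- TRUE
      donor_values[[sel[j]]] <- pool_vals[order(dist)[seq_len(kk)]]
    }
  }
  if (small_pool) {
    warning("donor pool smaller than k_donors for some missing trials; ",
            "full available pool used", call. = FALSE)
  }

  datasets <- vector("list", m)
  for (d in seq_len(m)) {
    fill <- rep(NA_real_, nrow(trials))
    fill[mi_all] <- vapply(donor_values, function(v) {
      v[sample.int(length(v), 1L)]
    }, numeric(1))
    datasets[[d]] <- .complete_one(trials, fill)
  }
  .as_imputation(paste0("pmm_", classes), datasets, seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pool multiply-imputed estimates by Rubin's rules
#'
#' Combines `m` complete-data estimates and their squared standard errors:
#' the pooled estimate is the mean of the estimates, the total variance is
#' `T = W + (1 + 1/m) B` with `W` the mean within-imputation variance and
#' `B` the between-imputation sample variance, and degrees of freedom follow
#' the Barnard-Rubin small-sample formula with complete-data df
#' `df_complete`. The confidence interval uses the t distribution on the
#' pooled df.
#'
#' @param estimates Numeric vector of length `m >= 2`.
#' @param variances Squared standard errors, same length.
#' @param df_complete Complete-data residual degrees of freedom.
#' @param level Confidence level (default 0.95).
#' @return List with `estimate`, `W`, `B`, `T`, `df`, `se`, `ci`, `m`.
#' @export
pool_rubin <- function(estimates, variances, df_complete, level = 0.95) {
  m <- length(estimates)
  if (m < 2L) stop("pooling requires multiple imputations (m >= 2)", call. = FALSE)
  stopifnot(length(variances) == m, all(variances >= 0), df_complete > 0)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  Tv <- W + (1 + 1 / m) * B
  if (Tv == 0) {
    df <- df_complete
  } else {
    lambda <- (1 + 1 / m) * B / Tv
    df_obs <- (df_complete + 1) / (df_complete + 3) * df_complete * (1 - lambda)
    if (lambda == 0) {
      df <- df_obs
    } else {
      df_old <- (m - 1) / lambda^2
      df <- df_old * df_obs / (df_old + df_obs)
    }
  }
  se <- sqrt(Tv)
  halfw <- stats::qt(1 - (1 - level) / 2, df) * se
  list(estimate = qbar, W = W, B = B, T = Tv, df = df, se = se,
       ci = c(qbar - halfw, qbar + halfw), m = m, level = level)
}
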