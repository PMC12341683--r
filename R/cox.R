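#' Survival dataset container
#'
#' Bundles a covariate matrix with observed durations and event indicators.
#' Categorical covariates are expected to be label-encoded (integer codes on
#' one column); the code-to-label maps travel with the dataset so encoded
#' columns can be symbolized as discrete maps later.
#'
#' @param X numeric matrix (or data frame) of covariates, one row per subject.
#' @param time non-negative durations (event or censoring times).
#' @param event event indicators: 1 = event observed, 0 = right-censored.
#' @param feature_names optional column names (default from `X`).
#' @param categorical_levels optional named list mapping a feature name to its
#'   character vector of level labels (position `i` is code `i - 1`).
#' @return an object of class `survival_dataset`.
#' @export
survival_dataset <- function(X, time, event, feature_names = NULL,
                             categorical_levels = list()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  time <- as.numeric(time); event <- as.numeric(event)
  if (nrow(X) != length(time) || length(time) != length(event))
    stop("X, time and event must have matching lengths")
  if (anyNA(X)) stop("covariates contain missing values; impute first")
  if (any(!is.finite(time)) || any(time < 0))
    stop("durations must be finite and non-negative")
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 (censored) or 1 (event)")
  if (is.null(feature_names))
    feature_names <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  colnames(X) <- feature_names
  structure(list(X = X, time = time, event = event,
                 feature_names = feature_names,
                 categorical_levels = categorical_levels),
            class = "survival_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("survival_dataset: %d subjects, %d features, %.1f%% events\n",
              nrow(x$X), ncol(x$X), 100 * mean(x$event)))
  invisible(x)
}

#' Subset a survival dataset by row index
#' @param data a `survival_dataset`.
#' @param idx integer row indices.
#' @return the subsetted `survival_dataset`.
#' @export
sd_subset <- function(data, idx) {
  survival_dataset(data$X[idx, , drop = FALSE], data$time[idx],
                   data$event[idx], data$feature_names,
                   data$categorical_levels)
}

check_loss_inputs <- function(theta, time, event) {
  if (length(theta) != length(time) || length(time) != length(event))
    stop("theta, time, event must have equal length")
  if (sum(event) == 0)
    stop("Cox loss undefined: no events in the batch")
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Exact negative Cox partial log-likelihood
#'
#' Computes `-sum_{i: event_i = 1} [theta_i - log sum_{j in R(t_i)}
#' exp(theta_j)]`, where the risk set `R(t_i) = {j : t_j >= t_i}` contains all
#' subjects still under observation just before `t_i`. Tied event times follow
#' the Breslow convention: every tied event uses the full shared risk set.
#' Evaluated with a numerically stable log-sum-exp.
#'
#' @param theta numeric vector of log-partial hazards.
#' @param time durations.
#' @param event event indicators in {0, 1}; at least one event required.
#' @return the scalar loss (not averaged).
#' @export
cox_loss_exact <- function(theta, time, event) {
  check_loss_inputs(theta, time, event)
  ord <- order(time, decreasing = TRUE)          # largest duration first
  th <- theta[ord]; tt <- time[ord]; ev <- event[ord]
  m <- max(th)
  cs <- cumsum(exp(th - m))                       # prefix over {t_j >= ...}
  # Breslow: subjects tied with t_i all belong to R(t_i); take, per row, the
  # prefix sum at the LAST position sharing its duration.
  r <- rle(tt)
  last_tie <- rep.int(cumsum(r$lengths), r$lengths)
  denom <- m + log(cs[last_tie])
  -sum((th - denom)[ev == 1])
}

#' Fast (sorted-prefix) approximation of the Cox loss
#'
#' Sorts subjects once by duration (descending, stable, events before
#' censored at equal times) and forms each event's risk-set denominator from
#' the running log-cumulative-sum-exp of `exp(theta)` under that order, in
#' O(n log n). When all durations are distinct this equals
#' [cox_loss_exact()]; with tied durations the denominator uses the running
#' prefix under the sorted order, a deliberate, documented approximation that
#' slightly mis-states risk sets at heavy ties.
#'
#' @inheritParams cox_loss_exact
#' @return the scalar loss.
#' @export
cox_loss_fast <- function(theta, time, event) {
  check_loss_inputs(theta, time, event)
  ord <- fast_loss_order(time, event)
  th <- theta[ord]; ev <- event[ord]
  m <- max(th)
  denom <- m + log(cumsum(exp(th - m)))
  -sum((th - denom)[ev == 1])
}

# stable descending-duration order with events before censored at equal times
fast_loss_order <- function(time, event) {
  order(-time, -event)
}

# gradient of cox_loss_fast w.r.t. theta (same prefix convention)
cox_loss_fast_grad <- function(theta, time, event) {
  ord <- fast_loss_order(time, event)
  th <- theta[ord]; ev <- event[ord]
  m <- max(th)
  e <- exp(th - m)
  S <- cumsum(e)
  r <- rev(cumsum(rev(ev / S)))   # sum over events at or after each position
  g <- e * r - ev
  g[order(ord)]
}

#' Harrell's concordance index
#'
#' Fraction of admissible subject pairs whose predicted risk ordering agrees
#' with their observed event-time ordering: pair (i, j) is admissible when
#' `t_i < t_j` and subject i had the event; it is concordant when
#' `theta_i > theta_j`, and ties in `theta` count one half. 0.5 is chance
#' level, 1 a perfect ranking. Computed via the O(n log n) routine in the
#' survival package.
#'
#' @param theta risk scores (higher = earlier expected event).
#' @param time durations.
#' @param event event indicators in {0, 1}.
#' @return the concordance estimate in [0, 1].
#' @export
concordance_index <- function(theta, time, event) {
  if (length(theta) < 2L) stop("concordance needs at least two subjects")
  cf <- survival::concordance(survival::Surv(time, event) ~ theta,
                              reverse = TRUE)
  counts <- cf$count
  adm <- counts["concordant"] + counts["discordant"] + counts["tied.x"]
  if (adm == 0) stop("concordance undefined: no admissible pairs")
  unname(cf$concordance)
}

# concordance estimate with its asymptotic standard error
concordance_with_se <- function(theta, time, event) {
  cf <- survival::concordance(survival::Surv(time, event) ~ theta,
                              reverse = TRUE)
  list(c = unname(cf$concordance), se = sqrt(cf$var))
}

#' Bootstrap confidence interval for the concordance index
#'
#' Nonparametric percentile bootstrap: subjects are resampled with
#' replacement `n_bootstrap` times and the 2.5/97.5 percentiles of the
#' resampled C-indices form the 95% interval. Resamples with no admissible
#' pairs are skipped (and counted). Deterministic under `seed`.
#'
#' @inheritParams concordance_index
#' @param n_bootstrap number of resamples (default 1000).
#' @param seed RNG seed (default 0).
#' @param conf confidence level (default 0.95).
#' @return a list of class `cindex_result` with `estimate`, `ci_low`,
#'   `ci_high`, `n_bootstrap`, `seed`, `n_skipped`.
#' @export
bootstrap_cindex <- function(theta, time, event, n_bootstrap = 1000L,
                             seed = 0L, conf = 0.95) {
  est <- concordance_index(theta, time, event)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  n <- length(theta)
  cs <- rep(NA_real_, n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(n, n, replace = TRUE)
    cs[b] <- tryCatch(concordance_index(theta[idx], time[idx], event[idx]),
                      error = function(e) NA_real_)
  }
  skipped <- sum(is.na(cs))
  if (skipped == n_bootstrap) stop("all bootstrap resamples were degenerate")
  a <- (1 - conf) / 2
  q <- stats::quantile(cs, c(a, 1 - a), na.rm = TRUE, names = FALSE,
                       type = 7)
  structure(list(estimate = est, ci_low = q[1L], ci_high = q[2L],
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed), n_skipped = skipped),
            class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("C-index %.3f (%.3f, %.3f)  [%d bootstrap resamples]\n",
              x$estimate, x$ci_low, x$ci_high, x$n_bootstrap))
  invisible(x)
}

#' Linear Cox proportional hazards baseline
#'
#' Fits `theta(x) = beta' x` by maximizing the Breslow partial likelihood
#' (via [survival::coxph()]); with `l1_penalty > 0` the Lasso-penalized
#' partial likelihood is maximized instead (via [glmnet::glmnet()] with the
#' Cox family, `lambda = l1_penalty`), which drives irrelevant coefficients
#' exactly to zero.
#'
#' @param data a `survival_dataset`.
#' @param l1_penalty non-negative Lasso penalty (glmnet `lambda` scale).
#' @param standardize passed to glmnet when penalized (default `FALSE` so
#'   coefficients stay on the covariate scale).
#' @return a list of class `linear_cox_model` with `beta` and `l1_penalty`.
#' @export
fit_coxph <- function(data, l1_penalty = 0, standardize = FALSE) {
  stopifnot(inherits(data, "survival_dataset"))
  if (sum(data$event) == 0) stop("cannot fit Cox model: no events")
  if (l1_penalty < 0) stop("l1_penalty must be non-negative")
  p <- ncol(data$X)
  if (l1_penalty == 0) {
    df <- as.data.frame(data$X)
    names(df) <- make.names(paste0("V", seq_len(p)))
    df$.time <- data$time; df$.event <- data$event
    fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                   paste(names(df)[seq_len(p)],
                                         collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = "breslow")
    beta <- unname(stats::coef(fit))
    beta[is.na(beta)] <- 0
    se <- sqrt(diag(fit$var))
  } else {
    fit <- glmnet::glmnet(data$X, survival::Surv(data$time, data$event),
                          family = "cox", lambda = l1_penalty,
                          standardize = standardize)
    beta <- as.numeric(fit$beta[, 1L])
    se <- rep(NA_real_, p)
  }
  structure(list(beta = stats::setNames(beta, data$feature_names),
                 se = se, l1_penalty = l1_penalty),
            class = "linear_cox_model")
}

#' Predict log-partial hazards from a linear Cox model
#' @param object a `linear_cox_model`.
#' @param newdata covariate matrix or `survival_dataset`.
#' @param ... unused.
#' @return numeric vector `beta' x`.
#' @export
predict.linear_cox_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "survival_dataset")) newdata$X
       else as.matrix(newdata)
  drop(X %*% object$beta)
}

#' @export
print.linear_cox_model <- function(x, ...) {
  cat("Linear Cox model (l1 =", x$l1_penalty, ")\n")
  print(round(x$beta, 4))
  invisible(x)
}
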