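#' Training configuration
#'
#' Collects every knob of the optimizer and model constructor. All stochastic
#' choices (train/validation split, parameter initialization) derive from
#' `seed`, so identical config + seed reproduces identical models.
#'
#' @param shape network layer widths, e.g. `c(p, 1)` or `c(p, 2, 1)`; if
#'   `NULL` it defaults to `c(p, 1)` at fit time.
#' @param G grid intervals per spline (3-5 typical).
#' @param k spline degree.
#' @param basis_kind residual basis: `"silu"` (default) or `"identity"`.
#' @param learning_rate Adam step size.
#' @param steps maximum number of full-batch epochs.
#' @param lambda overall regularization weight in `loss = cox + lambda * R`.
#' @param lambda_ent entropy weight inside the regularizer.
#' @param lambda_coef spline-coefficient weight inside the regularizer.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping.
#' @param val_fraction fraction of subjects held out for validation,
#'   in (0, 0.5].
#' @param cv_folds folds used by [hyperparameter_search()].
#' @param seed integer seed fixing all stochastic choices.
#' @param init_scale s.d. of initial spline coefficients.
#' @param hidden_range half-width of hidden-layer spline domains.
#' @return a `train_config` list.
#' @export
train_config <- function(shape = NULL, G = 5L, k = 3L, basis_kind = "silu",
                         learning_rate = 0.05, steps = 300L,
                         lambda = 0.01, lambda_ent = 2, lambda_coef = 0.5,
                         early_stop_patience = 40L, val_fraction = 0.2,
                         cv_folds = 5L, seed = 0L, init_scale = 0.1,
                         hidden_range = 4) {
  stopifnot(learning_rate > 0, steps >= 1, lambda >= 0, lambda_ent >= 0,
            lambda_coef >= 0, val_fraction > 0, val_fraction <= 0.5)
  structure(list(shape = shape, G = as.integer(G), k = as.integer(k),
                 basis_kind = basis_kind, learning_rate = learning_rate,
                 steps = as.integer(steps), lambda = lambda,
                 lambda_ent = lambda_ent, lambda_coef = lambda_coef,
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), init_scale = init_scale,
                 hidden_range = hidden_range),
            class = "train_config")
}

# event-stratified split: returns validation indices
stratified_val_idx <- function(event, val_fraction) {
  idx1 <- which(event == 1); idx0 <- which(event == 0)
  n1 <- max(1L, round(length(idx1) * val_fraction))
  n0 <- round(length(idx0) * val_fraction)
  c(if (length(idx1)) sample(idx1, min(n1, length(idx1) - 1L)),
    if (length(idx0) && n0 > 0) sample(idx0, min(n0, length(idx0))))
}

#' Train a KAN survival model
#'
#' Full-batch Adam on the total objective (fast Cox loss + weighted sparsity
#' regularizer). The data are split into training and validation parts
#' (stratified on the event indicator, under the config seed); after every
#' epoch the validation C-index is recorded and the parameters achieving the
#' best validation C-index are the ones returned. Training stops early after
#' `early_stop_patience` epochs without improvement, and errors out if the
#' loss becomes non-finite.
#'
#' @param data a `survival_dataset`.
#' @param config a [train_config()].
#' @return a list of class `kan_fit`: `model` (best-validation checkpoint),
#'   `trace` (data frame of epoch, train loss, validation C-index),
#'   `best_epoch`, `val_idx`, `config`.
#' @export
train <- function(data, config = train_config()) {
  stopifnot(inherits(data, "survival_dataset"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  p <- ncol(data$X)
  shape <- config$shape %||% c(p, 1L)
  if (shape[1L] != p) stop("config shape does not match feature count")
  val_idx <- stratified_val_idx(data$event, config$val_fraction)
  tr <- sd_subset(data, setdiff(seq_len(nrow(data$X)), val_idx))
  va <- sd_subset(data, val_idx)
  if (sum(tr$event) == 0 || sum(va$event) == 0)
    stop("train/validation split left a part with no events")
  model <- kan_model(shape, data$feature_names, G = config$G, k = config$k,
                     basis_kind = config$basis_kind, seed = config$seed,
                     init_scale = config$init_scale,
                     hidden_range = config$hidden_range)
  model <- kan_set_normalization(model, tr$X)
  # config$lambda weights the regularizer against the PER-EVENT mean Cox
  # loss; the objective below is the equivalent n_events * (mean + lambda R),
  # to which Adam's per-coordinate scaling is invariant.
  lambda_eff <- config$lambda * sum(tr$event)
  par <- kan_get_params(model)
  m <- numeric(length(par)); v <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(c = -Inf, par = par, epoch = 0L)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_c = numeric(0))
  stall <- 0L
  for (epoch in seq_len(config$steps)) {
    model <- kan_set_params(model, par)
    lg <- total_loss_grad(model, tr, lambda_eff, config$lambda_ent,
                          config$lambda_coef)
    if (!is.finite(lg$loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    g <- lg$grad
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^epoch); vh <- v / (1 - b2^epoch)
    par <- par - config$learning_rate * mh / (sqrt(vh) + eps)
    model_eval <- kan_set_params(model, par)
    vc <- tryCatch(concordance_index(kan_forward(model_eval, va$X),
                                     va$time, va$event),
                   error = function(e) NA_real_)
    trace <- rbind(trace, data.frame(epoch = epoch, train_loss = lg$loss,
                                     val_c = vc))
    if (!is.na(vc) && vc > best$c) {
      best <- list(c = vc, par = par, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stop_patience) break
    }
  }
  model <- kan_set_params(model, best$par)
  structure(list(model = model, trace = trace, best_epoch = best$epoch,
                 best_val_c = best$c, val_idx = sort(val_idx),
                 config = config),
            class = "kan_fit")
}

#' @export
print.kan_fit <- function(x, ...) {
  cat(sprintf("kan_fit: best validation C-index %.4f at epoch %d/%d\n",
              x$best_val_c, x$best_epoch, nrow(x$trace)))
  print(x$model)
  invisible(x)
}

sample_space_point <- function(space) {
  pt <- list()
  for (nm in names(space)) {
    sp <- space[[nm]]
    pt[[nm]] <- if (is.list(sp)) sp[[sample.int(length(sp), 1L)]]
    else if (!is.null(attr(sp, "log")) && isTRUE(attr(sp, "log")))
      exp(stats::runif(1, log(sp[1L]), log(sp[2L])))
    else if (length(sp) == 2L && is.numeric(sp) && sp[1L] < sp[2L] &&
             !is.null(attr(sp, "range")))
      stats::runif(1, sp[1L], sp[2L])
    else sp[[sample.int(length(sp), 1L)]]
  }
  pt
}

#' Default hyperparameter search space
#'
#' Shapes with zero or one small hidden layer, grid sizes 3-5, and
#' log-uniform regularization weight and learning rate.
#'
#' @param p number of input features.
#' @return a named list understood by [hyperparameter_search()]; numeric
#'   ranges carry a `log` attribute for log-uniform sampling, list entries
#'   are sampled uniformly.
#' @export
default_search_space <- function(p) {
  lam <- c(1e-5, 1e-1); attr(lam, "log") <- TRUE
  lr <- c(1e-3, 1e-1); attr(lr, "log") <- TRUE
  list(shape = list(c(p, 1L), c(p, 1L, 1L), c(p, 2L, 1L)),
       G = list(3L, 4L, 5L),
       lambda = lam,
       learning_rate = lr)
}

#' Random hyperparameter search with cross-validated concordance
#'
#' Samples `budget` candidate configurations from the space and scores each
#' by the mean held-out-fold C-index over `cv_folds` event-stratified folds
#' (within each fold, training uses its own inner validation split for early
#' stopping). The best-scoring configuration is returned. Randomized but
#' fully deterministic under `seed`. This is a random-search reference; a
#' model-based sampler can be plugged in through the same interface.
#'
#' @param data a `survival_dataset`.
#' @param space search space as from [default_search_space()].
#' @param budget number of candidates (>= 1).
#' @param seed RNG seed.
#' @param base_config `train_config` supplying the non-searched fields.
#' @return list with `config` (best `train_config`), `results` (per-candidate
#'   mean CV C-index), `scores`.
#' @export
hyperparameter_search <- function(data, space = NULL, budget = 10L,
                                  seed = 0L, base_config = train_config()) {
  stopifnot(budget >= 1)
  if (is.null(space)) space <- default_search_space(ncol(data$X))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  candidates <- lapply(seq_len(budget), function(i) sample_space_point(space))
  folds <- make_cv_folds(data$event, base_config$cv_folds)
  scores <- rep(NA_real_, budget)
  errors <- character(0)
  for (ci in seq_len(budget)) {
    cfg <- base_config
    for (nm in names(candidates[[ci]])) cfg[[nm]] <- candidates[[ci]][[nm]]
    fold_c <- rep(NA_real_, length(folds))
    for (f in seq_along(folds)) {
      te <- folds[[f]]
      res <- tryCatch({
        fit <- train(sd_subset(data, setdiff(seq_len(nrow(data$X)), te)), cfg)
        ds <- sd_subset(data, te)
        concordance_index(kan_forward(fit$model, ds$X), ds$time, ds$event)
      }, error = function(e) { errors <<- c(errors, conditionMessage(e)); NA })
      fold_c[f] <- res
    }
    scores[ci] <- mean(fold_c, na.rm = TRUE)
  }
  if (all(is.na(scores) | is.nan(scores)))
    stop("all hyperparameter candidates failed: ",
         paste(unique(errors), collapse = "; "))
  best <- which.max(scores)
  cfg <- base_config
  for (nm in names(candidates[[best]])) cfg[[nm]] <- candidates[[best]][[nm]]
  list(config = cfg, candidates = candidates, scores = scores)
}

make_cv_folds <- function(event, k) {
  n <- length(event)
  fold <- integer(n)
  for (cls in unique(event)) {
    idx <- sample(which(event == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) which(fold == f))
}
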