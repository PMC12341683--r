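#' Activation L1 norm over a batch
#'
#' The L1 "norm" of an activation is its average magnitude over the batch:
#' `|phi|_1 = mean(|phi(x^(s))|)`. This is the quantity both the sparsity
#' regularizer and the pruning rule act on.
#'
#' @param edge a `kan_edge`.
#' @param x numeric vector of pre-activations (non-empty).
#' @return non-negative scalar.
#' @export
activation_l1 <- function(edge, x) {
  if (length(x) == 0) stop("activation_l1 needs a non-empty batch")
  mean(abs(edge_eval(edge, x)))
}

# per-edge L1s for one layer given the cached edge outputs (n x n_edges)
layer_edge_l1 <- function(edge_out) colMeans(abs(edge_out))

# mean absolute spline coefficient of one edge (0 for non-spline states)
edge_coef_l1 <- function(edge) {
  if (edge$state != "spline") return(0)
  mean(abs(edge$spline$coef))
}

#' Entropy of a layer's activation-magnitude distribution
#'
#' Shannon entropy of the normalized per-edge L1 norms
#' `S(Phi) = -sum p_e log p_e` with `p_e = |phi_e|_1 / |Phi|_1`, using the
#' convention `0 log 0 = 0`. If the layer's total L1 is zero the entropy is
#' defined as 0. Bounded by `log(n_in * n_out)`.
#'
#' @param layer a `kan_layer`.
#' @param X batch of layer inputs (n x n_in matrix).
#' @return entropy in `[0, log(n_in * n_out)]`.
#' @export
layer_entropy <- function(layer, X) {
  fw <- layer_forward(layer, as.matrix(X), keep_edges = TRUE)
  entropy_from_l1(layer_edge_l1(fw$edge_out))
}

entropy_from_l1 <- function(l1) {
  A <- sum(l1)
  if (A <= 0) return(0)
  p <- l1 / A
  p <- p[p > 0]
  -sum(p * log(p))
}

# full regularization bookkeeping in one pass over a cached forward
reg_report_from_cache <- function(model, cache) {
  L <- length(model$layers)
  per_layer <- vector("list", L)
  for (l in seq_len(L)) {
    ly <- model$layers[[l]]
    l1 <- layer_edge_l1(cache$edge_out[[l]])
    coef_l1 <- vapply(ly$edges, edge_coef_l1, 0)
    per_layer[[l]] <- list(edge_l1 = l1, layer_l1 = sum(l1),
                           entropy = entropy_from_l1(l1),
                           coef_l1 = sum(coef_l1))
  }
  per_layer
}

#' Total sparsity regularizer
#'
#' `R = sum_l |Phi_l|_1 + lambda_ent * sum_l S(Phi_l) +
#' lambda_coef * sum_l |C_l|_1`, where `|Phi_l|_1` sums the per-edge
#' batch-average activation magnitudes, `S` is the layer entropy and
#' `|C_l|_1` sums each edge's mean absolute spline coefficient. The L1 and
#' entropy terms push whole edges (and hence nodes and input features)
#' towards zero; the coefficient term favours smooth, simple splines.
#'
#' @param model a `kan_model`.
#' @param X batch of (raw) covariates.
#' @param lambda_ent,lambda_coef entropy / coefficient weights.
#' @return non-negative scalar; an attribute `"report"` carries the per-layer
#'   breakdown.
#' @export
regularization_total <- function(model, X, lambda_ent = 1, lambda_coef = 1) {
  cache <- kan_forward(model, X, cache = TRUE)
  rep_ <- reg_report_from_cache(model, cache)
  val <- sum(vapply(rep_, function(r)
    r$layer_l1 + lambda_ent * r$entropy + lambda_coef * r$coef_l1, 0))
  attr(val, "report") <- rep_
  val
}

#' Total training objective
#'
#' `loss = cox_loss_fast(theta, t, delta) + lambda * R`, the fast Cox loss on
#' the batch's predicted log-partial hazards plus the weighted sparsity
#' regularizer.
#'
#' @param model a `kan_model`.
#' @param data a `survival_dataset` (the batch; must contain an event).
#' @param lambda overall regularization weight.
#' @param lambda_ent,lambda_coef inner weights of the regularizer.
#' @return scalar objective value.
#' @export
total_loss <- function(model, data, lambda = 0, lambda_ent = 1,
                       lambda_coef = 1) {
  theta <- kan_forward(model, data$X)
  base <- cox_loss_fast(theta, data$time, data$event)
  if (lambda == 0) return(base)
  base + lambda * as.numeric(
    regularization_total(model, data$X, lambda_ent, lambda_coef))
}

# objective value and flat gradient in one pass (used by the trainer).
# Cox loss is normalized by n events? No: kept as the plain sum, matching
# total_loss(); gradients flow through both the Cox term and the regularizer
# (entropy gradient via the per-edge L1s; |.|_1 terms via sign subgradients).
total_loss_grad <- function(model, data, lambda = 0, lambda_ent = 1,
                            lambda_coef = 1) {
  cache <- kan_forward(model, data$X, cache = TRUE)
  g_theta <- cox_loss_fast_grad(cache$theta, data$time, data$event)
  loss <- cox_loss_fast(cache$theta, data$time, data$event)
  g_edge_extra <- NULL
  if (lambda > 0) {
    rep_ <- reg_report_from_cache(model, cache)
    loss <- loss + lambda * sum(vapply(rep_, function(r)
      r$layer_l1 + lambda_ent * r$entropy + lambda_coef * r$coef_l1, 0))
    g_edge_extra <- vector("list", length(model$layers))
    for (l in seq_along(model$layers)) {
      E <- cache$edge_out[[l]]
      n <- nrow(E)
      l1 <- rep_[[l]]$edge_l1
      A <- sum(l1)
      # d/d l1_e of (|Phi|_1 + lambda_ent * S)
      if (A > 0 && lambda_ent > 0) {
        p <- pmax(l1 / A, 1e-300)
        dS <- (-log(p) - rep_[[l]]$entropy) / A
      } else dS <- rep(0, length(l1))
      w <- lambda * (1 + lambda_ent * dS)      # per-edge weight on d l1/d y
      g_edge_extra[[l]] <- sweep(sign(E), 2, w / n, "*")
    }
  }
  grad <- kan_backward(model, cache, g_theta, g_edge_extra)
  if (lambda > 0 && lambda_coef > 0) {
    # coefficient-L1 subgradient, aligned with the flat parameter layout
    gc <- unlist(lapply(model$layers, function(ly)
      lapply(ly$edges, function(e) {
        if (e$state != "spline") return(numeric(0))
        c(0, 0, lambda * lambda_coef * sign(e$spline$coef) /
            length(e$spline$coef))
      })))
    grad <- grad + gc
  }
  list(loss = loss, grad = grad)
}

# ---- pruning ----------------------------------------------------------------

# per-layer matrix (n_out x n_in) of edge L1 norms over a reference dataset
model_edge_l1 <- function(model, X) {
  cache <- kan_forward(model, X, cache = TRUE)
  lapply(seq_along(model$layers), function(l) {
    ly <- model$layers[[l]]
    matrix(layer_edge_l1(cache$edge_out[[l]]), nrow = ly$n_out,
           ncol = ly$n_in, byrow = TRUE)
  })
}

#' Prune low-magnitude activations (automatic feature selection)
#'
#' Sets every edge whose L1 norm (average activation magnitude over the full
#' training set, for deterministic decisions) falls below `l1_threshold` to
#' the `pruned` state. A hidden node whose incoming edges are all pruned, or
#' whose outgoing edges are all pruned, is removed (all its edges pruned),
#' and removals cascade. Input features left with no surviving outgoing edge
#' are reported as deselected in the `"deselected"` attribute. The pruned
#' model's forward pass equals the original minus the removed edges'
#' contributions.
#'
#' @param model a trained `kan_model`.
#' @param data a `survival_dataset` (training set) supplying activations.
#' @param l1_threshold non-negative threshold; 0 leaves the model unchanged.
#' @return the pruned `kan_model`, with attributes `"deselected"` (character
#'   vector of dropped input features) and `"n_pruned"` (edges pruned).
#' @export
prune <- function(model, data, l1_threshold) {
  stopifnot(inherits(model, "kan_model"))
  if (l1_threshold < 0) stop("l1_threshold must be non-negative")
  X <- if (inherits(data, "survival_dataset")) data$X else as.matrix(data)
  L <- length(model$layers)
  n_pruned_total <- 0L
  # iterate to a fixed point: removing edges changes downstream node inputs,
  # so magnitudes are re-evaluated on the pruned network until stable --
  # this makes the operation idempotent
  repeat {
    l1 <- model_edge_l1(model, X)
    keep_edge <- lapply(seq_len(L), function(l) {
      ly <- model$layers[[l]]
      m <- l1[[l]] >= l1_threshold
      st <- matrix(vapply(ly$edges, function(e) e$state == "pruned", TRUE),
                   nrow = ly$n_out, ncol = ly$n_in, byrow = TRUE)
      m & !st
    })
    repeat {
      changed <- FALSE
      for (l in seq_len(L - 1L)) {
        for (j in seq_len(model$layers[[l]]$n_out)) {
          incoming <- keep_edge[[l]][j, ]
          outgoing <- keep_edge[[l + 1L]][, j]
          if ((!any(incoming) || !any(outgoing)) &&
              (any(incoming) || any(outgoing))) {
            keep_edge[[l]][j, ] <- FALSE
            keep_edge[[l + 1L]][, j] <- FALSE
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    if (!any(keep_edge[[L]]))
      stop("pruning removed the entire output path (threshold too high)")
    n_new <- 0L
    for (l in seq_len(L)) {
      ly <- model$layers[[l]]
      for (j in seq_len(ly$n_out)) for (i in seq_len(ly$n_in)) {
        idx <- edge_index(ly, j, i)
        if (!keep_edge[[l]][j, i] &&
            model$layers[[l]]$edges[[idx]]$state != "pruned") {
          model$layers[[l]]$edges[[idx]]$state <- "pruned"
          n_new <- n_new + 1L
        }
      }
    }
    n_pruned_total <- n_pruned_total + n_new
    if (n_new == 0L) break
  }
  surviving <- vapply(seq_len(model$shape[1L]), function(i) {
    ly <- model$layers[[1L]]
    any(vapply(seq_len(ly$n_out), function(j)
      ly$edges[[edge_index(ly, j, i)]]$state != "pruned", TRUE))
  }, TRUE)
  attr(model, "deselected") <- model$feature_names[!surviving]
  attr(model, "n_pruned") <- n_pruned_total
  model
}

#' Select a pruning threshold by validation concordance
#'
#' Scans a log-spaced grid of candidate thresholds between the smallest and
#' largest observed edge L1 norm, prunes at each, and selects by validation
#' C-index. With `se_rule = TRUE` (default) the largest threshold whose
#' validation C lies within one standard error of the best one is chosen --
#' the same sparsity-favoring convention as the "1-SE" rule in
#' cross-validated Lasso -- since C-index differences well inside sampling
#' noise should not veto a simpler model. With `se_rule = FALSE` the
#' C-maximizing threshold is kept, ties broken toward the larger threshold.
#'
#' @param model a trained `kan_model`.
#' @param train_data `survival_dataset` supplying activation magnitudes.
#' @param val_data `survival_dataset` scored for threshold selection.
#' @param n_grid number of candidate thresholds (default 20).
#' @param se_rule apply the one-standard-error rule (default `TRUE`).
#' @return list with `threshold`, `model` (pruned at it), `val_c`, and the
#'   scan table.
#' @export
prune_auto <- function(model, train_data, val_data, n_grid = 20L,
                       se_rule = TRUE) {
  l1 <- unlist(model_edge_l1(model, train_data$X))
  l1 <- l1[l1 > 0]
  lo <- max(min(l1), 1e-12); hi <- max(l1)
  grid <- exp(seq(log(lo * 0.5), log(hi), length.out = n_grid))
  scan <- data.frame(threshold = grid, val_c = NA_real_, val_se = NA_real_,
                     n_pruned = NA_integer_)
  for (g in seq_along(grid)) {
    pm <- tryCatch(prune(model, train_data, grid[g]), error = function(e) NULL)
    if (is.null(pm)) next
    cc <- tryCatch(concordance_with_se(kan_forward(pm, val_data$X),
                                       val_data$time, val_data$event),
                   error = function(e) NULL)
    if (is.null(cc)) next
    scan$val_c[g] <- cc$c
    scan$val_se[g] <- cc$se
    scan$n_pruned[g] <- attr(pm, "n_pruned")
  }
  if (all(is.na(scan$val_c))) stop("no prunable threshold found")
  best_g <- max(which(scan$val_c == max(scan$val_c, na.rm = TRUE)))
  cutoff <- if (se_rule)
    scan$val_c[best_g] - scan$val_se[best_g] else scan$val_c[best_g]
  sel <- max(which(!is.na(scan$val_c) & scan$val_c >= cutoff))
  pm <- prune(model, train_data, grid[sel])
  list(threshold = grid[sel], model = pm, val_c = scan$val_c[sel],
       scan = scan)
}
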