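#' B-spline curve on a fixed uniform grid
#'
#' Constructs the learnable part of a KAN activation: a degree-`k` B-spline
#' with `G` grid intervals on `[lo, hi]`, extended by `k` knots on each side
#' so that the basis forms a partition of unity on the whole grid domain.
#' The curve is `spline(x) = sum_i c_i B_{i,k}(x)` with `G + k` coefficients.
#'
#' @param k spline degree (default 3, i.e. cubic).
#' @param G number of grid intervals (positive integer).
#' @param lo,hi grid domain endpoints.
#' @param coef optional numeric vector of `G + k` coefficients (default all 0).
#' @return an object of class `kan_spline`.
#' @export
kan_spline <- function(k = 3L, G = 5L, lo = -1, hi = 1, coef = NULL) {
  k <- as.integer(k); G <- as.integer(G)
  if (k < 1L || G < 1L) stop("spline degree and grid size must be positive")
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("malformed grid domain [lo, hi]")
  h <- (hi - lo) / G
  knots <- seq(lo - k * h, hi + k * h, by = h)
  # floating-point seq() can drift; force exact count
  knots <- lo + h * (seq_len(G + 1L + 2L * k) - 1L - k)
  if (is.null(coef)) coef <- numeric(G + k)
  if (length(coef) != G + k) stop("spline needs G + k coefficients")
  structure(list(k = k, G = G, lo = lo, hi = hi, knots = knots,
                 coef = as.numeric(coef)),
            class = "kan_spline")
}

#' B-spline basis matrix
#'
#' Evaluates the `G + k` B-spline basis functions (Cox-de Boor basis) of a
#' `kan_spline` at the given points. Inside the grid domain the basis sums to
#' one; outside the extended knot support all basis functions vanish.
#'
#' @param x numeric vector of evaluation points (not clamped).
#' @param spline a `kan_spline`.
#' @param deriv derivative order (0 = values).
#' @return a `length(x) x (G + k)` matrix of basis values, all `>= 0` for
#'   `deriv = 0`.
#' @export
bspline_basis <- function(x, spline, deriv = 0L) {
  if (!inherits(spline, "kan_spline")) stop("'spline' must be a kan_spline")
  kn <- spline$knots
  if (any(diff(kn) <= 0)) stop("malformed knot vector: not strictly increasing")
  x <- as.numeric(x)
  B <- matrix(0, length(x), spline$G + spline$k)
  # splineDesign only accepts x within the outer knots even with outer.ok;
  # points beyond the extended support have identically zero basis anyway.
  inside <- x >= kn[1L] & x <= kn[length(kn)]
  if (any(inside)) {
    B[inside, ] <- splines::splineDesign(
      kn, x[inside], ord = spline$k + 1L,
      derivs = rep(as.integer(deriv), sum(inside)), outer.ok = TRUE)
  }
  B
}

#' Evaluate a spline curve
#' @param spline a `kan_spline`.
#' @param x numeric vector (clamped to the grid domain by the caller if
#'   desired).
#' @param deriv derivative order.
#' @return numeric vector of curve values.
#' @export
spline_eval <- function(spline, x, deriv = 0L) {
  drop(bspline_basis(x, spline, deriv) %*% spline$coef)
}

silu  <- function(x) x * stats::plogis(x)
dsilu <- function(x) { s <- stats::plogis(x); s * (1 + x * (1 - s)) }

basis_fun <- function(kind) {
  switch(kind,
         identity = list(f = function(x) x, df = function(x) rep(1, length(x))),
         silu     = list(f = silu, df = dsilu),
         stop("unknown basis kind: ", kind))
}

#' KAN activation edge
#'
#' One learnable activation function `phi(x) = w_b * b(x) + w_s * spline(x)`
#' sitting on a network edge. The residual basis `b(x)` is `x` or
#' `silu(x) = x / (1 + exp(-x))` and is not trained. An edge is always in
#' exactly one of four states, which governs evaluation: `spline` (trainable),
#' `symbolic` (replaced by `c f(a x + b) + d` after distillation),
#' `categorical_map` (a finite code-to-value lookup), or `pruned`
#' (evaluates to 0).
#'
#' @param spline a `kan_spline` carrying the trainable part.
#' @param w_b,w_s basis and spline weights.
#' @param basis_kind `"silu"` (default) or `"identity"`.
#' @param state initial state, normally `"spline"`.
#' @return an object of class `kan_edge`.
#' @export
kan_edge <- function(spline, w_b = 1, w_s = 1, basis_kind = "silu",
                     state = "spline") {
  stopifnot(state %in% c("spline", "symbolic", "categorical_map", "pruned"))
  structure(list(w_b = w_b, w_s = w_s, basis_kind = basis_kind,
                 spline = spline, state = state,
                 symbolic_fit = NULL, category_map = NULL),
            class = "kan_edge")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an activation edge
#'
#' Dispatches on the edge state. In `spline` state the spline argument is
#' clamped to the grid domain (flat extrapolation) while the residual basis
#' acts on the raw input; in `symbolic` state the input is clamped to the
#' range seen when the fit was made before applying `c f(a x + b) + d`;
#' `categorical_map` looks the (encoded) level position up in a finite table
#' and errors on unseen codes; `pruned` edges are identically zero.
#'
#' @param edge a `kan_edge`.
#' @param x numeric vector of pre-activations.
#' @return numeric vector of post-activations.
#' @export
edge_eval <- function(edge, x) {
  x <- as.numeric(x)
  switch(edge$state,
    spline = {
      b <- basis_fun(edge$basis_kind)
      xc <- clamp(x, edge$spline$lo, edge$spline$hi)
      edge$w_b * b$f(x) + edge$w_s * spline_eval(edge$spline, xc)
    },
    symbolic = {
      fit <- edge$symbolic_fit
      if (is.null(fit)) stop("symbolic edge has no fit")
      xc <- clamp(x, fit$x_range[1L], fit$x_range[2L])
      symbolic_fit_eval(fit, xc)
    },
    categorical_map = {
      m <- edge$category_map
      if (is.null(m)) stop("categorical edge has no map")
      idx <- match(round(x, 8), round(m$positions, 8))
      if (anyNA(idx))
        stop("unseen category code(s) in categorical_map lookup: ",
             paste(unique(x[is.na(idx)]), collapse = ", "))
      m$values[idx]
    },
    pruned = numeric(length(x)),
    stop("unknown edge state: ", edge$state)
  )
}

# derivative of the edge output w.r.t. its input (spline state only);
# zero outside the grid where the spline is flat-extrapolated
edge_deriv <- function(edge, x) {
  stopifnot(edge$state == "spline")
  b <- basis_fun(edge$basis_kind)
  inside <- x >= edge$spline$lo & x <= edge$spline$hi
  xc <- clamp(x, edge$spline$lo, edge$spline$hi)
  ds <- spline_eval(edge$spline, xc, deriv = 1L) * as.numeric(inside)
  edge$w_b * b$df(x) + edge$w_s * ds
}

#' KAN layer
#'
#' A dense grid of `n_out x n_in` activation edges. Output node `j` is the sum
#' over inputs `i` of `phi[j,i](x_i)`.
#'
#' @param n_in,n_out layer dimensions.
#' @param edges list of `n_out * n_in` `kan_edge`s in row-major order
#'   (edge (j, i) at index `(j-1) * n_in + i`).
#' @return an object of class `kan_layer`.
#' @export
kan_layer <- function(n_in, n_out, edges) {
  if (length(edges) != n_in * n_out)
    stop("layer needs n_out * n_in edges")
  structure(list(n_in = as.integer(n_in), n_out = as.integer(n_out),
                 edges = edges),
            class = "kan_layer")
}

edge_index <- function(layer, j, i) (j - 1L) * layer$n_in + i

layer_forward <- function(layer, X, keep_edges = FALSE) {
  n <- nrow(X)
  out <- matrix(0, n, layer$n_out)
  E <- if (keep_edges) matrix(0, n, layer$n_in * layer$n_out) else NULL
  for (j in seq_len(layer$n_out)) {
    for (i in seq_len(layer$n_in)) {
      e <- layer$edges[[edge_index(layer, j, i)]]
      if (e$state == "pruned") next
      y <- edge_eval(e, X[, i])
      out[, j] <- out[, j] + y
      if (keep_edges) E[, edge_index(layer, j, i)] <- y
    }
  }
  list(out = out, edge_out = E)
}

#' Construct a KAN survival model
#'
#' Builds a Kolmogorov-Arnold network that maps a covariate vector to a single
#' scalar: the log-partial hazard of a proportional-hazards model. Layer
#' widths are given by `shape = c(n0, n1, ..., 1)`; between consecutive layers
#' every input-output pair carries its own learnable spline activation.
#' Inputs are affinely normalized per feature to `[-1, 1]` (the first layer's
#' grid domain); hidden-layer splines live on the wider fixed domain
#' `[-hidden_range, hidden_range]` since node sums are unbounded.
#'
#' Spline coefficients are initialized i.i.d. normal with small scale under
#' `seed`; `w_b = w_s = 1`.
#'
#' @param shape integer vector of layer widths; last entry must be 1.
#' @param feature_names names of the `shape[1]` input features.
#' @param G grid intervals per spline (typically 3-5).
#' @param k spline degree.
#' @param basis_kind residual basis, `"silu"` (default) or `"identity"`.
#' @param seed integer seed controlling coefficient initialization.
#' @param init_scale s.d. of the initial spline coefficients.
#' @param hidden_range half-width of the hidden-layer grid domain.
#' @param normalization optional list with per-feature `alpha`, `beta` such
#'   that the network sees `alpha * x + beta`; default is the identity (set it
#'   from training data with [kan_set_normalization()]).
#' @return an object of class `kan_model`.
#' @export
kan_model <- function(shape, feature_names = NULL, G = 5L, k = 3L,
                      basis_kind = "silu", seed = 0L, init_scale = 0.1,
                      hidden_range = 4, normalization = NULL) {
  shape <- as.integer(shape)
  if (length(shape) < 2L) stop("shape needs at least input and output widths")
  if (shape[length(shape)] != 1L)
    stop("survival KAN must have a single output node (log-partial hazard)")
  if (any(shape < 1L)) stop("layer widths must be positive")
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(shape[1L]))
  if (length(feature_names) != shape[1L])
    stop("feature_names length must equal the input width")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  L <- length(shape) - 1L
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    dom <- if (l == 1L) c(-1, 1) else c(-hidden_range, hidden_range)
    n_in <- shape[l]; n_out <- shape[l + 1L]
    edges <- replicate(n_in * n_out, {
      sp <- kan_spline(k = k, G = G, lo = dom[1L], hi = dom[2L],
                       coef = stats::rnorm(G + k, 0, init_scale))
      kan_edge(sp, basis_kind = basis_kind)
    }, simplify = FALSE)
    layers[[l]] <- kan_layer(n_in, n_out, edges)
  }
  if (is.null(normalization))
    normalization <- list(alpha = rep(1, shape[1L]), beta = rep(0, shape[1L]))
  structure(list(shape = shape, layers = layers,
                 feature_names = feature_names,
                 normalization = normalization,
                 G = as.integer(G), k = as.integer(k),
                 basis_kind = basis_kind, hidden_range = hidden_range,
                 pruned_nodes = lapply(shape, function(n) logical(n))),
            class = "kan_model")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

#' Fit the input normalization of a model from training covariates
#'
#' Stores the per-feature affine map sending the training min/max to
#' `[-1, 1]`. Constant features map to 0. The same map is applied unchanged
#' at prediction time (inputs beyond the training range are clamped by the
#' first-layer splines' flat extrapolation).
#'
#' @param model a `kan_model`.
#' @param X training covariate matrix.
#' @return the model with normalization set.
#' @export
kan_set_normalization <- function(model, X) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rng <- hi - lo
  alpha <- ifelse(rng > 0, 2 / rng, 0)
  beta  <- ifelse(rng > 0, -(hi + lo) / rng, 0)
  model$normalization <- list(alpha = as.numeric(alpha),
                              beta = as.numeric(beta))
  model
}

normalize_input <- function(model, X) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, model$normalization$alpha, "*"),
        2, model$normalization$beta, "+")
}

#' KAN forward pass
#'
#' Computes the estimated log-partial hazard for each row of `X` by composing
#' the layers: node `j` of layer `l+1` is the sum over `i` of
#' `phi[l,j,i](x[l,i])`. Deterministic given the parameters.
#'
#' @param model a `kan_model`.
#' @param X covariate matrix (raw scale; `ncol` must equal the input width).
#' @param cache if `TRUE`, also return per-layer inputs and per-edge outputs
#'   (needed for backpropagation and regularization bookkeeping).
#' @return numeric vector of log-partial hazards, or (with `cache = TRUE`) a
#'   list with elements `theta`, `inputs`, `edge_out`.
#' @export
kan_forward <- function(model, X, cache = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != model$shape[1L])
    stop(sprintf("input width %d does not match model input width %d",
                 ncol(X), model$shape[1L]))
  A <- normalize_input(model, X)
  inputs <- vector("list", length(model$layers))
  edge_out <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    inputs[[l]] <- A
    fw <- layer_forward(model$layers[[l]], A, keep_edges = cache)
    edge_out[[l]] <- fw$edge_out
    A <- fw$out
  }
  theta <- drop(A)
  if (!cache) return(theta)
  list(theta = theta, inputs = inputs, edge_out = edge_out)
}

# ---- parameter flattening (for the optimizer) -------------------------------

# only spline-state edges carry trainable parameters: (w_b, w_s, coef)
kan_get_params <- function(model) {
  unlist(lapply(model$layers, function(ly)
    lapply(ly$edges, function(e)
      if (e$state == "spline") c(e$w_b, e$w_s, e$spline$coef) else numeric(0))))
}

kan_set_params <- function(model, par) {
  pos <- 0L
  for (l in seq_along(model$layers)) {
    for (e in seq_along(model$layers[[l]]$edges)) {
      ed <- model$layers[[l]]$edges[[e]]
      if (ed$state != "spline") next
      nc <- length(ed$spline$coef)
      ed$w_b <- par[pos + 1L]
      ed$w_s <- par[pos + 2L]
      ed$spline$coef <- par[pos + 2L + seq_len(nc)]
      pos <- pos + 2L + nc
      model$layers[[l]]$edges[[e]] <- ed
    }
  }
  if (pos != length(par)) stop("parameter vector length mismatch")
  model
}

# Backpropagation through the network. `cache` comes from
# kan_forward(cache = TRUE); `g_theta` is dL/dtheta per row; `g_edge_extra`
# is an optional list (per layer) of n x n_edges matrices of additional
# gradient applied directly to each edge output (used by the activation-L1 and
# entropy regularizers). Returns the gradient as a flat vector aligned with
# kan_get_params().
kan_backward <- function(model, cache, g_theta, g_edge_extra = NULL) {
  L <- length(model$layers)
  grads <- vector("list", L)
  g_nodes <- matrix(g_theta, ncol = 1L)   # dL/d(output nodes of last layer)
  for (l in rev(seq_len(L))) {
    ly <- model$layers[[l]]
    X <- cache$inputs[[l]]
    n <- nrow(X)
    g_in <- matrix(0, n, ly$n_in)
    gl <- vector("list", length(ly$edges))
    for (j in seq_len(ly$n_out)) {
      for (i in seq_len(ly$n_in)) {
        idx <- edge_index(ly, j, i)
        e <- ly$edges[[idx]]
        if (e$state != "spline") { gl[[idx]] <- numeric(0); next }
        gy <- g_nodes[, j]
        if (!is.null(g_edge_extra) && !is.null(g_edge_extra[[l]]))
          gy <- gy + g_edge_extra[[l]][, idx]
        x <- X[, i]
        b <- basis_fun(e$basis_kind)
        xc <- clamp(x, e$spline$lo, e$spline$hi)
        B <- bspline_basis(xc, e$spline)
        sp <- drop(B %*% e$spline$coef)
        g_wb <- sum(gy * b$f(x))
        g_ws <- sum(gy * sp)
        g_coef <- drop(crossprod(B, gy)) * e$w_s
        inside <- as.numeric(x >= e$spline$lo & x <= e$spline$hi)
        dsp <- drop(bspline_basis(xc, e$spline, deriv = 1L) %*%
                      e$spline$coef) * inside
        g_in[, i] <- g_in[, i] + gy * (e$w_b * b$df(x) + e$w_s * dsp)
        gl[[idx]] <- c(g_wb, g_ws, g_coef)
      }
    }
    grads[[l]] <- gl
    g_nodes <- g_in
  }
  unlist(grads)
}

#' @export
print.kan_model <- function(x, ...) {
  cat("KAN survival model  shape [", paste(x$shape, collapse = ", "),
      "]  G =", x$G, " k =", x$k, " basis =", x$basis_kind, "\n")
  states <- table(unlist(lapply(x$layers, function(ly)
    vapply(ly$edges, function(e) e$state, ""))))
  cat("edges:", paste(names(states), as.integer(states),
                      sep = "=", collapse = "  "), "\n")
  invisible(x)
}
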