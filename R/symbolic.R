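#' Univariate operator library for symbolic fitting
#'
#' The candidate operators `f` used when an activation is distilled into the
#' affine-wrapped form `phi(x) = c f(a x + b) + d`. Each entry provides the
#' numeric function, a domain predicate (points violating it are excluded
#' from that operator's search grid), and an expression template used when
#' the closed-form hazard formula is assembled.
#'
#' @return named list of operators.
#' @export
op_library <- function() {
  ok_all <- function(z) rep(TRUE, length(z))
  list(
    x        = list(f = function(z) z,            dom = ok_all,
                    expr = function(u) u),
    x2       = list(f = function(z) z^2,          dom = ok_all,
                    expr = function(u) bquote((.(u))^2)),
    x3       = list(f = function(z) z^3,          dom = ok_all,
                    expr = function(u) bquote((.(u))^3)),
    x4       = list(f = function(z) z^4,          dom = ok_all,
                    expr = function(u) bquote((.(u))^4)),
    inv      = list(f = function(z) 1 / z,        dom = function(z) abs(z) > 1e-6,
                    expr = function(u) bquote(1 / (.(u)))),
    inv2     = list(f = function(z) 1 / z^2,      dom = function(z) abs(z) > 1e-6,
                    expr = function(u) bquote(1 / (.(u))^2)),
    sqrt     = list(f = function(z) sqrt(z),      dom = function(z) z >= 0,
                    expr = function(u) bquote(sqrt(.(u)))),
    exp      = list(f = function(z) exp(z),       dom = function(z) z < 50,
                    expr = function(u) bquote(exp(.(u)))),
    log      = list(f = function(z) log(z),       dom = function(z) z > 1e-12,
                    expr = function(u) bquote(log(.(u)))),
    abs      = list(f = function(z) abs(z),       dom = ok_all,
                    expr = function(u) bquote(abs(.(u)))),
    sin      = list(f = function(z) sin(z),       dom = ok_all,
                    expr = function(u) bquote(sin(.(u)))),
    cos      = list(f = function(z) cos(z),       dom = ok_all,
                    expr = function(u) bquote(cos(.(u)))),
    tan      = list(f = function(z) tan(z),       dom = function(z)
                      abs(cos(z)) > 1e-3,
                    expr = function(u) bquote(tan(.(u)))),
    tanh     = list(f = function(z) tanh(z),      dom = ok_all,
                    expr = function(u) bquote(tanh(.(u)))),
    sigmoid  = list(f = function(z) stats::plogis(z), dom = ok_all,
                    expr = function(u) bquote(1 / (1 + exp(-(.(u)))))),
    sgn      = list(f = function(z) sign(z),      dom = ok_all,
                    expr = function(u) bquote(sign(.(u)))),
    arcsin   = list(f = function(z) asin(z),      dom = function(z) abs(z) <= 1,
                    expr = function(u) bquote(asin(.(u)))),
    arctan   = list(f = function(z) atan(z),      dom = ok_all,
                    expr = function(u) bquote(atan(.(u)))),
    arccosh  = list(f = function(z) acosh(z),     dom = function(z) z >= 1,
                    expr = function(u) bquote(acosh(.(u)))),
    gaussian = list(f = function(z) exp(-z^2),    dom = ok_all,
                    expr = function(u) bquote(exp(-(.(u))^2))),
    step     = list(f = function(z) as.numeric(z > 0), dom = ok_all,
                    expr = function(u) bquote(as.numeric(.(u) > 0))),
    const    = list(f = function(z) rep(1, length(z)), dom = ok_all,
                    expr = function(u) 1)
  )
}

r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - yhat)^2)
  if (sst == 0) return(if (sse < 1e-20) 1 else -Inf)
  1 - sse / sst
}

new_symbolic_fit <- function(op, a, b, c, d, r2, stage, x_range,
                             expr = NULL, accepted = NA, warn = FALSE) {
  structure(list(op = op, a = a, b = b, c = c, d = d, r2 = r2,
                 stage = stage, x_range = as.numeric(x_range),
                 expr = expr, accepted = accepted, warn = warn),
            class = "symbolic_fit")
}

#' @export
print.symbolic_fit <- function(x, ...) {
  cat(sprintf("symbolic fit [%s]: %s  R2 = %.5f\n", x$stage,
              deparse1(symbolic_fit_expr(x, quote(x))), x$r2))
  invisible(x)
}

# numeric evaluation of a symbolic fit at (already clamped) x
symbolic_fit_eval <- function(fit, x) {
  if (fit$stage == "genetic") {
    y <- eval_gp_tree(fit$tree, x)
  } else {
    y <- fit$c * op_library()[[fit$op]]$f(fit$a * x + fit$b) + fit$d
  }
  y[!is.finite(y)] <- if (is.null(fit$d)) 0 else fit$d
  y
}

#' Least-squares linear fit of activation samples
#'
#' First stage of progressive symbolic fitting: an ordinary least-squares
#' line through the pre/post-activation pairs, accepted when `R^2 > 0.99`.
#' A constant response is returned as that constant with `R^2` defined as 1.
#'
#' @param x,y numeric vectors of pre- and post-activation samples
#'   (at least two distinct `x`).
#' @param accept_r2 acceptance threshold (default 0.99).
#' @return a `symbolic_fit` with `stage = "linear"` (slope in `c`, intercept
#'   in `d`, operator = identity) and an `accepted` flag.
#' @export
fit_linear <- function(x, y, accept_r2 = 0.99) {
  if (length(unique(x)) < 2L) stop("fit_linear needs >= 2 distinct x values")
  if (stats::var(y) == 0) {
    return(new_symbolic_fit("x", 1, 0, 0, y[1L], 1, "linear", range(x),
                            accepted = TRUE))
  }
  vx <- stats::var(x)
  slope <- stats::cov(x, y) / vx
  icpt <- mean(y) - slope * mean(x)
  r2 <- r_squared(y, slope * x + icpt)
  new_symbolic_fit("x", 1, 0, slope, icpt, r2, "linear", range(x),
                   accepted = r2 > accept_r2)
}

#' Fit the best affine-wrapped library operator
#'
#' Second stage of progressive symbolic fitting. For every operator `f` in
#' the library, `(a, b)` are scanned over a bounded grid (log-spaced
#' magnitudes for `a` with both signs, linear for `b`); at each grid point
#' `(c, d)` solve the linear regression of `y` on `f(a x + b)` in closed
#' form. The best `(f, a, b, c, d)` by `R^2` is then polished by Nelder-Mead
#' over all four affine parameters. Grid points violating an operator's
#' domain on the sample are skipped (not fatal).
#'
#' @param x,y pre/post-activation samples.
#' @param library operator list (default [op_library()]).
#' @param accept_r2 acceptance threshold (default 0.95).
#' @param a_grid,b_grid candidate inner affine parameters.
#' @param max_grid_n cap on sample size used during the grid scan (the polish
#'   and reported `R^2` always use all pairs).
#' @return a `symbolic_fit` with `stage = "library"`.
#' @export
fit_operator_library <- function(x, y, library = op_library(),
                                 accept_r2 = 0.95,
                                 a_grid = NULL, b_grid = NULL,
                                 max_grid_n = 400L) {
  if (length(library) == 0) stop("operator library is empty")
  if (length(unique(x)) < 2L) stop("need >= 2 distinct x values")
  if (is.null(a_grid)) {
    mags <- exp(seq(log(0.1), log(10), length.out = 21L))
    a_grid <- c(-rev(mags), mags)
  }
  if (is.null(b_grid)) b_grid <- seq(-5, 5, length.out = 21L)
  if (length(x) > max_grid_n) {
    sub <- round(seq(1L, length(x), length.out = max_grid_n))
    o <- order(x)
    xs <- x[o][sub]; ys <- y[o][sub]
  } else { xs <- x; ys <- y }
  # grid scan: best (a, b) per operator, (c, d) by closed-form regression
  per_op <- list()
  for (op_name in names(library)) {
    op <- library[[op_name]]
    best <- NULL
    for (a in a_grid) {
      za <- a * xs
      for (b in b_grid) {
        z <- za + b
        if (!all(op$dom(z))) next
        fz <- op$f(z)
        if (!all(is.finite(fz))) next
        vz <- stats::var(fz)
        if (vz < 1e-14) { cc <- 0; dd <- mean(ys) }
        else {
          cc <- stats::cov(ys, fz) / vz
          dd <- mean(ys) - cc * mean(fz)
        }
        r2 <- r_squared(ys, cc * fz + dd)
        if (is.null(best) || r2 > best$r2)
          best <- list(r2 = r2, a = a, b = b, c = cc, d = dd)
      }
    }
    if (!is.null(best)) per_op[[op_name]] <- best
  }
  if (length(per_op) == 0L) stop("no admissible operator/grid point found")
  # polish each operator's best grid candidate on the full sample, then
  # pick the best polished fit (avoids a flexible operator edging out the
  # true one on grid resolution alone)
  final <- list(r2 = -Inf)
  for (op_name in names(per_op)) {
    op <- library[[op_name]]
    cand <- per_op[[op_name]]
    sse <- function(p) {
      z <- p[1L] * x + p[2L]
      if (!all(op$dom(z))) return(1e12)
      fz <- op$f(z)
      if (!all(is.finite(fz))) return(1e12)
      sum((y - (p[3L] * fz + p[4L]))^2)
    }
    p0 <- c(cand$a, cand$b, cand$c, cand$d)
    pol <- stats::optim(p0, sse, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    p <- if (pol$value <= sse(p0)) pol$par else p0
    fz <- op$f(p[1L] * x + p[2L]); fz[!is.finite(fz)] <- 0
    r2 <- r_squared(y, p[3L] * fz + p[4L])
    if (r2 > final$r2)
      final <- list(r2 = r2, op = op_name, a = p[1L], b = p[2L],
                    c = p[3L], d = p[4L])
  }
  new_symbolic_fit(final$op, final$a, final$b, final$c, final$d, final$r2,
                   "library", range(x), accepted = final$r2 > accept_r2)
}

# expression for a fit in terms of an arbitrary argument expression `u`
symbolic_fit_expr <- function(fit, u) {
  if (fit$stage == "genetic") {
    e <- gp_tree_to_expr(fit$tree)
    return(simplify_expr(sub_var(e, "x", u)))
  }
  inner <- simplify_expr(bquote(.(fit$a) * .(u) + .(fit$b)))
  fe <- op_library()[[fit$op]]$expr(inner)
  simplify_expr(bquote(.(fit$c) * .(fe) + .(fit$d)))
}

# ---- expression utilities ---------------------------------------------------

# substitute variable `name` by expression `repl` throughout `e`
sub_var <- function(e, name, repl) {
  if (is.symbol(e)) {
    if (identical(as.character(e), name)) return(repl) else return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) e[[i]] <- sub_var(e[[i]], name, repl)
    return(e)
  }
  e
}

# constant folding + trivial algebraic identities
simplify_expr <- function(e) {
  if (!is.call(e)) return(e)
  for (i in seq_along(e)[-1L]) e[[i]] <- simplify_expr(e[[i]])
  args_num <- vapply(as.list(e)[-1L], is.numeric, TRUE)
  fname <- as.character(e[[1L]])
  if (all(args_num) && fname %in% c("+", "-", "*", "/", "^", "(", "exp",
                                    "log", "sqrt", "abs", "sin", "cos",
                                    "tan", "tanh", "sign", "asin", "atan",
                                    "acosh")) {
    v <- tryCatch(eval(e, baseenv()), error = function(err) NULL)
    if (!is.null(v) && length(v) == 1L && is.finite(v)) return(v)
  }
  if (fname == "(") return(e[[2L]])
  is_num <- function(a, v) is.numeric(a) && length(a) == 1L &&
    isTRUE(all.equal(a, v, tolerance = 1e-15))
  if (fname == "*" && length(e) == 3L) {
    if (is_num(e[[2L]], 1)) return(e[[3L]])
    if (is_num(e[[3L]], 1)) return(e[[2L]])
    if (is_num(e[[2L]], 0) || is_num(e[[3L]], 0)) return(0)
  }
  if (fname == "+" && length(e) == 3L) {
    if (is_num(e[[2L]], 0)) return(e[[3L]])
    if (is_num(e[[3L]], 0)) return(e[[2L]])
  }
  if (fname == "-" && length(e) == 3L && is_num(e[[3L]], 0)) return(e[[2L]])
  if (fname == "^" && length(e) == 3L && is_num(e[[3L]], 1)) return(e[[2L]])
  e
}

# ---- genetic-programming fallback ------------------------------------------

# protected operators used inside evolved expressions
#' Protected division: denominator bounded away from zero
#' @param a,b numerators / denominators.
#' @return `a / b` with `|b|` floored at 1e-9 (sign preserved).
#' @export
pdiv <- function(a, b) a / ifelse(abs(b) < 1e-9, sign(b + (b == 0)) * 1e-9, b)

#' Protected logarithm: `log(|x| + 1e-12)`
#' @param x numeric.
#' @return protected log values.
#' @export
plog <- function(x) log(abs(x) + 1e-12)

#' Protected square root: `sqrt(|x|)`
#' @param x numeric.
#' @return protected square-root values.
#' @export
psqrt <- function(x) sqrt(abs(x))

gp_ops <- function() {
  list(
    binary = list(
      add = list(f = function(a, b) a + b, sym = "+"),
      sub = list(f = function(a, b) a - b, sym = "-"),
      mul = list(f = function(a, b) a * b, sym = "*"),
      div = list(f = pdiv,                 sym = "pdiv")
    ),
    unary = list(
      sin    = list(f = sin,                 sym = "sin"),
      cos    = list(f = cos,                 sym = "cos"),
      exp    = list(f = function(z) exp(pmin(z, 50)), sym = "exp"),
      log    = list(f = plog,                sym = "plog"),
      abs    = list(f = abs,                 sym = "abs"),
      square = list(f = function(z) z^2,     sym = "square"),
      sqrt   = list(f = psqrt,               sym = "psqrt")
    )
  )
}

gp_random_tree <- function(depth, ops, p_const = 0.3, full = FALSE) {
  if (depth <= 0 ||
      (!full && stats::runif(1) < 0.3)) {
    if (stats::runif(1) < p_const)
      return(list(type = "const", value = round(stats::runif(1, -3, 3), 3)))
    return(list(type = "var"))
  }
  if (stats::runif(1) < 0.6) {
    nm <- sample(names(ops$binary), 1L)
    list(type = "bin", name = nm,
         l = gp_random_tree(depth - 1L, ops, p_const, full),
         r = gp_random_tree(depth - 1L, ops, p_const, full))
  } else {
    nm <- sample(names(ops$unary), 1L)
    list(type = "un", name = nm,
         a = gp_random_tree(depth - 1L, ops, p_const, full))
  }
}

eval_gp_tree <- function(node, x) {
  ops <- gp_ops()
  rec <- function(nd) {
    switch(nd$type,
           var = x,
           const = rep(nd$value, length(x)),
           bin = ops$binary[[nd$name]]$f(rec(nd$l), rec(nd$r)),
           un  = ops$unary[[nd$name]]$f(rec(nd$a)))
  }
  rec(node)
}

gp_tree_size <- function(node) {
  switch(node$type,
         var = 1L, const = 1L,
         bin = 1L + gp_tree_size(node$l) + gp_tree_size(node$r),
         un  = 1L + gp_tree_size(node$a))
}

gp_tree_to_expr <- function(node) {
  switch(node$type,
    var = quote(x),
    const = node$value,
    bin = {
      sym <- gp_ops()$binary[[node$name]]$sym
      as.call(list(as.name(sym), gp_tree_to_expr(node$l),
                   gp_tree_to_expr(node$r)))
    },
    un = {
      sym <- gp_ops()$unary[[node$name]]$sym
      if (sym == "square")
        bquote((.(gp_tree_to_expr(node$a)))^2)
      else
        as.call(list(as.name(sym), gp_tree_to_expr(node$a)))
    })
}

# enumerate node paths; path is an integer vector of slot picks
gp_paths <- function(node, prefix = integer(0)) {
  out <- list(prefix)
  if (node$type == "bin") {
    out <- c(out, gp_paths(node$l, c(prefix, 1L)),
             gp_paths(node$r, c(prefix, 2L)))
  } else if (node$type == "un") {
    out <- c(out, gp_paths(node$a, c(prefix, 1L)))
  }
  out
}

gp_get <- function(node, path) {
  for (p in path) node <- if (node$type == "bin") {
    if (p == 1L) node$l else node$r
  } else node$a
  node
}

gp_set <- function(node, path, sub) {
  if (length(path) == 0L) return(sub)
  if (node$type == "bin") {
    if (path[1L] == 1L) node$l <- gp_set(node$l, path[-1L], sub)
    else node$r <- gp_set(node$r, path[-1L], sub)
  } else node$a <- gp_set(node$a, path[-1L], sub)
  node
}

gp_mutate <- function(node, ops, max_depth) {
  u <- stats::runif(1)
  paths <- gp_paths(node)
  path <- paths[[sample.int(length(paths), 1L)]]
  target <- gp_get(node, path)
  if (u < 0.4) {                         # subtree replacement
    gp_set(node, path, gp_random_tree(sample(1:2, 1L), ops))
  } else if (u < 0.7 && target$type == "const") {   # constant jitter
    target$value <- target$value + stats::rnorm(1, 0, 0.3)
    gp_set(node, path, target)
  } else if (target$type == "bin") {     # operator swap
    target$name <- sample(names(ops$binary), 1L)
    gp_set(node, path, target)
  } else if (target$type == "un") {
    target$name <- sample(names(ops$unary), 1L)
    gp_set(node, path, target)
  } else {
    gp_set(node, path, gp_random_tree(1L, ops))
  }
}

gp_crossover <- function(a, b) {
  pa <- gp_paths(a); pb <- gp_paths(b)
  path_a <- pa[[sample.int(length(pa), 1L)]]
  path_b <- pb[[sample.int(length(pb), 1L)]]
  gp_set(a, path_a, gp_get(b, path_b))
}

# tune the numeric constants of a tree by Nelder-Mead on the SSE
gp_polish_constants <- function(node, x, y) {
  consts <- list(); paths <- gp_paths(node)
  cpaths <- Filter(function(p) gp_get(node, p)$type == "const", paths)
  if (length(cpaths) == 0L) return(node)
  p0 <- vapply(cpaths, function(p) gp_get(node, p)$value, 0)
  obj <- function(p) {
    nd <- node
    for (i in seq_along(cpaths))
      nd <- gp_set(nd, cpaths[[i]], list(type = "const", value = p[i]))
    yh <- eval_gp_tree(nd, x)
    if (!all(is.finite(yh))) return(1e12)
    sum((y - yh)^2)
  }
  fit <- if (length(p0) == 1L)
    stats::optim(p0, obj, method = "Brent", lower = p0 - 10, upper = p0 + 10)
  else stats::optim(p0, obj, method = "Nelder-Mead",
                    control = list(maxit = 300))
  if (fit$value < obj(p0)) {
    for (i in seq_along(cpaths))
      node <- gp_set(node, cpaths[[i]],
                     list(type = "const", value = fit$par[i]))
  }
  node
}

#' Default configuration for genetic symbolic regression
#'
#' @param pop_size population size per generation.
#' @param generations number of generations per restart.
#' @param max_depth maximum initial tree depth.
#' @param tournament tournament size for selection.
#' @param p_crossover crossover probability (else mutation).
#' @param parsimony complexity penalty per tree node added to `1 - R^2`.
#' @param n_restarts independent restarts (best result kept).
#' @param seed RNG seed; all randomness in the search derives from it.
#' @param polish_constants numerically refine constants of the best tree.
#' @return a config list for [fit_genetic()].
#' @export
gp_config <- function(pop_size = 300L, generations = 60L, max_depth = 4L,
                      tournament = 5L, p_crossover = 0.8,
                      parsimony = 1e-3, n_restarts = 2L, seed = 0L,
                      polish_constants = TRUE) {
  list(pop_size = pop_size, generations = generations, max_depth = max_depth,
       tournament = tournament, p_crossover = p_crossover,
       parsimony = parsimony, n_restarts = n_restarts, seed = seed,
       polish_constants = polish_constants)
}

#' Genetic-programming symbolic regression of activation samples
#'
#' Final stage of progressive symbolic fitting, engaged when no single
#' library operator fits well enough. Evolves expression trees over
#' `{+, -, *, /, sin, cos, exp, log, abs, square, sqrt}` (division, log and
#' sqrt in protected form) with tournament selection, subtree crossover and
#' mutation, and a parsimony penalty on tree size. Deterministic under the
#' config seed; if the search budget is exhausted below the acceptance
#' threshold the best-so-far expression is returned with a warning flag.
#'
#' @param x,y pre/post-activation samples.
#' @param config a [gp_config()] list.
#' @param accept_r2 threshold used only to set the warning flag.
#' @return a `symbolic_fit` with `stage = "genetic"` and fields `tree`
#'   (internal representation) and `expr` (an R expression in `x`).
#' @export
fit_genetic <- function(x, y, config = gp_config(), accept_r2 = 0.99) {
  ops <- gp_ops()
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  sst <- sum((y - mean(y))^2)
  fitness <- function(node) {
    yh <- eval_gp_tree(node, x)
    if (!all(is.finite(yh))) return(Inf)
    sse <- sum((y - yh)^2)
    r2 <- if (sst == 0) as.numeric(sse > 1e-20) else sse / sst
    r2 + config$parsimony * gp_tree_size(node)
  }
  best <- NULL; best_fit <- Inf
  for (rs in seq_len(config$n_restarts)) {
    set.seed(as.integer(config$seed) + 7919L * (rs - 1L))
    pop <- lapply(seq_len(config$pop_size), function(i)
      gp_random_tree(1L + (i %% config$max_depth), ops,
                     full = i %% 2L == 0L))
    fits <- vapply(pop, fitness, 0)
    for (gen in seq_len(config$generations)) {
      newpop <- vector("list", config$pop_size)
      # elitism: carry over the best individual
      eb <- which.min(fits)
      newpop[[1L]] <- pop[[eb]]
      for (i in 2:config$pop_size) {
        pick <- function() {
          cand <- sample.int(config$pop_size, config$tournament)
          pop[[cand[which.min(fits[cand])]]]
        }
        child <- if (stats::runif(1) < config$p_crossover)
          gp_crossover(pick(), pick())
        else gp_mutate(pick(), ops, config$max_depth)
        if (gp_tree_size(child) > 40L) child <- pick()
        newpop[[i]] <- child
      }
      pop <- newpop
      fits <- vapply(pop, fitness, 0)
    }
    b <- which.min(fits)
    cand <- pop[[b]]
    if (config$polish_constants) cand <- gp_polish_constants(cand, x, y)
    cf <- fitness(cand)
    if (cf < best_fit) { best <- cand; best_fit <- cf }
  }
  yh <- eval_gp_tree(best, x)
  r2 <- r_squared(y, yh)
  fit <- new_symbolic_fit(op = NA_character_, a = NA, b = NA, c = NA,
                          d = mean(y), r2 = r2, stage = "genetic",
                          x_range = range(x), accepted = r2 > accept_r2,
                          warn = r2 <= accept_r2)
  fit$tree <- best
  fit$expr <- simplify_expr(gp_tree_to_expr(best))
  fit
}

# ---- edge-level symbolization ----------------------------------------------

#' Thresholds and knobs for progressive symbolic fitting
#' @param linear_r2 acceptance threshold for the linear stage (stated
#'   default 0.99).
#' @param library_r2 acceptance threshold for the operator-library stage.
#' @param max_pairs cap on activation sample pairs used per edge.
#' @param gp [gp_config()] for the genetic fallback.
#' @return a config list.
#' @export
symbolic_config <- function(linear_r2 = 0.99, library_r2 = 0.95,
                            max_pairs = 1000L, gp = gp_config()) {
  list(linear_r2 = linear_r2, library_r2 = library_r2,
       max_pairs = max_pairs, gp = gp)
}

#' Distill one activation edge into symbolic form
#'
#' Progressive scheme: a linear fit is tried first and accepted at
#' `R^2 > linear_r2`; otherwise the best affine-wrapped library operator is
#' fitted and accepted at `R^2 > library_r2`; otherwise genetic symbolic
#' regression is engaged and its best expression is kept regardless (with a
#' warning flag if still poor). Later stages are never run once an earlier
#' stage accepts. The edge's evaluation is replaced by the symbolic form.
#'
#' @param edge a trained `kan_edge` in `spline` state.
#' @param x numeric vector of pre-activations observed for this edge.
#' @param config a [symbolic_config()].
#' @return the edge in `symbolic` state; attribute `"stages_tried"` lists the
#'   stages that were actually run.
#' @export
symbolize_edge <- function(edge, x, config = symbolic_config()) {
  stopifnot(inherits(edge, "kan_edge"))
  if (edge$state != "spline")
    stop("symbolize_edge expects an edge in 'spline' state")
  if (length(x) > config$max_pairs) {
    o <- order(x)
    x <- x[o][round(seq(1L, length(x), length.out = config$max_pairs))]
  }
  y <- edge_eval(edge, x)
  tried <- "linear"
  fit <- fit_linear(x, y, accept_r2 = config$linear_r2)
  if (!isTRUE(fit$accepted)) {
    tried <- c(tried, "library")
    fit <- fit_operator_library(x, y, accept_r2 = config$library_r2)
    if (!isTRUE(fit$accepted)) {
      tried <- c(tried, "genetic")
      fit <- fit_genetic(x, y, config = config$gp,
                         accept_r2 = config$library_r2)
    }
  }
  edge$state <- "symbolic"
  edge$symbolic_fit <- fit
  attr(edge, "stages_tried") <- tried
  edge
}

#' Replace a categorical feature's activation by a discrete map
#'
#' For a label-encoded categorical input the learned spline is only ever
#' evaluated at the finite set of encoded level positions, so its exact
#' symbolic form is a lookup table: code -> activation value. This bypasses
#' all curve-fitting stages and reproduces the trained forward pass exactly.
#'
#' @param edge a `kan_edge` in `spline` state.
#' @param codes integer level codes (0, 1, ...).
#' @param positions the codes as the edge sees them (i.e. after input
#'   normalization).
#' @return the edge in `categorical_map` state.
#' @export
categorical_to_map <- function(edge, codes, positions) {
  stopifnot(inherits(edge, "kan_edge"), edge$state == "spline",
            length(codes) == length(positions))
  values <- edge_eval(edge, positions)
  edge$state <- "categorical_map"
  edge$category_map <- list(codes = as.numeric(codes),
                            positions = as.numeric(positions),
                            values = as.numeric(values))
  edge
}

#' Symbolize every retained edge of a trained model
#'
#' Walks the network layer by layer, converting each non-pruned spline edge
#' into symbolic form with [symbolize_edge()] (or [categorical_to_map()] for
#' first-layer edges fed by a declared categorical feature). Pre-activations
#' for each layer are recomputed from the partially symbolized model, so
#' later layers are fitted against the inputs they will actually receive.
#'
#' @param model a trained (optionally pruned) `kan_model`.
#' @param data a `survival_dataset` supplying pre-activations; its
#'   `categorical_levels` mark categorical features.
#' @param config a [symbolic_config()].
#' @return the symbolized model; attribute `"symbolic_report"` is a data
#'   frame of per-edge stage and `R^2`.
#' @export
symbolize <- function(model, data, config = symbolic_config()) {
  stopifnot(inherits(model, "kan_model"),
            inherits(data, "survival_dataset"))
  A <- normalize_input(model, data$X)
  rows <- list()
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    for (j in seq_len(ly$n_out)) for (i in seq_len(ly$n_in)) {
      idx <- edge_index(ly, j, i)
      e <- model$layers[[l]]$edges[[idx]]
      if (e$state != "spline") next
      fname <- if (l == 1L) model$feature_names[i] else NA_character_
      if (l == 1L && fname %in% names(data$categorical_levels)) {
        codes <- seq_along(data$categorical_levels[[fname]]) - 1
        pos <- model$normalization$alpha[i] * codes +
          model$normalization$beta[i]
        e2 <- categorical_to_map(e, codes, pos)
        rows[[length(rows) + 1L]] <-
          data.frame(layer = l, j = j, i = i, stage = "categorical_map",
                     r2 = 1, feature = fname)
      } else {
        e2 <- symbolize_edge(e, A[, i], config)
        rows[[length(rows) + 1L]] <-
          data.frame(layer = l, j = j, i = i, stage = e2$symbolic_fit$stage,
                     r2 = e2$symbolic_fit$r2, feature = fname)
      }
      model$layers[[l]]$edges[[idx]] <- e2
    }
    A <- layer_forward(model$layers[[l]], A)$out
  }
  attr(model, "symbolic_report") <- do.call(rbind, rows)
  model
}

# ---- formula extraction -----------------------------------------------------

#' Extract the closed-form log-partial-hazard formula
#'
#' Composes the per-edge symbolic expressions through the layer structure
#' into a single expression for the estimated log-partial hazard in terms of
#' the raw (un-normalized) input features, folding the input normalization
#' into each first-layer term and constant-folding/simplifying the result.
#' Every retained edge must already be in `symbolic` or `categorical_map`
#' state. When a reference dataset is given, each top-level term's standard
#' deviation over it is reported as a relative-importance score; constant
#' terms (sigma = 0) are dropped from the ranked report.
#'
#' @param model a fully symbolized `kan_model`.
#' @param data optional `survival_dataset` used for term importances.
#' @return an object of class `symbolic_model`: `expr` (full expression),
#'   `terms` (data frame with per-term expression text, provenance, sigma),
#'   `maps` (categorical lookup tables), `feature_names`.
#' @export
extract_formula <- function(model, data = NULL) {
  stopifnot(inherits(model, "kan_model"))
  states <- unlist(lapply(model$layers, function(ly)
    vapply(ly$edges, function(e) e$state, "")))
  if (any(states == "spline"))
    stop("extract_formula requires all retained edges symbolized; ",
         "run symbolize() first")
  maps <- list()
  # expressions feeding each layer; start with normalized raw features
  node_exprs <- lapply(seq_len(model$shape[1L]), function(i) {
    f <- as.name(model$feature_names[i])
    simplify_expr(bquote(.(model$normalization$alpha[i]) * .(f) +
                           .(model$normalization$beta[i])))
  })
  L <- length(model$layers)
  out_terms <- NULL
  for (l in seq_len(L)) {
    ly <- model$layers[[l]]
    new_exprs <- vector("list", ly$n_out)
    term_list <- vector("list", ly$n_out)
    for (j in seq_len(ly$n_out)) {
      parts <- list(); prov <- character(0)
      for (i in seq_len(ly$n_in)) {
        e <- ly$edges[[edge_index(ly, j, i)]]
        if (e$state == "pruned") next
        if (e$state == "categorical_map") {
          fname <- model$feature_names[i]
          maps[[fname]] <- e$category_map
          pe <- as.call(list(as.name("catmap"), as.name(fname), fname))
        } else {
          pe <- symbolic_fit_expr(e$symbolic_fit, node_exprs[[i]])
        }
        parts[[length(parts) + 1L]] <- pe
        prov <- c(prov, sprintf("layer%d.edge(%d,%d)", l, j, i))
      }
      if (length(parts) == 0L) { new_exprs[[j]] <- 0; term_list[[j]] <- NULL }
      else {
        s <- parts[[1L]]
        if (length(parts) > 1L)
          for (pp in parts[-1L]) s <- bquote(.(s) + .(pp))
        new_exprs[[j]] <- simplify_expr(s)
        term_list[[j]] <- list(parts = parts, prov = prov)
      }
    }
    node_exprs <- new_exprs
    out_terms <- term_list
  }
  full <- node_exprs[[1L]]
  terms_df <- NULL
  if (!is.null(out_terms[[1L]])) {
    parts <- out_terms[[1L]]$parts
    prov <- out_terms[[1L]]$prov
    sig <- rep(NA_real_, length(parts))
    if (!is.null(data)) {
      env <- formula_eval_env(data, maps)
      for (t in seq_along(parts)) {
        v <- tryCatch(eval(parts[[t]], env), error = function(e) NA_real_)
        sig[t] <- if (length(v) > 1L) stats::sd(v) else 0
      }
    }
    terms_df <- data.frame(term = vapply(parts, deparse1, ""),
                           provenance = prov, sigma = sig,
                           stringsAsFactors = FALSE)
    if (!is.null(data)) {
      terms_df <- terms_df[order(-terms_df$sigma), ]
      terms_df <- terms_df[is.na(terms_df$sigma) | terms_df$sigma > 0, ]
      rownames(terms_df) <- NULL
    }
  }
  structure(list(expr = full, terms = terms_df, maps = maps,
                 feature_names = model$feature_names),
            class = "symbolic_model")
}

formula_eval_env <- function(data, maps) {
  env <- new.env(parent = asNamespace("survkan"))
  for (i in seq_len(ncol(data$X)))
    assign(colnames(data$X)[i], data$X[, i], envir = env)
  assign("catmap", function(v, name) {
    m <- maps[[name]]
    idx <- match(round(v, 8), round(m$codes, 8))
    if (anyNA(idx)) stop("unseen category code for feature ", name)
    m$values[idx]
  }, envir = env)
  env
}

#' Evaluate a symbolic model on new data
#' @param object a `symbolic_model`.
#' @param newdata a `survival_dataset` or data frame with the raw features.
#' @param ... unused.
#' @return numeric vector of log-partial hazards from the closed-form
#'   expression.
#' @export
predict.symbolic_model <- function(object, newdata, ...) {
  if (!inherits(newdata, "survival_dataset")) {
    X <- as.matrix(newdata)
    newdata <- list(X = X)
  }
  env <- formula_eval_env(newdata, object$maps)
  v <- eval(object$expr, env)
  if (length(v) == 1L) v <- rep(v, nrow(newdata$X))
  v
}

#' Render a symbolic model's formula as LaTeX
#'
#' Straightforward structural translation of the expression tree:
#' divisions become `\frac`, `sqrt`/`abs`/powers use their LaTeX forms,
#' function names are set upright, and feature names are subscripted at
#' underscores. Numeric constants are shown to `digits` significant digits
#' (display only; the stored expression keeps full precision).
#'
#' @param x a `symbolic_model`.
#' @param digits significant digits for displayed constants.
#' @return a single LaTeX string for the log-partial hazard.
#' @export
format_latex <- function(x, digits = 4) {
  stopifnot(inherits(x, "symbolic_model"))
  paste0("\\theta(x) = ", expr_latex(x$expr, digits))
}

expr_latex <- function(e, digits) {
  rec <- function(e) expr_latex(e, digits)
  if (is.numeric(e)) return(format(signif(e, digits)))
  if (is.symbol(e)) {
    s <- as.character(e)
    if (grepl("_", s)) {
      parts <- strsplit(s, "_", fixed = TRUE)[[1L]]
      s <- paste0(parts[1L], "_{", paste(parts[-1L], collapse = "\\_"), "}")
    }
    return(s)
  }
  fn <- as.character(e[[1L]])
  a <- as.list(e)[-1L]
  wrap <- function(s) paste0("\\left(", s, "\\right)")
  switch(fn,
    "+" = paste(rec(a[[1L]]), "+", rec(a[[2L]])),
    "-" = if (length(a) == 1L) paste0("-", rec(a[[1L]]))
          else paste(rec(a[[1L]]), "-", wrap(rec(a[[2L]]))),
    "*" = paste(rec(a[[1L]]), "\\cdot", rec(a[[2L]])),
    "/" = ,
    "pdiv" = paste0("\\frac{", rec(a[[1L]]), "}{", rec(a[[2L]]), "}"),
    "^" = paste0("{", wrap(rec(a[[1L]])), "}^{", rec(a[[2L]]), "}"),
    "(" = wrap(rec(a[[1L]])),
    "sqrt" = ,
    "psqrt" = paste0("\\sqrt{", rec(a[[1L]]), "}"),
    "abs" = paste0("\\left|", rec(a[[1L]]), "\\right|"),
    "exp" = paste0("e^{", rec(a[[1L]]), "}"),
    "log" = ,
    "plog" = paste0("\\log", wrap(rec(a[[1L]]))),
    "catmap" = paste0("\\mathrm{map}_{\\mathrm{",
                      gsub("_", "\\\\_", as.character(a[[2L]])), "}}"),
    # default: \mathrm{fn}(args)
    paste0("\\mathrm{", fn, "}",
           wrap(paste(vapply(a, rec, ""), collapse = ", "))))
}

#' @export
print.symbolic_model <- function(x, ...) {
  cat("log-partial hazard formula:\n  theta(x) =",
      paste(deparse(x$expr, width.cutoff = 72), collapse = "\n    "), "\n")
  if (!is.null(x$terms) && nrow(x$terms) > 0) {
    cat("terms by importance (sigma over reference data):\n")
    print(x$terms, digits = 3)
  }
  invisible(x)
}
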