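test_that("linear fit recovers slope/intercept and rejects pure curvature", {
  x <- seq(-1, 1, length.out = 50)
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(f$c, 2, tolerance = 1e-12)
  expect_equal(f$d, 1, tolerance = 1e-12)
  expect_equal(f$r2, 1)
  expect_true(f$accepted)
  # y = x^2 on a symmetric grid is orthogonal to x: slope ~ 0, rejected
  g <- fit_linear(x, x^2)
  expect_equal(g$c, 0, tolerance = 1e-10)
  expect_lt(g$r2, 0.1)
  expect_false(g$accepted)
  # constant response: the constant, with R2 defined as 1
  h <- fit_linear(x, rep(3.5, 50))
  expect_equal(h$d, 3.5)
  expect_equal(h$r2, 1)
  expect_error(fit_linear(rep(1, 5), 1:5), "distinct")
})

test_that("noisy linear fit matches the normal-equations oracle", {
  set.seed(31)
  x <- runif(80, -2, 2)
  y <- -1.3 * x + 0.4 + rnorm(80, 0, 0.3)
  f <- fit_linear(x, y)
  Xd <- cbind(1, x)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(f$d, beta[1], tolerance = 1e-10)
  expect_equal(f$c, beta[2], tolerance = 1e-10)
})

test_that("operator library recovers exact members and parameters", {
  x <- seq(-1, 1, length.out = 120)
  fs <- fit_operator_library(x, sin(x))
  expect_equal(fs$op, "sin")
  expect_gt(fs$r2, 0.999)
  expect_equal(abs(fs$a * fs$c), 1, tolerance = 0.05)
  # 3 * exp(2x - 1) + 0.5
  fe <- fit_operator_library(x, 3 * exp(2 * x - 1) + 0.5)
  expect_equal(fe$op, "exp")
  expect_gt(fe$r2, 0.9999)
  # parameter recovery up to the exp(b) x c gauge freedom: compare by the
  # reconstructed curve and the (a, d) parameters which are identified
  expect_equal(fe$a, 2, tolerance = 1e-2)
  expect_equal(fe$d, 0.5, tolerance = 1e-2)
  expect_equal(fe$c * exp(fe$b), 3 * exp(-1), tolerance = 1e-2)
  # constant pairs: R2 = 1 with c = 0
  fc <- fit_operator_library(x, rep(2, 120))
  expect_equal(fc$r2, 1)
  expect_equal(fc$c * 0 + fc$d + fc$c * mean(op_library()[[fc$op]]$f(
    fc$a * x + fc$b)), 2, tolerance = 1e-8)
})

test_that("library fit recovers self-generated affine-wrapped targets", {
  ops <- c("sin", "cos", "exp", "tanh", "gaussian", "x2", "abs",
           "sigmoid", "arctan", "x3")
  set.seed(32)
  x <- seq(-1, 1, length.out = 150)
  for (op in ops) {
    a <- runif(1, 0.5, 2.5) * sample(c(-1, 1), 1)
    b <- runif(1, -0.5, 0.5)
    cc <- runif(1, 0.5, 2)
    dd <- runif(1, -1, 1)
    y <- cc * op_library()[[op]]$f(a * x + b) + dd
    fit <- fit_operator_library(x, y)
    yhat <- fit$c * op_library()[[fit$op]]$f(fit$a * x + fit$b) + fit$d
    expect_lt(max(abs(yhat - y)), 1e-2)
  }
})

test_that("genetic search nails linear targets and is seed-deterministic", {
  x <- seq(-1, 1, length.out = 60)
  y <- 1.5 * x - 0.25
  cfg <- gp_config(pop_size = 150, generations = 25, seed = 7,
                   n_restarts = 1)
  g1 <- fit_genetic(x, y, cfg)
  expect_gt(g1$r2, 0.999)
  g2 <- fit_genetic(x, y, cfg)
  expect_identical(deparse(g1$expr), deparse(g2$expr))
})

test_that("genetic search reaches R2 >= 0.99 on x * sin(3x)", {
  x <- seq(-1, 1, length.out = 120)
  y <- x * sin(3 * x)
  g <- fit_genetic(x, y, gp_config(seed = 1))
  expect_gte(g$r2, 0.99)
})

test_that("edge symbolization is progressive and stops at the first accept", {
  # near-linear trained edge -> linear stage only
  e_lin <- kan_edge(kan_spline(), w_b = 1.2, w_s = 0,
                    basis_kind = "identity")
  x <- seq(-1, 1, length.out = 200)
  s1 <- symbolize_edge(e_lin, x)
  expect_identical(s1$symbolic_fit$stage, "linear")
  expect_identical(attr(s1, "stages_tried"), "linear")
  # Gaussian-bump edge: fit a spline to exp(-x^2) first, then symbolize
  sp <- kan_spline(G = 5)
  B <- bspline_basis(x, sp)
  sp$coef <- qr.solve(crossprod(B) + 1e-9 * diag(ncol(B)),
                      crossprod(B, exp(-x^2)))
  e_g <- kan_edge(sp, w_b = 0, w_s = 1)
  s2 <- symbolize_edge(e_g, x)
  expect_true(s2$symbolic_fit$stage %in% c("library", "genetic"))
  expect_false("genetic" %in% attr(s2, "stages_tried") &&
                 !("library" %in% attr(s2, "stages_tried")))
  expect_gte(s2$symbolic_fit$r2, 0.99)
  expect_equal(edge_eval(s2, x), exp(-x^2), tolerance = 0.05)
})

test_that("categorical map reproduces the spline exactly at level codes", {
  set.seed(41)
  sp <- kan_spline(coef = rnorm(8))
  e <- kan_edge(sp, w_b = 1, w_s = 1)
  # binary feature at encoded positions -1, 1
  pos2 <- c(-1, 1)
  m2 <- categorical_to_map(e, 0:1, pos2)
  expect_equal(edge_eval(m2, pos2), edge_eval(e, pos2), tolerance = 1e-12)
  # 5-level feature
  pos5 <- seq(-1, 1, length.out = 5)
  m5 <- categorical_to_map(e, 0:4, pos5)
  expect_equal(edge_eval(m5, pos5), edge_eval(e, pos5), tolerance = 1e-12)
  expect_identical(m5$state, "categorical_map")
})

test_that("full-model symbolization bypasses curve fitting for categoricals", {
  set.seed(42)
  n <- 400
  X <- cbind(grp = sample(0:2, n, TRUE), x2 = runif(n, -1, 1))
  theta <- c(0.5, -0.3, 0.8)[X[, 1] + 1] + X[, 2]
  tte <- rexp(n, 0.01 * exp(theta))
  ds <- survival_dataset(X, tte, rep(1, n),
                         categorical_levels = list(grp = c("a", "b", "c")))
  fit <- train(ds, train_config(shape = c(2, 1), steps = 80, seed = 1))
  sym <- symbolize(fit$model, ds)
  rep_ <- attr(sym, "symbolic_report")
  expect_identical(rep_$stage[rep_$feature == "grp"], "categorical_map")
  # the categorical edge itself is an exact replacement on its level codes
  grp_pre <- fit$model$layers[[1]]$edges[[1]]
  grp_post <- sym$layers[[1]]$edges[[1]]
  pos <- sort(unique(survkan:::normalize_input(fit$model, ds$X)[, 1]))
  expect_equal(edge_eval(grp_post, pos), edge_eval(grp_pre, pos),
               tolerance = 1e-12)
  # the whole model changes only by the continuous edge's fit error
  pre <- kan_forward(fit$model, ds$X)
  post <- kan_forward(sym, ds$X)
  expect_gt(cor(pre, post), 0.99)
})

test_that("extract_formula reproduces an all-linear model as affine terms", {
  m <- kan_model(c(2, 1), basis_kind = "identity", seed = 43,
                 init_scale = 0)
  m$layers[[1]]$edges[[1]]$w_b <- 2
  m$layers[[1]]$edges[[2]]$w_b <- -1
  set.seed(44)
  X <- matrix(runif(600, -1, 1), 300, 2,
              dimnames = list(NULL, c("x1", "x2")))
  ds <- survival_dataset(X, rexp(300), rep(1, 300))
  sym <- symbolize(m, ds)
  sm <- extract_formula(sym, ds)
  pred <- predict(sm, ds)
  expect_equal(pred, kan_forward(m, X), tolerance = 1e-8)
  fit <- lm(pred ~ X)
  expect_equal(unname(coef(fit)[-1]), c(2, -1), tolerance = 1e-6)
})

test_that("term importance sigma matches the uniform-distribution moment", {
  # a pure passthrough term x with x ~ U(-1,1): sigma -> 1/sqrt(3)
  m <- kan_model(c(1, 1), basis_kind = "identity", seed = 45,
                 init_scale = 0)
  set.seed(46)
  X <- matrix(runif(20000, -1, 1), ncol = 1, dimnames = list(NULL, "x1"))
  ds <- survival_dataset(X, rexp(20000), rep(1, 20000))
  sym <- symbolize(m, ds)
  sm <- extract_formula(sym, ds)
  expect_equal(sm$terms$sigma[1], 1 / sqrt(3), tolerance = 0.02)
})

test_that("LaTeX rendering covers the expression grammar", {
  sm <- structure(list(expr = quote(2 * exp(-(x1)^2) + pdiv(sqrt(abs(x2)),
                                                            3.25))),
                  class = "symbolic_model")
  tex <- format_latex(sm)
  expect_match(tex, "^\\\\theta\\(x\\) = ", perl = TRUE)
  expect_match(tex, "e\\^\\{", perl = TRUE)
  expect_match(tex, "\\\\frac\\{\\\\sqrt\\{", perl = TRUE)
  expect_match(tex, "x1")
})

test_that("constant terms are dropped from the ranked importance report", {
  m <- kan_model(c(2, 1), basis_kind = "identity", seed = 47,
                 init_scale = 0)
  m$layers[[1]]$edges[[2]]$w_b <- 0     # edge 2 becomes the constant 0 map
  set.seed(48)
  X <- matrix(runif(400, -1, 1), 200, 2,
              dimnames = list(NULL, c("x1", "x2")))
  ds <- survival_dataset(X, rexp(200), rep(1, 200))
  sm <- extract_formula(symbolize(m, ds), ds)
  expect_false(any(grepl("x2", sm$terms$term)))
})
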