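test_that("B-spline basis is a partition of unity inside the grid", {
  for (k in c(2L, 3L)) for (G in c(3L, 4L, 5L)) {
    sp <- kan_spline(k = k, G = G)
    set.seed(10 * k + G)
    x <- runif(1000, -1, 1)
    B <- bspline_basis(x, sp)
    expect_true(all(B >= 0))
    expect_lt(max(abs(rowSums(B) - 1)), 1e-9)
  }
})

test_that("basis vanishes outside the extended knot support", {
  sp <- kan_spline(k = 3L, G = 5L)
  far <- c(-100, -3, 3, 100)
  expect_equal(max(abs(bspline_basis(far, sp))), 0)
})

test_that("basis matches an independent Cox-de Boor recursion", {
  sp <- kan_spline(k = 3L, G = 5L)
  set.seed(42)
  x <- runif(50, -0.999, 0.999)
  B <- bspline_basis(x, sp)
  for (r in seq_along(x)) {
    expect_equal(B[r, ], oracle_basis_row(x[r], sp$knots, sp$k),
                 tolerance = 1e-10)
  }
})

test_that("malformed knot vectors are rejected", {
  sp <- kan_spline(k = 3L, G = 5L)
  sp$knots[4] <- sp$knots[6]   # break monotonicity
  expect_error(bspline_basis(0.3, sp), "knot")
  expect_error(kan_spline(k = 3, G = 4, coef = 1:3), "coefficients")
})

test_that("spline approximation of sin(3x) improves monotonically with G", {
  target <- function(x) sin(3 * x)
  errs <- vapply(c(5L, 10L, 20L), function(G) {
    sp <- kan_spline(k = 3L, G = G)
    xg <- seq(-1, 1, length.out = 200)
    B <- bspline_basis(xg, sp)
    sp$coef <- qr.solve(crossprod(B) + 1e-10 * diag(ncol(B)),
                        crossprod(B, target(xg)))
    xt <- seq(-1, 1, length.out = 2001)
    max(abs(spline_eval(sp, xt) - target(xt)))
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("edge evaluation covers all four states", {
  sp <- kan_spline(coef = rnorm(8))
  # identity basis passthrough
  e_id <- kan_edge(kan_spline(), w_b = 1, w_s = 0, basis_kind = "identity")
  x <- seq(-2, 2, by = 0.25)
  expect_equal(edge_eval(e_id, x), x)
  # zero edge
  e0 <- kan_edge(sp, w_b = 0, w_s = 0)
  expect_equal(edge_eval(e0, x), rep(0, length(x)))
  # silu + spline equals basis-oracle composition (inside the grid)
  set.seed(7)
  co <- rnorm(8)
  e <- kan_edge(kan_spline(coef = co), w_b = 1, w_s = 1)
  xi <- runif(20, -1, 1)
  expected <- xi / (1 + exp(-xi)) +
    vapply(xi, function(z)
      sum(co * oracle_basis_row(z, kan_spline()$knots, 3L)), 0)
  expect_equal(edge_eval(e, xi), expected, tolerance = 1e-10)
  # pruned edge is identically zero
  ep <- kan_edge(sp); ep$state <- "pruned"
  expect_equal(edge_eval(ep, x), rep(0, length(x)))
  # unseen categorical code errors
  em <- kan_edge(sp); em$state <- "categorical_map"
  em$category_map <- list(codes = 0:1, positions = c(-1, 1), values = c(2, 3))
  expect_equal(edge_eval(em, c(1, -1, 1)), c(3, 2, 3))
  expect_error(edge_eval(em, 0.5), "unseen")
})

test_that("spline-state edges clamp to the grid (flat extrapolation)", {
  set.seed(3)
  e <- kan_edge(kan_spline(coef = rnorm(8)), w_b = 0, w_s = 1)
  expect_equal(edge_eval(e, 5), edge_eval(e, 1))
  expect_equal(edge_eval(e, -5), edge_eval(e, -1))
})

test_that("forward pass: linear identity edges sum the inputs", {
  m <- kan_model(c(2, 1), basis_kind = "identity", seed = 1, init_scale = 0)
  # identity basis, w_b = 1, w_s arbitrary but coef = 0
  X <- cbind(x1 = c(0.1, -0.5, 0.9), x2 = c(0.4, 0.2, -0.3))
  expect_equal(kan_forward(m, X), X[, 1] + X[, 2])
})

test_that("forward pass with every edge pruned is identically zero", {
  m <- kan_model(c(3, 2, 1), seed = 2)
  for (l in seq_along(m$layers))
    for (e in seq_along(m$layers[[l]]$edges))
      m$layers[[l]]$edges[[e]]$state <- "pruned"
  X <- matrix(runif(15, -1, 1), 5, 3)
  expect_equal(kan_forward(m, X), rep(0, 5))
})

test_that("forward pass matches a double-loop reference on a [3,2,1] model", {
  m <- kan_model(c(3, 2, 1), seed = 5, init_scale = 0.5)
  set.seed(6)
  X <- matrix(runif(60, -1, 1), 20, 3)
  expect_equal(kan_forward(m, X), oracle_kan_forward(m, X),
               tolerance = 1e-12)
})

test_that("forward pass rejects width mismatches", {
  m <- kan_model(c(3, 1), seed = 0)
  expect_error(kan_forward(m, matrix(0, 2, 4)), "width")
})

test_that("an all-linear [n,1] model is an affine function of the inputs", {
  m <- kan_model(c(3, 1), basis_kind = "identity", seed = 8, init_scale = 0)
  for (e in seq_along(m$layers[[1]]$edges)) {
    m$layers[[1]]$edges[[e]]$w_b <- rnorm(1)
  }
  set.seed(9)
  X <- matrix(runif(300, -1, 1), 100, 3)
  y <- kan_forward(m, X)
  beta <- qr.solve(cbind(1, X), y)
  expect_lt(max(abs(cbind(1, X) %*% beta - y)), 1e-10)
})

test_that("backpropagated gradients match numerical differentiation", {
  fm <- hazard_formula(quote(x1 - x2^2), c("x1", "x2"), n_noise = 1)
  ds <- simulate_survival(fm, 60, seed = 11)
  m <- kan_model(c(3, 2, 1), seed = 12)
  m <- kan_set_normalization(m, ds$X)
  lg <- survkan:::total_loss_grad(m, ds, lambda = 0.05, lambda_ent = 2,
                                  lambda_coef = 0.5)
  par <- survkan:::kan_get_params(m)
  idx <- round(seq(1, length(par), length.out = 15))
  h <- 1e-6
  for (i in idx) {
    pp <- par; pp[i] <- pp[i] + h
    pm <- par; pm[i] <- pm[i] - h
    f1 <- total_loss(survkan:::kan_set_params(m, pp), ds, 0.05, 2, 0.5)
    f2 <- total_loss(survkan:::kan_set_params(m, pm), ds, 0.05, 2, 0.5)
    expect_equal(lg$grad[i], (f1 - f2) / (2 * h), tolerance = 1e-4)
  }
})
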