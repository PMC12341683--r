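test_that("activation L1 equals the mean absolute activation", {
  sp <- kan_spline(coef = rnorm(8))
  e0 <- kan_edge(sp, w_b = 0, w_s = 0)
  expect_equal(activation_l1(e0, c(1, -1, 0.3)), 0)
  eid <- kan_edge(kan_spline(), w_b = 1, w_s = 0, basis_kind = "identity")
  expect_equal(activation_l1(eid, c(1, -1)), 1)
  set.seed(5)
  e <- kan_edge(kan_spline(coef = rnorm(8)), w_b = 0.7, w_s = -1.2)
  x <- runif(40, -1, 1)
  expect_equal(activation_l1(e, x), mean(abs(edge_eval(e, x))),
               tolerance = 1e-12)
  expect_error(activation_l1(e, numeric(0)), "non-empty")
})

test_that("layer entropy: degenerate, uniform, and formula oracle", {
  mk_layer <- function(w) {
    # identity-basis edges with controllable magnitude -> |phi|_1 = |w|/2
    # on a symmetric batch
    edges <- lapply(w, function(wi)
      kan_edge(kan_spline(), w_b = wi, w_s = 0, basis_kind = "identity"))
    kan_layer(2, length(w) / 2, edges)
  }
  X <- cbind(c(-1, 1), c(-1, 1))
  expect_equal(layer_entropy(mk_layer(c(3, 0)), X), 0)
  expect_equal(layer_entropy(mk_layer(c(2, 2)), X), log(2))
  expect_equal(layer_entropy(mk_layer(c(1, 1, 1, 1)), X), log(4))
  # random norms against the direct formula
  set.seed(11)
  w <- runif(4, 0.1, 3)
  l1 <- abs(w) * 1        # batch {-1, 1}: mean |w * x| = |w|
  p <- l1 / sum(l1)
  expect_equal(layer_entropy(mk_layer(w), X), -sum(p * log(p)),
               tolerance = 1e-12)
})

test_that("entropy is bounded by log(n_edges) over random layers", {
  set.seed(12)
  for (rep in 1:300) {
    n_in <- sample(1:3, 1); n_out <- sample(1:3, 1)
    edges <- replicate(n_in * n_out,
                       kan_edge(kan_spline(G = 3, coef = rnorm(6, 0, 1)),
                                w_b = rnorm(1), w_s = rnorm(1)),
                       simplify = FALSE)
    ly <- kan_layer(n_in, n_out, edges)
    X <- matrix(runif(10 * n_in, -1, 1), 10, n_in)
    S <- layer_entropy(ly, X)
    expect_gte(S, 0)
    expect_lte(S, log(n_in * n_out) + 1e-12)
  }
})

test_that("total regularizer decomposes into its terms", {
  m <- kan_model(c(3, 2, 1), seed = 13, init_scale = 0.4)
  set.seed(14)
  X <- matrix(runif(60, -1, 1), 20, 3)
  le <- 0.7; lc <- 0.3
  # independent per-term computation through the public pieces
  A <- survkan:::normalize_input(m, X)
  expected <- 0
  for (l in seq_along(m$layers)) {
    ly <- m$layers[[l]]
    l1s <- vapply(seq_along(ly$edges), function(idx) {
      i <- (idx - 1) %% ly$n_in + 1
      activation_l1(ly$edges[[idx]], A[, i])
    }, 0)
    # note: edge index (j,i) = (j-1)*n_in + i, so column i = (idx-1) %% n_in + 1
    p <- l1s / sum(l1s)
    ent <- -sum(ifelse(p > 0, p * log(p), 0))
    coefs <- sum(vapply(ly$edges, function(e) mean(abs(e$spline$coef)), 0))
    expected <- expected + sum(l1s) + le * ent + lc * coefs
    A <- survkan:::layer_forward(ly, A)$out
  }
  expect_equal(as.numeric(regularization_total(m, X, le, lc)), expected,
               tolerance = 1e-10)
})

test_that("all-zero network has zero regularizer", {
  m <- kan_model(c(2, 1), seed = 15, init_scale = 0)
  for (e in seq_along(m$layers[[1]]$edges)) {
    m$layers[[1]]$edges[[e]]$w_b <- 0
    m$layers[[1]]$edges[[e]]$w_s <- 0
  }
  X <- matrix(runif(20, -1, 1), 10, 2)
  expect_equal(as.numeric(regularization_total(m, X)), 0)
})

test_that("total loss reduces to the fast Cox loss at lambda = 0 and is additive", {
  fm <- hazard_formula(quote(x1), "x1", n_noise = 1)
  ds <- simulate_survival(fm, 100, seed = 16)
  m <- kan_model(c(2, 1), seed = 17)
  m <- kan_set_normalization(m, ds$X)
  theta <- kan_forward(m, ds$X)
  expect_equal(total_loss(m, ds, lambda = 0),
               cox_loss_fast(theta, ds$time, ds$event))
  lam <- 0.3
  expect_equal(total_loss(m, ds, lam, 2, 0.5),
               cox_loss_fast(theta, ds$time, ds$event) +
                 lam * as.numeric(regularization_total(m, ds$X, 2, 0.5)),
               tolerance = 1e-12)
})

test_that("pruning: identity at zero threshold, error above the maximum", {
  fm <- builtin_formula("mixed")
  ds <- simulate_survival(fm, 300, seed = 18)
  m <- kan_model(c(5, 1), seed = 19, init_scale = 0.3)
  m <- kan_set_normalization(m, ds$X)
  p0 <- prune(m, ds, 0)
  expect_equal(kan_forward(p0, ds$X), kan_forward(m, ds$X))
  expect_equal(attr(p0, "n_pruned"), 0L)
  expect_error(prune(m, ds, 1e6), "output path")
})

test_that("pruning is idempotent and subtracts exactly the pruned edges", {
  fm <- builtin_formula("mixed")
  ds <- simulate_survival(fm, 300, seed = 20)
  m <- kan_model(c(5, 2, 1), seed = 21, init_scale = 0.3)
  m <- kan_set_normalization(m, ds$X)
  l1 <- unlist(survkan:::model_edge_l1(m, ds$X))
  tau <- stats::median(l1)
  p1 <- prune(m, ds, tau)
  p2 <- prune(p1, ds, tau)
  s1 <- unlist(lapply(p1$layers, function(ly)
    vapply(ly$edges, function(e) e$state, "")))
  s2 <- unlist(lapply(p2$layers, function(ly)
    vapply(ly$edges, function(e) e$state, "")))
  expect_identical(s1, s2)
  # removed-contribution bookkeeping on a single-layer model
  m1 <- kan_model(c(5, 1), seed = 22, init_scale = 0.3)
  m1 <- kan_set_normalization(m1, ds$X)
  l1s <- survkan:::model_edge_l1(m1, ds$X)[[1]]
  tau1 <- sort(l1s)[3]            # prune the two weakest edges
  pr <- prune(m1, ds, tau1)
  A <- survkan:::normalize_input(m1, ds$X)
  removed <- which(l1s < tau1)
  contrib <- rowSums(vapply(removed, function(i)
    edge_eval(m1$layers[[1]]$edges[[i]], A[, i]), numeric(nrow(A))))
  expect_equal(kan_forward(pr, ds$X), kan_forward(m1, ds$X) - contrib,
               tolerance = 1e-12)
})

test_that("cascading node removal drops orphaned hidden nodes", {
  m <- kan_model(c(2, 2, 1), seed = 23, init_scale = 0.3)
  # manually sever all incoming edges of hidden node 1
  m$layers[[1]]$edges[[1]]$state <- "pruned"   # (j=1, i=1)
  m$layers[[1]]$edges[[2]]$state <- "pruned"   # (j=1, i=2)
  ds <- simulate_survival(hazard_formula(quote(x1 + x2), c("x1", "x2"),
                                         n_noise = 0), 100, seed = 24)
  pr <- prune(m, ds, 1e-9)
  # outgoing edge of hidden node 1 in layer 2 must now also be pruned
  expect_identical(pr$layers[[2]]$edges[[1]]$state, "pruned")
})
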