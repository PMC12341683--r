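test_that("exact Cox loss reproduces closed forms under uniform risk", {
  # three distinct event times, theta = 0: log 3 + log 2 + log 1
  expect_equal(cox_loss_exact(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1)),
               log(3) + log(2))
  # single earliest event among N subjects at theta = 0: log N
  N <- 7
  expect_equal(cox_loss_exact(rep(0, N), seq_len(N), c(1, rep(0, N - 1))),
               log(N))
})

test_that("exact Cox loss matches risk-set enumeration with ties", {
  for (s in 1:20) {
    set.seed(s)
    n <- 12
    theta <- rnorm(n)
    t <- sample(1:5, n, replace = TRUE)     # heavy ties
    d <- rbinom(n, 1, 0.7); d[1] <- 1
    expect_equal(cox_loss_exact(theta, t, d), oracle_cox_exact(theta, t, d),
                 tolerance = 1e-12)
  }
})

test_that("zero events is an explicit error", {
  expect_error(cox_loss_exact(rnorm(4), 1:4, rep(0, 4)), "no events")
  expect_error(cox_loss_fast(rnorm(4), 1:4, rep(0, 4)), "no events")
})

test_that("fast loss equals exact loss on tie-free data", {
  for (s in 1:100) {
    b <- rand_surv(200, seed = s)
    b$d[1] <- 1
    expect_equal(cox_loss_fast(b$theta, b$t, b$d),
                 cox_loss_exact(b$theta, b$t, b$d), tolerance = 1e-10)
  }
})

test_that("fast loss follows the documented prefix rule under ties", {
  for (s in 1:20) {
    set.seed(s)
    n <- 15
    theta <- rnorm(n)
    t <- sample(1:4, n, replace = TRUE)
    d <- rbinom(n, 1, 0.6); d[1] <- 1
    expect_equal(cox_loss_fast(theta, t, d), oracle_cox_fast(theta, t, d),
                 tolerance = 1e-12)
  }
})

test_that("both losses are invariant to shifting theta by a constant", {
  b <- rand_surv(100, seed = 33); b$d[1] <- 1
  for (cc in c(-5, 1e-3, 17)) {
    expect_equal(cox_loss_exact(b$theta + cc, b$t, b$d),
                 cox_loss_exact(b$theta, b$t, b$d), tolerance = 1e-9)
    expect_equal(cox_loss_fast(b$theta + cc, b$t, b$d),
                 cox_loss_fast(b$theta, b$t, b$d), tolerance = 1e-9)
  }
})

test_that("fast-loss analytic gradient matches numerical differentiation", {
  b <- rand_surv(30, seed = 4); b$d[1] <- 1
  g <- survkan:::cox_loss_fast_grad(b$theta, b$t, b$d)
  h <- 1e-6
  for (i in seq_len(30)) {
    tp <- b$theta; tp[i] <- tp[i] + h
    tm <- b$theta; tm[i] <- tm[i] - h
    expect_equal(g[i], (cox_loss_fast(tp, b$t, b$d) -
                          cox_loss_fast(tm, b$t, b$d)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("concordance index: perfect ranking, all ties, pair oracle", {
  t <- sort(runif(20)); d <- rep(1, 20)
  expect_equal(concordance_index(rev(seq_len(20)), t, d), 1.0)
  expect_equal(concordance_index(rep(0, 20), t, d), 0.5)
  for (s in 1:200) {
    set.seed(1000 + s)
    n <- sample(5:20, 1)
    theta <- rnorm(n)
    t <- runif(n)
    d <- rbinom(n, 1, 0.6); d[which.min(t)] <- 1
    expect_equal(concordance_index(theta, t, d), oracle_cindex(theta, t, d),
                 tolerance = 1e-12)
  }
})

test_that("concordance is invariant under strictly increasing transforms", {
  b <- rand_surv(80, seed = 9); b$d[1] <- 1
  c0 <- concordance_index(b$theta, b$t, b$d)
  expect_equal(concordance_index(exp(b$theta), b$t, b$d), c0)
  expect_equal(concordance_index(5 * b$theta - 2, b$t, b$d), c0)
  expect_equal(concordance_index(atan(b$theta), b$t, b$d), c0)
})

test_that("concordance errors without admissible pairs", {
  expect_error(concordance_index(c(1, 2), c(1, 2), c(0, 0)), "admissible")
})

test_that("bootstrap C-index interval behaves at the extremes", {
  t <- sort(runif(30)); d <- rep(1, 30)
  res <- bootstrap_cindex(rev(seq_len(30)), t, d, n_bootstrap = 50, seed = 1)
  expect_equal(res$ci_low, 1.0)
  expect_equal(res$ci_high, 1.0)
  b <- rand_surv(40, seed = 2); b$d[1] <- 1
  one <- bootstrap_cindex(b$theta, b$t, b$d, n_bootstrap = 1, seed = 3)
  expect_equal(one$ci_low, one$ci_high)
  expect_lte(one$ci_low, max(one$estimate, one$ci_high))
  # determinism under seed
  r1 <- bootstrap_cindex(b$theta, b$t, b$d, n_bootstrap = 20, seed = 5)
  r2 <- bootstrap_cindex(b$theta, b$t, b$d, n_bootstrap = 20, seed = 5)
  expect_identical(r1$ci_low, r2$ci_low)
  expect_true(r1$ci_low <= r1$estimate && r1$estimate <= r1$ci_high)
})

test_that("linear Cox fit recovers null and non-null truth", {
  # null data: no association
  f0 <- hazard_formula(quote(0 * x1), c("x1"), n_noise = 1)
  d0 <- simulate_survival(f0, 800, seed = 21)
  fit0 <- fit_coxph(d0)
  expect_true(all(abs(fit0$beta) < 3 * fit0$se))
  # beta = (1.0, -0.5) recovery at n = 5000
  f1 <- hazard_formula(quote(1.0 * x1 - 0.5 * x2), c("x1", "x2"),
                       n_noise = 0)
  d1 <- simulate_survival(f1, 5000, seed = 22)
  fit1 <- fit_coxph(d1)
  expect_equal(unname(fit1$beta), c(1.0, -0.5), tolerance = 0.1)
})

test_that("heavy Lasso drives all coefficients to zero and C to 0.5", {
  f <- hazard_formula(quote(1.0 * x1 - 0.5 * x2), c("x1", "x2"))
  d <- simulate_survival(f, 1000, seed = 23)
  fit <- fit_coxph(d, l1_penalty = 5)
  expect_true(all(fit$beta == 0))
  expect_equal(concordance_index(predict(fit, d) + seq_len(1000) * 1e-12,
                                 d$time, d$event), 0.5, tolerance = 0.05)
})

test_that("radially symmetric hazard leaves the linear model at chance", {
  fm <- builtin_formula("gaussian")
  d <- simulate_survival(fm, 4000, seed = 24)
  dt <- simulate_survival(fm, 4000, seed = 25)
  fit <- fit_coxph(d)
  cc <- concordance_index(predict(fit, dt), dt$time, dt$event)
  expect_equal(cc, 0.5, tolerance = 0.02)
})
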