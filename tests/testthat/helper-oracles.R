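# Independent reference implementations used as oracles. These are written
# directly from the defining formulas (recursions, enumerations) and share no
# code with the package internals.

# Cox-de Boor recursion, one basis function B_{i,k}(x) at a time
oracle_bspline <- function(x, knots, i, k) {
  if (k == 0) {
    return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  }
  left <- 0
  if (knots[i + k] != knots[i])
    left <- (x - knots[i]) / (knots[i + k] - knots[i]) *
      oracle_bspline(x, knots, i, k - 1)
  right <- 0
  if (knots[i + k + 1] != knots[i + 1])
    right <- (knots[i + k + 1] - x) / (knots[i + k + 1] - knots[i + 1]) *
      oracle_bspline(x, knots, i + 1, k - 1)
  left + right
}

oracle_basis_row <- function(x, knots, k) {
  n_basis <- length(knots) - k - 1
  vapply(seq_len(n_basis), function(i) oracle_bspline(x, knots, i, k), 0)
}

# risk-set enumeration of the exact negative partial log-likelihood (Breslow)
oracle_cox_exact <- function(theta, t, d) {
  s <- 0
  for (i in which(d == 1)) {
    R <- which(t >= t[i])
    s <- s - (theta[i] - log(sum(exp(theta[R]))))
  }
  s
}

# explicit-loop version of the sorted-prefix fast loss (same tie convention:
# descending time, events before censored at equal times)
oracle_cox_fast <- function(theta, t, d) {
  ord <- order(-t, -d)
  th <- theta[ord]; ev <- d[ord]
  s <- 0
  for (i in seq_along(th)) {
    if (ev[i] == 1) s <- s - (th[i] - log(sum(exp(th[1:i]))))
  }
  s
}

# exhaustive O(n^2) pair enumeration of Harrell's C
oracle_cindex <- function(theta, t, d) {
  num <- 0; den <- 0
  n <- length(theta)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (t[i] < t[j] && d[i] == 1) {
      den <- den + 1
      if (theta[i] > theta[j]) num <- num + 1
      else if (theta[i] == theta[j]) num <- num + 0.5
    }
  }
  num / den
}

# double-loop reference forward pass for a KAN: sums edge_eval over inputs,
# layer by layer, without any matrix bookkeeping
oracle_kan_forward <- function(model, X) {
  A <- survkan:::normalize_input(model, as.matrix(X))
  for (ly in model$layers) {
    out <- matrix(0, nrow(A), ly$n_out)
    for (j in seq_len(ly$n_out)) for (i in seq_len(ly$n_in)) {
      e <- ly$edges[[(j - 1) * ly$n_in + i]]
      if (e$state == "pruned") next
      out[, j] <- out[, j] + edge_eval(e, A[, i])
    }
    A <- out
  }
  drop(A)
}

# quick random survival batch with continuous (tie-free) durations
rand_surv <- function(n, seed, p_event = 0.7) {
  set.seed(seed)
  list(theta = rnorm(n), t = runif(n, 0.1, 10),
       d = rbinom(n, 1, p_event))
}
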