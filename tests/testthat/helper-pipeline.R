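# Shared synthetic benchmark runs, computed once per test session.
# Conditions: n = 10000 train / 10000 test, default training configuration,
# shapes matched to each family's structure (hidden layer only where the
# truth composes univariate functions of a sum).
.bench_cache <- new.env(parent = emptyenv())

bench_shape <- function(name) {
  switch(name,
         gaussian = c(4L, 1L, 1L),
         mixed = c(5L, 1L),
         euclidean = c(5L, 1L, 1L),
         complex = c(6L, 1L))
}

bench_run <- function(name, n = 10000L) {
  key <- paste0(name, "_", n)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  fm <- builtin_formula(name)
  d_train <- simulate_survival(fm, n, seed = 1)
  d_test <- simulate_survival(fm, n, seed = 2)
  cox <- fit_coxph(d_train)
  cox_c <- concordance_index(predict(cox, d_test), d_test$time,
                             d_test$event)
  true_c <- concordance_index(attr(d_test, "true_theta"),
                              d_test$time, d_test$event)
  pl <- kan_survival_pipeline(
    d_train, train_config(shape = bench_shape(name), seed = 1),
    test_data = d_test)
  res <- list(train = d_train, test = d_test, cox_c = cox_c,
              true_c = true_c, pipeline = pl)
  .bench_cache[[key]] <- res
  res
}
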