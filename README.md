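# survkan

Interpretable survival regression with Kolmogorov-Arnold networks (KANs).

## The problem

Survival analysis models the time to an event (death, relapse, failure)
from right-censored data: each subject contributes covariates $x$, an
observed duration $t$, and an event indicator $\delta \in \{0, 1\}$. The
workhorse Cox proportional-hazards model,

$$h(t, x) = h_0(t)\, e^{\theta(x)}, \qquad \theta^{\mathrm{CPH}}(x) = \beta^\top x,$$

is interpretable but linear; deep survival networks are flexible but
opaque. `survkan` replaces the linear predictor with a Kolmogorov-Arnold
network — a network whose *edges* carry learnable univariate B-spline
activations $\phi(x) = w_b\, b(x) + w_s \sum_i c_i B_{i,k}(x)$, summed at
the nodes — so the fitted risk score $\theta(x) = \mathrm{KAN}(x)$ is both
flexible and, after distillation, an explicit formula a practitioner can
read and audit.

The package provides, for biostatisticians and methodologists working with
tabular survival data:

* the negative Cox partial log-likelihood, exact (Breslow ties) and in a
  fast $O(n \log n)$ sorted-prefix approximation used for training;
* full-batch Adam training with event-stratified validation splits, early
  stopping on the validation C-index, and sparsity regularization
  (activation L1 + layer entropy + spline-coefficient L1);
* activation pruning with validation-selected thresholds — automatic
  feature selection;
* progressive symbolic distillation of each surviving activation: linear
  fit, affine-wrapped operator library (22 candidates), then genetic
  symbolic regression, yielding a closed-form $\hat\theta(x)$ with
  per-term importance scores;
* Harrell's C-index with bootstrap confidence intervals, a linear Cox
  baseline (optionally Lasso via glmnet);
* a proportional-hazards simulator (constant baseline hazard, uniform
  censoring, appended noise covariates) with four built-in benchmark
  hazard families;
* CSV-based survival-data loading, label encoding, univariate Cox
  screening, correlated-feature consolidation, and median/mode imputation
  for high-dimensional tables.

## Worked example

```r
library(survkan)

# simulate: theta(x) = 2 exp(-(x1^2 + x2^2)), h0 = 0.01, ~30% censoring,
# two irrelevant covariates appended
fm <- builtin_formula("gaussian")
d_train <- simulate_survival(fm, 10000, seed = 1)
d_test  <- simulate_survival(fm, 10000, seed = 2)

# linear baseline is blind to the radially symmetric signal
cox <- fit_coxph(d_train)
concordance_index(predict(cox, d_test), d_test$time, d_test$event)
#> [1] 0.4976542

# ceiling: the generating formula itself
concordance_index(attr(d_test, "true_theta"), d_test$time, d_test$event)
#> [1] 0.6175825

# train -> prune -> symbolize
pl <- kan_survival_pipeline(d_train,
                            train_config(shape = c(4, 1, 1), seed = 1),
                            test_data = d_test)
round(pl$metrics, 4)
#>  trained   pruned symbolic
#>   0.6167   0.6167   0.6170
pl$deselected
#> [1] "eps1" "eps2"
```

The linear model scores 0.498 (chance — the hazard is symmetric in every
covariate, so no linear score can rank subjects), while the network
reaches 0.617, within 0.001 of the best possible 0.618 attained by the
true formula on the same test set. Pruning removed exactly the two noise
covariates, and `pl$formula` holds the distilled closed-form risk score
with per-term importance (standard deviation over the training set).

Models serialize to JSON (`save_kan()` / `load_kan()`) with bit-exact
round-trip. A thin command-line front end with `simulate`, `train`,
`prune`, `symbolize`, and `preprocess` subcommands is installed at
`inst/cli/survkan.R`.

See the vignette (`vignettes/kan-survival-methods.Rmd`) for the model,
the fast-loss approximation, the pruning and distillation rules, what the
simulator does and does not emulate, and known limitations.

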