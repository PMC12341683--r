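#' Load tabular survival data from CSV
#'
#' Parses one row per subject, label-encodes the declared categorical
#' columns (levels sorted, codes 0, 1, ...), and checks the survival
#' columns: durations must be non-negative reals and events must be exactly
#' 0 or 1, with row-indexed errors otherwise. Missing covariate values are
#' tolerated at this stage (impute with [impute_missing()] before
#' modelling); missingness is reported in the `"missingness"` attribute.
#'
#' @param path CSV file path.
#' @param duration_col,event_col column names of duration and event
#'   indicator.
#' @param categorical_cols character vector of categorical column names.
#' @return a `survival_dataset` (with `NA`s allowed in `X` until imputation).
#' @export
load_survival_csv <- function(path, duration_col = "duration",
                              event_col = "event",
                              categorical_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in c(duration_col, event_col))
    if (!cl %in% names(df)) stop("required column missing: ", cl)
  time <- suppressWarnings(as.numeric(df[[duration_col]]))
  bad <- which(is.na(time) | time < 0)
  if (length(bad))
    stop("bad duration at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  event <- suppressWarnings(as.numeric(df[[event_col]]))
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad))
    stop("event indicator must be 0 or 1; bad row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  feat <- setdiff(names(df), c(duration_col, event_col))
  X <- matrix(NA_real_, nrow(df), length(feat),
              dimnames = list(NULL, feat))
  levels_map <- list()
  for (j in seq_along(feat)) {
    col <- df[[feat[j]]]
    if (feat[j] %in% categorical_cols || is.character(col) ||
        is.factor(col)) {
      lv <- sort(unique(as.character(col[!is.na(col)])))
      levels_map[[feat[j]]] <- lv
      X[, j] <- match(as.character(col), lv) - 1
    } else {
      v <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(v) & !is.na(col) & col != "")
      if (length(bad))
        stop("unparseable numeric cell(s) in '", feat[j], "' at row(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
      X[, j] <- v
    }
  }
  miss <- colSums(is.na(X))
  ds <- new_survival_dataset_allow_na(X, time, event, feat, levels_map)
  attr(ds, "missingness") <- miss
  ds
}

# internal constructor that permits NAs (pre-imputation)
new_survival_dataset_allow_na <- function(X, time, event, feature_names,
                                          categorical_levels) {
  structure(list(X = X, time = time, event = event,
                 feature_names = feature_names,
                 categorical_levels = categorical_levels),
            class = "survival_dataset")
}

#' Impute missing covariate values
#'
#' Deterministic single imputation: per-feature median for numeric columns
#' and mode (most frequent level, ties to the lowest code) for categorical
#' columns. The imputed-cell mask is kept in the `"imputed_mask"` attribute.
#'
#' @param data a `survival_dataset` (possibly with `NA`s in `X`).
#' @param strategy currently `"median_mode"`.
#' @return the completed `survival_dataset`.
#' @export
impute_missing <- function(data, strategy = "median_mode") {
  stopifnot(strategy == "median_mode")
  X <- data$X
  mask <- is.na(X)
  if (any(mask)) {
    for (j in seq_len(ncol(X))) {
      mj <- is.na(X[, j])
      if (!any(mj)) next
      if (all(mj)) stop("feature '", colnames(X)[j], "' entirely missing")
      fill <- if (colnames(X)[j] %in% names(data$categorical_levels)) {
        tab <- table(X[!mj, j])
        as.numeric(names(tab)[which.max(tab)])
      } else stats::median(X[!mj, j])
      X[mj, j] <- fill
    }
  }
  out <- survival_dataset(X, data$time, data$event, data$feature_names,
                          data$categorical_levels)
  attr(out, "imputed_mask") <- mask
  out
}

#' Univariate Cox screening of features
#'
#' Fits a one-covariate Cox model per feature and retains those with Wald
#' p-value `<= alpha` -- the standard first-pass filter for
#' high-dimensional (e.g. genomics) survival data. Constant features are
#' skipped with a warning.
#'
#' @param data a `survival_dataset`.
#' @param alpha significance threshold.
#' @return character vector of retained feature names; the full table
#'   (feature, beta, se, p) is in the `"table"` attribute.
#' @export
univariate_screen <- function(data, alpha) {
  stopifnot(inherits(data, "survival_dataset"), sum(data$event) > 0)
  if (missing(alpha)) stop("alpha must be given explicitly")
  res <- lapply(seq_len(ncol(data$X)), function(j) {
    x <- data$X[, j]
    if (stats::var(x) == 0) {
      warning("skipping constant feature: ", data$feature_names[j])
      return(data.frame(feature = data$feature_names[j], beta = NA_real_,
                        se = NA_real_, p = NA_real_))
    }
    fit <- survival::coxph(survival::Surv(data$time, data$event) ~ x,
                           ties = "breslow")
    s <- summary(fit)
    data.frame(feature = data$feature_names[j],
               beta = unname(stats::coef(fit)),
               se = s$coefficients[1, "se(coef)"],
               p = s$coefficients[1, "Pr(>|z|)"])
  })
  tab <- do.call(rbind, res)
  keep <- tab$feature[!is.na(tab$p) & tab$p <= alpha]
  attr(keep, "table") <- tab
  keep
}

#' Consolidate groups of highly correlated features
#'
#' Builds the graph whose edges join feature pairs with `|Pearson r| >=
#' r_threshold`, finds its connected components, and replaces every
#' multi-feature component by a single column: the element-wise median of
#' the group. Consolidated columns are named `grp1`, `grp2`, ... and their
#' source features are recorded in the `"groups"` attribute. This tames
#' multicollinearity (e.g. copy-number segments moving together) before
#' model fitting.
#'
#' @param data a `survival_dataset` with numeric features.
#' @param r_threshold absolute-correlation threshold; values above 1 leave
#'   the data unchanged.
#' @return the consolidated `survival_dataset`.
#' @export
consolidate_correlated <- function(data, r_threshold) {
  stopifnot(inherits(data, "survival_dataset"))
  if (missing(r_threshold)) stop("r_threshold must be given explicitly")
  p <- ncol(data$X)
  if (p < 2L || r_threshold > 1) {
    attr(data, "groups") <- list()
    return(data)
  }
  sds <- apply(data$X, 2, stats::sd)
  R <- suppressWarnings(abs(stats::cor(data$X)))
  R[is.na(R)] <- 0
  adj <- R >= r_threshold
  diag(adj) <- FALSE
  comp <- rep(0L, p); cid <- 0L
  for (v in seq_len(p)) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      if (comp[u] != 0L) next
      comp[u] <- cid
      queue <- c(queue, which(adj[u, ] & comp == 0L))
    }
  }
  groups <- split(seq_len(p), comp)
  keep_cols <- list(); names_out <- character(0); grp_meta <- list()
  g_counter <- 0L
  for (g in groups) {
    if (length(g) == 1L) {
      keep_cols[[length(keep_cols) + 1L]] <- data$X[, g]
      names_out <- c(names_out, data$feature_names[g])
    } else {
      g_counter <- g_counter + 1L
      nm <- paste0("grp", g_counter)
      keep_cols[[length(keep_cols) + 1L]] <-
        apply(data$X[, g, drop = FALSE], 1, stats::median)
      names_out <- c(names_out, nm)
      grp_meta[[nm]] <- data$feature_names[g]
    }
  }
  X <- do.call(cbind, keep_cols)
  colnames(X) <- names_out
  out <- survival_dataset(X, data$time, data$event, names_out,
                          data$categorical_levels[
                            names(data$categorical_levels) %in% names_out])
  attr(out, "groups") <- grp_meta
  invisible(sds)
  out
}

#' Event- and duration-stratified train/test split
#'
#' Splits subjects into train and test sets stratified jointly on the event
#' indicator and the duration quartile, so both parts see similar censoring
#' and follow-up distributions.
#'
#' @param data a `survival_dataset`.
#' @param test_fraction fraction assigned to the test set.
#' @param seed RNG seed.
#' @return list with `train` and `test` `survival_dataset`s.
#' @export
stratified_split <- function(data, test_fraction = 0.2, seed = 0L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  q <- stats::quantile(data$time, c(0.25, 0.5, 0.75))
  bin <- findInterval(data$time, q)
  strata <- interaction(data$event, bin, drop = TRUE)
  test_idx <- unlist(lapply(split(seq_along(strata), strata), function(idx) {
    k <- round(length(idx) * test_fraction)
    if (k > 0) sample(idx, k) else integer(0)
  }))
  list(train = sd_subset(data, setdiff(seq_len(nrow(data$X)), test_idx)),
       test = sd_subset(data, sort(test_idx)))
}
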