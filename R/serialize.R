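#' Save a KAN model checkpoint as JSON
#'
#' Serializes the full model -- shape, normalization, and for every edge its
#' state, weights, spline knots/coefficients, symbolic fit or categorical
#' map -- at full floating-point precision, so that a save/load round trip
#' reproduces the model bit-exactly.
#'
#' @param model a `kan_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_kan <- function(model, path) {
  ser_fit <- function(fit) {
    if (is.null(fit)) return(NULL)
    out <- list(op = fit$op, a = fit$a, b = fit$b, c = fit$c, d = fit$d,
                r2 = fit$r2, stage = fit$stage, x_range = fit$x_range,
                accepted = fit$accepted, warn = fit$warn)
    if (fit$stage == "genetic") out$tree <- fit$tree
    out
  }
  obj <- list(
    format = "survkan-model", version = 1L,
    shape = model$shape, feature_names = model$feature_names,
    normalization = model$normalization,
    G = model$G, k = model$k, basis_kind = model$basis_kind,
    hidden_range = model$hidden_range,
    layers = lapply(model$layers, function(ly) {
      list(n_in = ly$n_in, n_out = ly$n_out,
           edges = lapply(ly$edges, function(e) {
             list(state = e$state, w_b = e$w_b, w_s = e$w_s,
                  basis_kind = e$basis_kind,
                  spline = list(k = e$spline$k, G = e$spline$G,
                                lo = e$spline$lo, hi = e$spline$hi,
                                coef = e$spline$coef),
                  symbolic_fit = ser_fit(e$symbolic_fit),
                  category_map = e$category_map)
           }))
    }))
  # I(17) = 17 significant digits: doubles round-trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a KAN model checkpoint from JSON
#' @param path file written by [save_kan()].
#' @return the reconstructed `kan_model`.
#' @export
load_kan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "survkan-model"))
    stop("not a survkan model checkpoint: ", path)
  num <- function(x) as.numeric(unlist(x))
  de_tree <- function(nd) {
    nd$type <- as.character(nd$type)
    if (nd$type == "const") nd$value <- as.numeric(nd$value)
    if (nd$type == "bin") { nd$l <- de_tree(nd$l); nd$r <- de_tree(nd$r) }
    if (nd$type == "un") nd$a <- de_tree(nd$a)
    nd
  }
  de_fit <- function(f) {
    if (is.null(f)) return(NULL)
    fit <- new_symbolic_fit(
      op = if (is.null(f$op)) NA_character_ else as.character(f$op),
      a = as.numeric(f$a %||% NA), b = as.numeric(f$b %||% NA),
      c = as.numeric(f$c %||% NA), d = as.numeric(f$d %||% NA),
      r2 = as.numeric(f$r2), stage = as.character(f$stage),
      x_range = num(f$x_range),
      accepted = isTRUE(f$accepted), warn = isTRUE(f$warn))
    if (fit$stage == "genetic") {
      fit$tree <- de_tree(f$tree)
      fit$expr <- simplify_expr(gp_tree_to_expr(fit$tree))
    }
    fit
  }
  layers <- lapply(obj$layers, function(lyo) {
    edges <- lapply(lyo$edges, function(eo) {
      sp <- kan_spline(k = eo$spline$k, G = eo$spline$G, lo = eo$spline$lo,
                       hi = eo$spline$hi, coef = num(eo$spline$coef))
      e <- kan_edge(sp, w_b = as.numeric(eo$w_b), w_s = as.numeric(eo$w_s),
                    basis_kind = as.character(eo$basis_kind),
                    state = "spline")
      e$state <- as.character(eo$state)
      e$symbolic_fit <- de_fit(eo$symbolic_fit)
      if (!is.null(eo$category_map))
        e$category_map <- list(codes = num(eo$category_map$codes),
                               positions = num(eo$category_map$positions),
                               values = num(eo$category_map$values))
      e
    })
    kan_layer(lyo$n_in, lyo$n_out, edges)
  })
  shape <- as.integer(unlist(obj$shape))
  structure(list(shape = shape, layers = layers,
                 feature_names = as.character(unlist(obj$feature_names)),
                 normalization = list(
                   alpha = num(obj$normalization$alpha),
                   beta = num(obj$normalization$beta)),
                 G = as.integer(obj$G), k = as.integer(obj$k),
                 basis_kind = as.character(obj$basis_kind),
                 hidden_range = as.numeric(obj$hidden_range),
                 pruned_nodes = lapply(shape, function(n) logical(n))),
            class = "kan_model")
}

#' Full training-pruning-symbolization pipeline
#'
#' Convenience wrapper running the three stages on one dataset: train under
#' `config`, prune (either at a given threshold or auto-selected on the
#' validation split), and symbolize the surviving activations. Stage-wise
#' test C-indices are reported when a test set is supplied, mirroring the
#' train / prune / symbolize ablation convention.
#'
#' @param data training `survival_dataset`.
#' @param config a [train_config()].
#' @param test_data optional test `survival_dataset` for stage metrics.
#' @param prune_threshold numeric threshold, or `"auto"` for validation-based
#'   selection, or `NA` to skip pruning.
#' @param sym_config a [symbolic_config()].
#' @return list of class `kan_pipeline` with `fit`, `pruned`, `symbolic`
#'   (model), `formula` (a `symbolic_model`), `deselected`, `metrics`.
#' @export
kan_survival_pipeline <- function(data, config = train_config(),
                                  test_data = NULL,
                                  prune_threshold = "auto",
                                  sym_config = symbolic_config()) {
  fit <- train(data, config)
  tr_idx <- setdiff(seq_len(nrow(data$X)), fit$val_idx)
  tr <- sd_subset(data, tr_idx)
  va <- sd_subset(data, fit$val_idx)
  score <- function(model) {
    if (is.null(test_data)) return(NA_real_)
    concordance_index(kan_forward(model, test_data$X),
                      test_data$time, test_data$event)
  }
  metrics <- c(trained = score(fit$model))
  if (identical(prune_threshold, "auto")) {
    pr <- prune_auto(fit$model, tr, va)
    pruned <- pr$model
  } else if (is.na(prune_threshold)) {
    pruned <- fit$model
  } else {
    pruned <- prune(fit$model, tr, prune_threshold)
  }
  metrics <- c(metrics, pruned = score(pruned))
  sym <- symbolize(pruned, tr, sym_config)
  metrics <- c(metrics, symbolic = score(sym))
  formula <- extract_formula(sym, data = tr)
  structure(list(fit = fit, pruned = pruned, symbolic = sym,
                 formula = formula,
                 deselected = attr(pruned, "deselected"),
                 metrics = metrics),
            class = "kan_pipeline")
}

#' @export
print.kan_pipeline <- function(x, ...) {
  cat("KAN survival pipeline\n")
  if (!all(is.na(x$metrics))) {
    cat("test C-index by stage:\n")
    print(round(x$metrics, 4))
  }
  if (length(x$deselected))
    cat("deselected features:", paste(x$deselected, collapse = ", "), "\n")
  print(x$formula)
  invisible(x)
}
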