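#' Prevalence-based class weights
#'
#' Weights each class by one minus its prevalence in the training data,
#' `w_c = 1 - N_c / N_total`, so rarer classes cost proportionally more to
#' misclassify. A class holding all observations gets weight 0 (degenerate
#' training; a warning is raised).
#'
#' @param counts Non-negative per-class counts with a positive total;
#'   names are preserved.
#' @return Numeric weights in [0, 1], same names as `counts`.
#' @export
class_weights <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("total count is zero")
  w <- 1 - counts / total
  if (any(w == 0))
    warning("a class holds every observation; its weight is 0 ",
            "(degenerate training data)")
  w
}

#' Random forest specification
#'
#' @param n_trees Number of trees (default 1000).
#' @param sample_fraction Per-tree with-replacement sampling fraction in
#'   (0, 1]; default 0.6.
#' @param weighting `"prevalence"` (weights from [class_weights()]) or
#'   `"none"`.
#' @param seed Integer seed for the forest.
#' @return An object of class `forest_spec`.
#' @export
forest_spec <- function(n_trees = 1000, sample_fraction = 0.6,
                        weighting = c("prevalence", "none"), seed = 1) {
  weighting <- match.arg(weighting)
  if (n_trees < 1) stop("`n_trees` must be >= 1")
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop("`sample_fraction` must be in (0, 1]")
  structure(list(n_trees = as.integer(n_trees),
                 sample_fraction = sample_fraction,
                 weighting = weighting, seed = seed),
            class = "forest_spec")
}

# Predictor columns = everything that is not observation metadata.
.meta_cols <- c("x", "y", "depth_m", "class", "source", "role", "row_id")

#' Fit a substrate classification forest
#'
#' Fits a random forest of classification trees (via the `ranger` engine):
#' each tree grows on a with-replacement sample of `sample_fraction` of the
#' rows, variable importance uses Gini impurity, and -- under prevalence
#' weighting -- class weights `1 - N_c/N_total` make errors on rarer classes
#' cost proportionally more. Deterministic given the spec seed (forests are
#' grown single-threaded).
#'
#' @param train Observation table with predictor columns joined; any column
#'   other than `x, y, depth_m, class, source, role, row_id` is treated as a
#'   predictor. Needs at least two classes and finite predictor values.
#' @param spec A `forest_spec`.
#' @param predictors Optional character vector naming the predictor columns
#'   explicitly.
#' @return An object of class `substrate_model`: the fitted ensemble plus
#'   training class counts, the applied weights, out-of-bag error, and the
#'   Gini importance vector.
#' @export
fit_substrate <- function(train, spec = forest_spec(), predictors = NULL) {
  stopifnot(is.data.frame(train), inherits(spec, "forest_spec"))
  if (is.null(predictors))
    predictors <- setdiff(names(train), .meta_cols)
  if (!length(predictors)) stop("no predictor columns found")
  miss <- setdiff(predictors, names(train))
  if (length(miss)) stop("missing predictor column(s): ",
                         paste(miss, collapse = ", "))
  y <- factor(as.character(train$class), levels = substrate_classes())
  y <- droplevels(y)
  if (nlevels(y) < 2) stop("training data contain a single class")
  X <- train[, predictors, drop = FALSE]
  if (!all(vapply(X, function(v) all(is.finite(v)), logical(1))))
    stop("non-finite predictor values in training data")
  counts <- table(y)
  cw <- if (spec$weighting == "prevalence")
    class_weights(as.numeric(counts)) else NULL
  fit <- ranger::ranger(
    x = X, y = y,
    num.trees = spec$n_trees,
    sample.fraction = spec$sample_fraction,
    replace = TRUE,
    importance = "impurity",
    class.weights = cw,
    seed = spec$seed,
    num.threads = 1
  )
  structure(list(
    forest = fit,
    levels = levels(y),
    predictors = predictors,
    counts = as.numeric(counts), counts_names = names(counts),
    weights = cw,
    oob = fit$prediction.error,
    importance = fit$variable.importance,
    spec = spec
  ), class = "substrate_model")
}

#' @export
print.substrate_model <- function(x, ...) {
  cat(sprintf("<substrate_model> %d trees, %s weighting, OOB error %.3f\n",
              x$spec$n_trees, x$spec$weighting, x$oob))
  cat("  classes:", paste(sprintf("%s(%d)", x$counts_names, x$counts),
                          collapse = " "), "\n")
  invisible(x)
}

#' Predict substrate classes at points
#'
#' Majority vote of the ensemble, one class per row. Rows are independent:
#' permuting the input permutes the output identically.
#'
#' @param model A `substrate_model`.
#' @param table Data frame containing the model's predictor columns.
#' @return Factor of predicted classes over the four substrate classes.
#' @export
predict_points <- function(model, table) {
  stopifnot(inherits(model, "substrate_model"), is.data.frame(table))
  miss <- setdiff(model$predictors, names(table))
  if (length(miss)) stop("missing predictor column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(table) == 0)
    return(factor(character(0), levels = substrate_classes()))
  pred <- predict(model$forest, data = table[, model$predictors,
                                             drop = FALSE],
                  num.threads = 1, seed = model$spec$seed)$predictions
  factor(as.character(pred), levels = substrate_classes())
}

#' Predict a substrate class map
#'
#' Applies the model across a predictor stack, producing an integer-coded
#' class grid (1 = Rock ... 4 = Mud). Cells where any predictor is nodata
#' are nodata in the map.
#'
#' @param model A `substrate_model`.
#' @param stack A `predictor_stack` holding the model's predictor layers.
#' @return A `depth_grid` of class codes with attribute `labels`.
#' @export
predict_grid <- function(model, stack) {
  stopifnot(inherits(model, "substrate_model"),
            inherits(stack, "predictor_stack"))
  miss <- setdiff(model$predictors, stack_layers(stack))
  if (length(miss)) stop("missing predictor layer(s): ",
                         paste(miss, collapse = ", "))
  dims <- dim(stack$geometry$values)
  df <- as.data.frame(lapply(stack$layers[model$predictors], as.vector),
                      optional = TRUE)
  ok <- stats::complete.cases(df)
  codes <- rep(NA_integer_, nrow(df))
  if (any(ok)) {
    pred <- predict(model$forest, data = df[ok, , drop = FALSE],
                    num.threads = 1, seed = model$spec$seed)$predictions
    codes[ok] <- match(as.character(pred), substrate_classes())
  }
  out <- grid_like(stack$geometry, matrix(codes, dims[1], dims[2]))
  attr(out, "labels") <- substrate_classes()
  out
}

#' Relative variable importance
#'
#' Gini importance scaled to the most important predictor
#' (\eqn{p / p_{max}}), so values lie in (0, 1] with exactly one 1. Layers
#' listed in `all_layers` but absent from the model (e.g. fetch in the
#' coastwide configuration) are reported as `NA`.
#'
#' @param model A `substrate_model`.
#' @param all_layers Optional character vector of the full predictor suite
#'   to report against.
#' @return Named numeric vector of relative importances.
#' @export
relative_importance <- function(model, all_layers = NULL) {
  stopifnot(inherits(model, "substrate_model"))
  imp <- model$importance
  rel <- imp / max(imp)
  if (!is.null(all_layers)) {
    out <- rep(NA_real_, length(all_layers))
    names(out) <- all_layers
    out[names(rel)[names(rel) %in% all_layers]] <-
      rel[names(rel) %in% all_layers]
    return(out)
  }
  rel
}
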