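# Declarative tree-model configurations.
#
# The three boosting rows and the forest row mirror the published
# default/tuned hyperparameter table: each engine key fixes the defaults
# (seed 42, round budgets, early stopping) and declares the tuned search
# space with the printed bounds. Engine keys are registry strings; any
# backend satisfying the probability + gain-importance contract may serve
# them (here: the package's own histogram growers).

tree_engines <- function() {
  list(
    xgb = list(
      family = "boosted_trees", rounds = 300L, early_stopping = 5L,
      defaults = list(max_depth = 6, eta = 0.3, subsample = 1, gamma = 0,
                      min_child_weight = 1, lambda = 1, min_data_in_leaf = 1),
      space = list(
        max_depth = list(type = "quniform", lo = 4, hi = 8, q = 1),
        eta = list(type = "uniform", lo = 0.005, hi = 0.3),
        subsample = list(type = "uniform", lo = 0.5, hi = 1),
        gamma = list(type = "uniform", lo = 0, hi = 22),
        min_child_weight = list(type = "uniform", lo = 0, hi = 15))),
    lgb = list(
      family = "boosted_trees", rounds = 300L, early_stopping = NULL,
      defaults = list(max_depth = 6, eta = 0.1, subsample = 1, gamma = 0,
                      min_child_weight = 1e-3, lambda = 0, min_data_in_leaf = 20),
      space = list(
        max_depth = list(type = "quniform", lo = 4, hi = 8, q = 1),
        eta = list(type = "uniform", lo = 0.005, hi = 0.3),           # learning_rate
        subsample = list(type = "uniform", lo = 0.5, hi = 1),         # bagging_fraction
        gamma = list(type = "uniform", lo = 0, hi = 22),              # min_split_gain
        min_child_weight = list(type = "uniform", lo = 0, hi = 15))),
    cat = list(
      family = "boosted_trees", rounds = 400L, early_stopping = 5L,
      defaults = list(max_depth = 6, eta = 0.1, subsample = 1, gamma = 0,
                      min_child_weight = 0, lambda = 3, min_data_in_leaf = 1),
      space = list(
        max_depth = list(type = "quniform", lo = 4, hi = 10, q = 1),  # depth
        eta = list(type = "uniform", lo = 0.005, hi = 0.3),
        lambda = list(type = "uniform", lo = 1, hi = 10),             # l2_leaf_reg
        min_data_in_leaf = list(type = "uniform", lo = 1, hi = 15))),
    rf = list(
      family = "random_forest", rounds = NULL, early_stopping = NULL,
      defaults = list(n_trees = 100, max_depth = 30, min_samples_split = 2,
                      min_samples_leaf = 1, max_features = "sqrt",
                      criterion = "gini"),
      space = list(
        max_depth = list(type = "quniform", lo = 4, hi = 20, q = 1),
        min_samples_split = list(type = "quniform", lo = 2, hi = 10, q = 1),
        min_samples_leaf = list(type = "quniform", lo = 1, hi = 5, q = 1),
        max_features = list(type = "choice", values = list("sqrt", "log2", 12)),
        criterion = list(type = "choice", values = list("gini", "entropy"))))
  )
}

#' Declarative tree-model configuration
#'
#' Builds a `tree_model_config` for one of the registered engines:
#' `"xgb"`, `"lgb"`, `"cat"` (gradient boosting; 300/300/400 round budgets,
#' early stopping after 5 stalled rounds where configured) or `"rf"`
#' (100-tree bagged forest). Defaults follow the published configuration
#' (seed 42); `overrides` patch individual hyperparameters, e.g. the result
#' of a [tpe_search()]. Fractional values supplied for integer-valued
#' hyperparameters are rounded at the engine boundary.
#'
#' @param engine registry key.
#' @param overrides named list of hyperparameter overrides.
#' @param seed RNG seed for row subsampling/bagging.
#' @return an object of class `tree_model_config`.
#' @export
tree_model_config <- function(engine = c("xgb", "lgb", "cat", "rf"),
                              overrides = list(), seed = 42L) {
  engine <- match.arg(engine)
  reg <- tree_engines()[[engine]]
  params <- reg$defaults
  for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  for (nm in c("max_depth", "min_data_in_leaf", "n_trees",
               "min_samples_split", "min_samples_leaf"))
    if (!is.null(params[[nm]]) && is.numeric(params[[nm]]))
      params[[nm]] <- as.integer(round(params[[nm]]))
  if (is.numeric(params$max_features))
    params$max_features <- as.integer(round(params$max_features))
  structure(list(engine = engine, family = reg$family, params = params,
                 rounds = reg$rounds, early_stopping = reg$early_stopping,
                 space = reg$space, seed = as.integer(seed)),
            class = "tree_model_config")
}

#' Train a tree model from a declarative configuration
#'
#' @param config a [tree_model_config()].
#' @param x,y training features (numeric matrix) and 0-based integer labels.
#' @param weights optional per-class weights (named or ordered by class, as
#'   from [class_weights()]); expanded to per-sample weights.
#' @param val_x,val_y optional validation split used for the loss curve and
#'   early stopping.
#' @param nclass number of classes (default: inferred from labels).
#' @return a fitted `news2_tree_model`.
#' @export
train_tree <- function(config, x, y, weights = NULL,
                       val_x = NULL, val_y = NULL,
                       nclass = max(y) + 1L) {
  stopifnot(inherits(config, "tree_model_config"))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values")
  y <- as.integer(y)
  w <- if (is.null(weights)) NULL else unname(unlist(weights))[y + 1L]
  if (config$family == "random_forest") {
    m <- rf_train(x, y, nclass, config$params, w = w, seed = config$seed)
  } else {
    m <- gbt_train(x, y, nclass, config$rounds, config$params, w = w,
                   val_x = if (is.null(val_x)) NULL else as.matrix(val_x),
                   val_y = val_y, early_stopping = config$early_stopping,
                   seed = config$seed)
  }
  m$engine <- config$engine
  m
}
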