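# Quantile binning shared by all tree engines. Splits are "bin <= t"; cuts
# are interior quantiles so binning is monotone and reproducible.
make_bins <- function(x, max_bins = 256L) {
  stopifnot(is.matrix(x))
  cuts <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (anyNA(v)) stop("tree engines require complete features (column ", j, ")")
    qs <- unique(quantile(v, probs = seq_len(max_bins - 1L) / max_bins,
                          names = FALSE, type = 7))
    cuts[[j]] <- qs
  }
  cuts
}

apply_bins <- function(x, cuts) {
  xb <- matrix(0L, nrow(x), ncol(x))
  for (j in seq_len(ncol(x)))
    xb[, j] <- findInterval(x[, j], cuts[[j]])
  storage.mode(xb) <- "integer"
  xb
}

softmax_rows <- function(f) {
  f <- f - apply(f, 1, max)
  e <- exp(f)
  e / rowSums(e)
}

mlogloss <- function(prob, y, w = NULL) {
  p <- pmax(prob[cbind(seq_along(y), y + 1L)], 1e-15)
  if (is.null(w)) mean(-log(p)) else sum(-w * log(p)) / sum(w)
}

# ---- gradient-boosted trees (softmax, second-order) -------------------------

gbt_train <- function(x, y, nclass, rounds, params, w = NULL,
                      val_x = NULL, val_y = NULL, early_stopping = NULL,
                      seed = 42L) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (is.null(w)) w <- rep(1, nrow(x))
  set.seed(seed)
  cuts <- make_bins(x)
  xb <- apply_bins(x, cuts)
  nbins <- max(1L, max(vapply(cuts, length, integer(1)))) + 1L
  vb <- if (!is.null(val_x)) apply_bins(val_x, cuts)
  n <- nrow(x)
  Ftr <- matrix(0, n, nclass)
  Fva <- if (!is.null(val_x)) matrix(0, nrow(val_x), nclass)
  onehot <- matrix(0, n, nclass)
  onehot[cbind(seq_len(n), y + 1L)] <- 1

  trees <- vector("list", rounds)
  curve <- data.table(iter = integer(), train_loss = numeric(),
                      val_loss = numeric())
  importance <- numeric(ncol(x))
  best_loss <- Inf; best_iter <- 0L; stall <- 0L

  for (it in seq_len(rounds)) {
    p <- softmax_rows(Ftr)
    rows <- if (params$subsample < 1)
      sort(sample.int(n, max(2L, floor(params$subsample * n)))) - 1L
    else seq_len(n) - 1L
    round_trees <- vector("list", nclass)
    for (k in seq_len(nclass)) {
      g <- (p[, k] - onehot[, k]) * w
      h <- pmax(p[, k] * (1 - p[, k]), 1e-16) * w
      tr <- .grow_reg_tree(xb, g, h, rows, nbins,
                           as.integer(params$max_depth), params$lambda,
                           params$gamma, params$min_child_weight,
                           as.integer(params$min_data_in_leaf))
      Ftr[, k] <- Ftr[, k] + params$eta * .predict_reg_tree(
        xb, tr$feature, tr$thr, tr$left, tr$right, tr$value)
      if (!is.null(val_x))
        Fva[, k] <- Fva[, k] + params$eta * .predict_reg_tree(
          vb, tr$feature, tr$thr, tr$left, tr$right, tr$value)
      importance <- importance + tr$importance
      round_trees[[k]] <- tr[c("feature", "thr", "left", "right", "value")]
    }
    trees[[it]] <- round_trees
    tl <- mlogloss(softmax_rows(Ftr), y, w)
    vl <- if (!is.null(val_x)) mlogloss(softmax_rows(Fva), val_y) else NA_real_
    curve <- rbind(curve, data.table(iter = it, train_loss = tl, val_loss = vl))
    if (!is.null(val_x) && !is.null(early_stopping)) {
      if (vl < best_loss - 1e-12) { best_loss <- vl; best_iter <- it; stall <- 0L }
      else { stall <- stall + 1L; if (stall >= early_stopping) break }
    } else best_iter <- it
  }
  trees <- trees[seq_len(if (best_iter > 0) best_iter else length(curve$iter))]
  structure(list(kind = "gbt", trees = trees, cuts = cuts, nbins = nbins,
                 nclass = nclass, eta = params$eta, params = params,
                 best_iter = length(trees), curve = curve,
                 importance = importance, seed = seed,
                 feature_names = colnames(x)),
            class = "news2_tree_model")
}

gbt_margin <- function(model, x) {
  xb <- apply_bins(x, model$cuts)
  f <- matrix(0, nrow(x), model$nclass)
  for (rt in model$trees)
    for (k in seq_len(model$nclass)) {
      tr <- rt[[k]]
      f[, k] <- f[, k] + model$eta * .predict_reg_tree(
        xb, tr$feature, tr$thr, tr$left, tr$right, tr$value)
    }
  f
}

# ---- bagged random forest ---------------------------------------------------

rf_train <- function(x, y, nclass, params, w = NULL, seed = 42L) {
  stopifnot(is.matrix(x))
  if (is.null(w)) w <- rep(1, nrow(x))
  set.seed(seed)
  cuts <- make_bins(x)
  xb <- apply_bins(x, cuts)
  nbins <- max(1L, max(vapply(cuts, length, integer(1)))) + 1L
  n <- nrow(x); p <- ncol(x)
  mf <- params$max_features
  mtry <- if (identical(mf, "sqrt")) max(1L, floor(sqrt(p)))
          else if (identical(mf, "log2")) max(1L, floor(log2(p)))
          else as.integer(mf)
  crit <- if (identical(params$criterion, "entropy")) 1L else 0L
  trees <- vector("list", params$n_trees)
  importance <- numeric(p)
  for (t in seq_len(params$n_trees)) {
    boot <- sample.int(n, n, replace = TRUE) - 1L
    tr <- .grow_cls_tree(xb, as.integer(y), w, boot, nbins, nclass,
                         as.integer(params$max_depth),
                         as.integer(params$min_samples_split),
                         as.integer(params$min_samples_leaf),
                         mtry, crit, sample.int(.Machine$integer.max, 1L))
    importance <- importance + tr$importance
    trees[[t]] <- tr[c("feature", "thr", "left", "right", "leaf_counts")]
  }
  structure(list(kind = "rf", trees = trees, cuts = cuts, nbins = nbins,
                 nclass = nclass, params = params, importance = importance,
                 seed = seed, curve = NULL, best_iter = params$n_trees,
                 feature_names = colnames(x)),
            class = "news2_tree_model")
}

rf_prob <- function(model, x) {
  xb <- apply_bins(x, model$cuts)
  pr <- matrix(0, nrow(x), model$nclass)
  for (tr in model$trees)
    pr <- pr + .predict_cls_tree(xb, tr$feature, tr$thr, tr$left, tr$right,
                                 tr$leaf_counts)
  pr / length(model$trees)
}

#' Predict from a fitted tree model
#'
#' @param object a fitted model from [train_tree()].
#' @param newdata numeric feature matrix with the training columns.
#' @param type `"prob"` for per-class probabilities, `"class"` for the argmax
#'   label (0-based, matching severity labels).
#' @param ... unused.
#' @return probability matrix or integer label vector.
#' @export
predict.news2_tree_model <- function(object, newdata, type = c("prob", "class"),
                                     ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (any(!is.finite(newdata))) stop("non-finite feature values")
  pr <- if (object$kind == "gbt") softmax_rows(gbt_margin(object, newdata))
        else rf_prob(object, newdata)
  colnames(pr) <- paste0("class", seq_len(object$nclass) - 1L)
  if (type == "prob") pr else max.col(pr, ties.method = "first") - 1L
}

#' @export
print.news2_tree_model <- function(x, ...) {
  cat(sprintf("<%s model: %d %s, %d classes, %d features>\n",
              toupper(x$kind), length(x$trees),
              if (x$kind == "gbt") "boosting rounds" else "trees",
              x$nclass, length(x$cuts)))
  invisible(x)
}

#' Gain-based feature importance of a fitted tree model
#'
#' Total split gain (boosted trees) or weighted impurity decrease (forest)
#' accumulated per feature, normalized to sum to 1 when any split occurred.
#'
#' @param model a fitted model from [train_tree()].
#' @return named numeric vector, one entry per training feature.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "news2_tree_model"))
  imp <- model$importance
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- model$feature_names %||% paste0("f", seq_along(imp))
  imp
}
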