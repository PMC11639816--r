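# Multi-class evaluation: confusion matrices, per-class and aggregate
# metrics, generalized Matthews correlation, one-vs-rest AUROC/AUPRC,
# feature-importance reporting, the SpO2/heart-rate ablation experiment,
# and light EDA (Pearson correlations, standardized PCA).

#' Confusion matrix with rows = true class, columns = predicted
#'
#' @param y_true,y_pred integer labels (0-based).
#' @param k number of classes (default 4).
#' @return k x k integer matrix.
#' @export
confusion_matrix <- function(y_true, y_pred, k = 4L) {
  stopifnot(length(y_true) == length(y_pred))
  m <- matrix(0L, k, k, dimnames = list(true = seq_len(k) - 1L,
                                        pred = seq_len(k) - 1L))
  for (i in seq_along(y_true))
    m[y_true[i] + 1L, y_pred[i] + 1L] <- m[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  m
}

#' Generalized (multi-class) Matthews correlation coefficient
#'
#' The covariance form over the confusion matrix; returns 0 when the
#' denominator vanishes (e.g. a constant predictor).
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @return number in \[-1, 1\].
#' @export
mcc_multiclass <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  trace <- sum(diag(cm))
  rs <- rowSums(cm)  # true-class totals t_k
  cs <- colSums(cm)  # predicted totals p_k
  num <- trace * n - sum(cs * rs)
  den <- sqrt(n^2 - sum(cs^2)) * sqrt(n^2 - sum(rs^2))
  if (den == 0) 0 else num / den
}

# trapezoidal ROC / PR areas, one class vs rest
roc_auc_binary <- function(truth, score) {
  # truth: logical; trapezoidal area under TPR(FPR)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  t_sorted <- truth[o]; s_sorted <- score[o]
  tp <- cumsum(t_sorted); fp <- cumsum(!t_sorted)
  keep <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  tpr <- c(0, tp[keep] / np); fpr <- c(0, fp[keep] / nn)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

pr_auc_binary <- function(truth, score) {
  np <- sum(truth)
  if (np == 0) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  t_sorted <- truth[o]; s_sorted <- score[o]
  tp <- cumsum(t_sorted)
  fpc <- cumsum(!t_sorted)
  keep <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  prec <- tp[keep] / (tp[keep] + fpc[keep])
  rec <- tp[keep] / np
  rec <- c(0, rec); prec <- c(prec[1], prec)
  sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
}

ovr_auroc <- function(y, prob) {
  vapply(seq_len(ncol(prob)) - 1L,
         function(c) roc_auc_binary(y == c, prob[, c + 1L]), numeric(1))
}

ovr_auprc <- function(y, prob) {
  vapply(seq_len(ncol(prob)) - 1L,
         function(c) pr_auc_binary(y == c, prob[, c + 1L]), numeric(1))
}

#' Full multi-class metric report
#'
#' Per-class precision, sensitivity (recall), specificity and F1; macro and
#' support-weighted aggregates; accuracy; generalized MCC; one-vs-rest
#' AUROC/AUPRC per class with unweighted averages. Classes absent from the
#' true labels get `NA` ranking metrics and are excluded from the averages
#' with a warning.
#'
#' @param y_true,y_pred integer labels (0-based).
#' @param prob optional probability matrix (rows must sum to 1 within 1e-6)
#'   for the ranking metrics.
#' @param k number of classes (default 4).
#' @return object of class `metric_report` (a list).
#' @export
compute_metrics <- function(y_true, y_pred, prob = NULL, k = 4L) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(all(y_true >= 0 & y_true < k), all(y_pred >= 0 & y_pred < k))
  if (!is.null(prob)) {
    stopifnot(nrow(prob) == length(y_true), ncol(prob) == k)
    if (any(abs(rowSums(prob) - 1) > 1e-6))
      stop("probability rows must sum to 1")
  }
  cm <- confusion_matrix(y_true, y_pred, k)
  n <- sum(cm)
  support <- rowSums(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  sensitivity <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  specificity <- ifelse(tn + fp > 0, tn / (tn + fp), 0)
  f1 <- ifelse(precision + sensitivity > 0,
               2 * precision * sensitivity / (precision + sensitivity), 0)
  wt <- support / n
  auroc <- auprc <- rep(NA_real_, k)
  if (!is.null(prob)) {
    auroc <- ovr_auroc(y_true, prob)
    auprc <- ovr_auprc(y_true, prob)
    if (anyNA(auroc))
      warning("class absent from true labels; excluded from AUROC/AUPRC averages")
  }
  structure(list(
    confusion = cm,
    per_class = data.table(class = seq_len(k) - 1L, support = support,
                           precision = precision, sensitivity = sensitivity,
                           specificity = specificity, f1 = f1,
                           auroc = auroc, auprc = auprc),
    accuracy = sum(tp) / n,
    macro = list(precision = mean(precision), sensitivity = mean(sensitivity),
                 specificity = mean(specificity), f1 = mean(f1)),
    weighted = list(precision = sum(wt * precision),
                    sensitivity = sum(wt * sensitivity),
                    f1 = sum(wt * f1)),
    mcc = mcc_multiclass(cm),
    avg_auroc = if (all(is.na(auroc))) NA_real_ else mean(auroc, na.rm = TRUE),
    avg_auprc = if (all(is.na(auprc))) NA_real_ else mean(auprc, na.rm = TRUE)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | MCC %.3f | macro F1 %.3f", x$accuracy, x$mcc,
              x$macro$f1))
  if (!is.na(x$avg_auroc))
    cat(sprintf(" | avg AUROC %.3f | avg AUPRC %.3f", x$avg_auroc, x$avg_auprc))
  cat("\n")
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Cross-model feature-importance report
#'
#' Normalized gain-based importance per model plus a cross-model rank table
#' for the shared features.
#'
#' @param models named list of fitted `news2_tree_model`s.
#' @param top keep the `top` highest-ranked features in the report
#'   (default 25).
#' @return list with `importance` (long `data.table`) and `ranks` (wide
#'   rank table, 1 = most important).
#' @export
importance_report <- function(models, top = 25L) {
  stopifnot(length(models) >= 1L)
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  long <- rbindlist(lapply(names(models), function(nm) {
    imp <- feature_importance(models[[nm]])
    data.table(model = nm, feature = names(imp), importance = as.numeric(imp))
  }))
  long[, rank := frank(-importance, ties.method = "min"), by = model]
  ranks <- dcast(long, feature ~ model, value.var = "rank")
  mean_rank <- rowMeans(as.matrix(ranks[, -1]), na.rm = TRUE)
  ranks <- ranks[order(mean_rank)]
  list(importance = long[rank <= top][order(model, rank)],
       ranks = head(ranks, top))
}

#' Feature-ablation experiment
#'
#' Retrains the same configuration with and without the named raw feature
#' columns (their provenance masks are dropped alongside; TAG columns are
#' kept unless `drop_tags = TRUE` — note TAG columns are coarse transforms
#' of their raw vitals, so keeping them leaves residual signal) and reports
#' both metric reports plus the deltas.
#'
#' @param config a [tree_model_config()].
#' @param features_to_drop character vector of raw feature names, e.g.
#'   `c("spo2", "heart_rate")`.
#' @param x,y,test_x,test_y train and held-out data (features must carry
#'   column names).
#' @param weights optional class weights.
#' @param val_x,val_y optional validation split for early stopping (both
#'   fits use it, restricted to the kept columns for the ablated fit).
#' @param drop_tags also drop the vitals' TAG columns and TAG masks.
#' @return list with `full`, `ablated` (metric reports), `delta_mcc`,
#'   `dropped`.
#' @export
ablate <- function(config, features_to_drop, x, y, test_x, test_y,
                   weights = NULL, val_x = NULL, val_y = NULL,
                   drop_tags = FALSE) {
  x <- as.matrix(x); test_x <- as.matrix(test_x)
  stopifnot(!is.null(colnames(x)))
  drop <- unlist(lapply(features_to_drop, function(f) {
    cols <- c(f, paste0("mask_", f))
    if (drop_tags) cols <- c(cols, paste0("tag_", f), paste0("mask_tag_", f))
    cols
  }))
  drop <- intersect(drop, colnames(x))
  missing <- setdiff(features_to_drop, colnames(x))
  if (length(missing)) stop("unknown features: ", paste(missing, collapse = ", "))
  keep <- setdiff(colnames(x), drop)
  if (!length(keep)) stop("cannot drop every feature")
  eval_one <- function(cols) {
    m <- train_tree(config, x[, cols, drop = FALSE], y, weights = weights,
                    val_x = if (is.null(val_x)) NULL
                            else as.matrix(val_x)[, cols, drop = FALSE],
                    val_y = val_y)
    tex <- test_x[, cols, drop = FALSE]
    compute_metrics(test_y, predict(m, tex, type = "class"),
                    predict(m, tex, type = "prob"),
                    k = max(c(y, test_y)) + 1L)
  }
  full <- eval_one(colnames(x))
  ablated <- eval_one(keep)
  list(full = full, ablated = ablated,
       delta_mcc = ablated$mcc - full$mcc, dropped = drop)
}

#' Correlation and standardized-PCA exploratory analysis
#'
#' Pearson correlation matrix and a PCA on standardized columns
#' (zero-variance columns are excluded with a warning), reporting the
#' variance explained per component and the cumulative curve.
#'
#' @param table numeric table (>= 2 usable columns, >= 3 rows).
#' @param columns columns to analyse (default: all numeric).
#' @return list with `correlation`, `variance_ratio`, `cumulative`,
#'   `loadings`, `excluded`.
#' @export
eda <- function(table, columns = NULL) {
  dt <- as.data.table(table)
  if (is.null(columns))
    columns <- names(dt)[vapply(dt, is.numeric, logical(1))]
  x <- as.matrix(dt[, columns, with = FALSE])
  if (nrow(x) < 3L) stop("need at least 3 rows")
  sds <- apply(x, 2, sd)
  excluded <- colnames(x)[sds == 0 | is.na(sds)]
  if (length(excluded)) {
    warning("zero-variance column(s) excluded: ",
            paste(excluded, collapse = ", "))
    x <- x[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least 2 non-constant columns")
  pca <- prcomp(x, center = TRUE, scale. = TRUE)
  vr <- pca$sdev^2 / sum(pca$sdev^2)
  list(correlation = cor(x), variance_ratio = vr, cumulative = cumsum(vr),
       loadings = pca$rotation, excluded = excluded)
}
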