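# Histogram gradient-boosted regressor (squared error), used as the
# conditional model inside the chained-equation imputer.
gbr_train <- function(x, y, rounds = 60L, eta = 0.1, max_depth = 3L,
                      lambda = 1, min_data_in_leaf = 5L) {
  cuts <- make_bins(x)
  xb <- apply_bins(x, cuts)
  nbins <- max(1L, max(vapply(cuts, length, integer(1)))) + 1L
  n <- nrow(x)
  base <- mean(y)
  pred <- rep(base, n)
  rows <- seq_len(n) - 1L
  trees <- vector("list", rounds)
  h <- rep(1, n)
  for (it in seq_len(rounds)) {
    g <- pred - y
    tr <- .grow_reg_tree(xb, g, h, rows, nbins, max_depth, lambda, 0,
                         1e-8, min_data_in_leaf)
    pred <- pred + eta * .predict_reg_tree(xb, tr$feature, tr$thr, tr$left,
                                           tr$right, tr$value)
    trees[[it]] <- tr[c("feature", "thr", "left", "right", "value")]
  }
  list(base = base, eta = eta, cuts = cuts, trees = trees)
}

gbr_predict <- function(model, x) {
  xb <- apply_bins(x, model$cuts)
  pred <- rep(model$base, nrow(x))
  for (tr in model$trees)
    pred <- pred + model$eta * .predict_reg_tree(xb, tr$feature, tr$thr,
                                                 tr$left, tr$right, tr$value)
  pred
}

#' Chained-equation imputation with gradient-boosted regressors
#'
#' Completes a numeric table by iterated conditional modelling: columns are
#' visited in ascending missingness, each missing cell predicted from the
#' other columns by a histogram-based gradient-boosted regression tree
#' ensemble, for at most `max_rounds` sweeps or until the largest relative
#' change of any imputed cell drops below `tol`. A single completed dataset
#' is returned (the downstream models train on one completed table, not on
#' pooled multiple imputations), together with 0/1 masks flagging every
#' imputed cell.
#'
#' @param table data.frame/data.table/matrix of numeric columns, `NA` where
#'   missing.
#' @param seed integer seed; the result is reproducible for a fixed seed.
#' @param max_rounds maximum chained sweeps (default 10).
#' @param tol early-stop threshold on the maximum relative change of imputed
#'   cells between sweeps (default 1e-3).
#' @param fit_rows cap on the number of observed rows used to fit each
#'   conditional model (a standard histogram-GB scalability device; all
#'   missing cells are still predicted).
#' @return list with `data` (completed `data.table`), `mask` (integer matrix,
#'   1 = imputed), and `rounds` (sweeps performed).
#' @export
impute_chained <- function(table, seed = 42L, max_rounds = 10L, tol = 1e-3,
                           fit_rows = 5000L) {
  dt <- as.data.table(table)
  num_cols <- names(dt)[vapply(dt, is.numeric, logical(1))]
  if (!length(num_cols)) stop("no numeric columns to impute")
  x <- as.matrix(dt[, num_cols, with = FALSE])
  miss <- is.na(x)
  if (any(colSums(!miss) == 0L))
    stop("column(s) entirely missing cannot be imputed: ",
         paste(num_cols[colSums(!miss) == 0L], collapse = ", "))
  mask <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  mask[miss] <- 1L
  if (!any(miss))
    return(list(data = dt, mask = mask, rounds = 0L))

  set.seed(seed)
  # initialize with column medians, then sweep in ascending missingness
  for (j in seq_len(ncol(x)))
    if (any(miss[, j])) x[miss[, j], j] <- median(x[!miss[, j], j])
  order_j <- order(colSums(miss))
  rounds_done <- 0L
  for (it in seq_len(max_rounds)) {
    max_rel <- 0
    for (j in order_j) {
      mj <- miss[, j]
      if (!any(mj)) next
      obs <- which(!mj)
      xr <- x[, -j, drop = FALSE]
      if (ncol(xr) == 0L) { x[mj, j] <- median(x[obs, j]); next }
      fit_on <- if (length(obs) > fit_rows) sort(sample(obs, fit_rows)) else obs
      fit <- gbr_train(xr[fit_on, , drop = FALSE], x[fit_on, j])
      new <- gbr_predict(fit, xr[mj, , drop = FALSE])
      scale <- max(diff(range(x[obs, j])), 1e-8)
      max_rel <- max(max_rel, max(abs(new - x[mj, j])) / scale)
      x[mj, j] <- new
    }
    rounds_done <- it
    if (max_rel < tol) break
  }
  out <- copy(dt)
  for (j in seq_along(num_cols)) set(out, j = num_cols[j], value = x[, j])
  list(data = out, mask = mask, rounds = rounds_done)
}
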