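# Tree-structured Parzen Estimator hyperparameter search.
#
# Sequential model-based optimization: after a random startup phase, trials
# are split at the gamma-quantile of the objective into "good" and "bad"
# sets; each numeric dimension gets a Parzen (truncated-Gaussian kernel)
# density for both sets, and the next point maximizes the density ratio
# l(x)/g(x) over a batch of candidates drawn from the good density.
# Categorical dimensions use add-one re-weighted category frequencies.

tpe_sample_prior <- function(space) {
  out <- list()
  for (nm in names(space)) {
    d <- space[[nm]]
    out[[nm]] <- switch(d$type,
      uniform = runif(1, d$lo, d$hi),
      quniform = round(runif(1, d$lo, d$hi) / d$q) * d$q,
      choice = d$values[[sample.int(length(d$values), 1)]],
      stop("unknown dimension type: ", d$type))
  }
  out
}

parzen_lpdf <- function(x, obs, lo, hi) {
  if (!length(obs)) return(log(1 / (hi - lo)))
  bw <- max((hi - lo) / max(length(obs), 1), (hi - lo) * 0.05)
  dens <- vapply(x, function(xx)
    mean(stats::dnorm(xx, mean = obs, sd = bw)) /
      mean(stats::pnorm(hi, obs, bw) - stats::pnorm(lo, obs, bw)),
    numeric(1))
  log(pmax(dens, 1e-300))
}

parzen_draw <- function(n, obs, lo, hi) {
  if (!length(obs)) return(runif(n, lo, hi))
  bw <- max((hi - lo) / max(length(obs), 1), (hi - lo) * 0.05)
  mu <- sample(obs, n, replace = TRUE)
  pmin(pmax(rnorm(n, mu, bw), lo), hi)
}

#' Hyperparameter search by Tree-structured Parzen Estimation
#'
#' Minimizes `objective(params)` over the search space of a tree-model
#' configuration (or any space in the same format). The two canonical
#' objectives for model tuning are one minus the macro-averaged one-vs-rest
#' validation AUROC, and validation log loss; see [tune_objective()].
#' Every sampled point lies inside the declared bounds, and the returned
#' best trial attains the minimum of the trials log.
#'
#' @param space named list of dimensions: `list(type = "uniform"|"quniform"
#'   |"choice", lo =, hi =, q =, values =)`, e.g. `tree_model_config("xgb")$space`.
#' @param objective function taking a named list of hyperparameters and
#'   returning a single number to minimize.
#' @param max_evals total number of trials (default 50).
#' @param n_startup random trials before the Parzen model kicks in
#'   (default 10).
#' @param gamma quantile separating good from bad trials (default 0.25).
#' @param n_candidates candidate draws per TPE step (default 24).
#' @param seed RNG seed.
#' @return list with `best` (hyperparameters), `best_value`, and `trials`
#'   (a `data.table` log with one row per evaluation).
#' @export
tpe_search <- function(space, objective, max_evals = 50L, n_startup = 10L,
                       gamma = 0.25, n_candidates = 24L, seed = 42L) {
  if (max_evals < 1L) stop("max_evals must be at least 1")
  if (!length(space)) stop("search space is empty")
  set.seed(seed)
  trials <- vector("list", max_evals)
  values <- numeric(max_evals)
  for (it in seq_len(max_evals)) {
    if (it <= n_startup) {
      cand <- tpe_sample_prior(space)
    } else {
      done <- trials[seq_len(it - 1L)]
      vals <- values[seq_len(it - 1L)]
      n_good <- max(1L, ceiling(gamma * length(vals)))
      good_idx <- order(vals)[seq_len(n_good)]
      cand <- list()
      for (nm in names(space)) {
        d <- space[[nm]]
        if (d$type == "choice") {
          key <- vapply(done, function(tr) as.character(tr[[nm]]), character(1))
          keys <- vapply(d$values, as.character, character(1))
          cg <- table(factor(key[good_idx], levels = keys)) + 1
          cb <- table(factor(key[-good_idx], levels = keys)) + 1
          score <- as.numeric(cg / sum(cg)) / as.numeric(cb / sum(cb))
          draws <- sample(seq_along(keys), n_candidates, replace = TRUE,
                          prob = as.numeric(cg) / sum(cg))
          best <- draws[which.max(score[draws])]
          cand[[nm]] <- d$values[[best]]
        } else {
          xs <- vapply(done, function(tr) as.numeric(tr[[nm]]), numeric(1))
          draws <- parzen_draw(n_candidates, xs[good_idx], d$lo, d$hi)
          ratio <- parzen_lpdf(draws, xs[good_idx], d$lo, d$hi) -
                   parzen_lpdf(draws, xs[-good_idx], d$lo, d$hi)
          v <- draws[which.max(ratio)]
          if (d$type == "quniform") v <- min(max(round(v / d$q) * d$q, d$lo), d$hi)
          cand[[nm]] <- v
        }
      }
    }
    trials[[it]] <- cand
    values[it] <- objective(cand)
  }
  best_i <- which.min(values)
  log <- rbindlist(lapply(seq_len(max_evals), function(i) {
    row <- lapply(trials[[i]], function(v) if (is.numeric(v)) v else as.character(v))
    c(list(trial = i, value = values[i]), row)
  }), fill = TRUE)
  list(best = trials[[best_i]], best_value = values[best_i], trials = log)
}

#' Standard tuning objectives for tree models
#'
#' Returns a closure suitable for [tpe_search()]: trains the engine with the
#' candidate hyperparameters on the training split and scores the validation
#' split with either `1 - macro one-vs-rest AUROC` (beneficial under class
#' imbalance) or multi-class log loss.
#'
#' @param engine registry key for [tree_model_config()].
#' @param x,y,val_x,val_y train/validation features and 0-based labels.
#' @param weights optional class weights.
#' @param objective `"one_minus_auc"` or `"logloss"`.
#' @param seed model seed.
#' @return function(params) -> numeric.
#' @export
tune_objective <- function(engine, x, y, val_x, val_y, weights = NULL,
                           objective = c("one_minus_auc", "logloss"),
                           seed = 42L) {
  objective <- match.arg(objective)
  force(x); force(y); force(val_x); force(val_y)
  function(params) {
    cfg <- tree_model_config(engine, overrides = params, seed = seed)
    m <- train_tree(cfg, x, y, weights = weights, val_x = val_x, val_y = val_y)
    pr <- predict(m, val_x, type = "prob")
    if (objective == "logloss") mlogloss(pr, as.integer(val_y))
    else {
      auc <- ovr_auroc(as.integer(val_y), pr)
      1 - mean(auc, na.rm = TRUE)
    }
  }
}
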