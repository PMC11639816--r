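make_blobs <- function(n = 1200, seed = 2, k = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.integer(x[, 1] + 0.5 * x[, 2] > 0) + as.integer(x[, 1] > 1)
  list(x = x, y = y)
}

test_that("engine registry enforces the declared search bounds and defaults", {
  cfg <- tree_model_config("xgb")
  expect_equal(cfg$space$max_depth[c("lo", "hi")], list(lo = 4, hi = 8))
  expect_equal(cfg$rounds, 300L)
  expect_equal(cfg$early_stopping, 5L)
  expect_equal(cfg$seed, 42L)
  rf <- tree_model_config("rf")
  expect_equal(rf$params$n_trees, 100L)
  expect_equal(rf$space$max_depth[c("lo", "hi")], list(lo = 4, hi = 20))
  # fractional integer hyperparameters are rounded at the engine boundary
  ct <- tree_model_config("cat", overrides = list(min_data_in_leaf = 14.9935))
  expect_identical(ct$params$min_data_in_leaf, 15L)
})

test_that("boosted trees separate separable data and are deterministic", {
  d <- make_blobs()
  idx <- 1:900
  cfg <- tree_model_config("xgb")
  m1 <- train_tree(cfg, d$x[idx, ], d$y[idx],
                   val_x = d$x[-idx, ], val_y = d$y[-idx])
  expect_gte(mean(predict(m1, d$x[idx, ], type = "class") == d$y[idx]), 0.99)
  m2 <- train_tree(cfg, d$x[idx, ], d$y[idx],
                   val_x = d$x[-idx, ], val_y = d$y[-idx])
  expect_identical(m1$curve, m2$curve)  # same seed -> identical loss curve
  pr <- predict(m1, d$x[-idx, ], type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-9)
  expect_error(predict(m1, d$x[-idx, ] * NA), "non-finite")
})

test_that("early stopping halts within the configured patience", {
  set.seed(6)
  x <- matrix(rnorm(400 * 4), 400, 4)
  y <- sample(0:2, 400, replace = TRUE)  # pure noise: validation stalls fast
  cfg <- tree_model_config("xgb")
  m <- train_tree(cfg, x[1:300, ], y[1:300], val_x = x[301:400, ],
                  val_y = y[301:400])
  expect_lt(nrow(m$curve), cfg$rounds)
  best <- which.min(m$curve$val_loss)
  expect_lte(nrow(m$curve) - best, cfg$early_stopping)
})

test_that("the random forest meets its probability/importance contract", {
  d <- make_blobs(seed = 4)
  idx <- 1:900
  m <- train_tree(tree_model_config("rf"), d$x[idx, ], d$y[idx])
  expect_gte(mean(predict(m, d$x[-idx, ], type = "class") == d$y[-idx]), 0.9)
  imp <- feature_importance(m)
  expect_true(all(imp >= 0))
  expect_equal(sum(imp), 1)
  expect_gt(imp["f1"], imp["f3"])
  pr <- predict(m, d$x[-idx, ], type = "prob")
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-9)
})

test_that("class weighting raises minority recall on a 95/5 cohort", {
  set.seed(12)
  n <- 3000
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(0L, n)
  minority <- sample(n, round(0.05 * n))
  y[minority] <- 1L
  x[minority, 1] <- x[minority, 1] + 1.2   # overlapping signal
  idx <- 1:2000
  cfg <- tree_model_config("xgb")
  recall <- function(m) {
    pred <- predict(m, x[-idx, ], type = "class")
    mean(pred[y[-idx] == 1L] == 1L)
  }
  m_plain <- train_tree(cfg, x[idx, ], y[idx], nclass = 2L)
  w <- class_weights(table(factor(y[idx], 0:1)))
  m_wt <- train_tree(cfg, x[idx, ], y[idx], weights = w, nclass = 2L)
  expect_gt(recall(m_wt), recall(m_plain))
})

test_that("TPE finds a 1-d quadratic minimum and respects bounds", {
  space <- list(z = list(type = "uniform", lo = 0, hi = 10))
  res <- tpe_search(space, function(p) (p$z - 7.3)^2, max_evals = 50, seed = 3)
  expect_lt(abs(res$best$z - 7.3), 0.1 * 7.3)   # within 10% of the minimizer
  expect_true(all(res$trials$z >= 0 & res$trials$z <= 10))
  expect_equal(res$best_value, min(res$trials$value))
  # constant objective: no error, any in-bounds point
  res2 <- tpe_search(space, function(p) 1, max_evals = 15, seed = 4)
  expect_equal(res2$best_value, 1)
  # boosted spaces: sampled depth always within the printed 4..8
  sp <- tree_model_config("xgb")$space
  res3 <- tpe_search(sp, function(p) p$eta + p$gamma / 100, max_evals = 25,
                     seed = 5)
  expect_true(all(res3$trials$max_depth >= 4 & res3$trials$max_depth <= 8))
  expect_true(all(res3$trials$subsample >= 0.5 & res3$trials$subsample <= 1))
  # categorical + quniform dimensions (forest space) also stay in range
  spr <- tree_model_config("rf")$space
  res4 <- tpe_search(spr, function(p) as.numeric(p$max_depth), max_evals = 20,
                     seed = 6)
  expect_true(all(res4$trials$criterion %in% c("gini", "entropy")))
  expect_error(tpe_search(space, function(p) 1, max_evals = 0), "max_evals")
})

test_that("voting follows the stated soft/hard rules", {
  fake <- function(p) structure(list(p = p), class = "fake_model")
  assign("predict.fake_model",
         function(object, newdata, type = "prob", ...) object$p,
         envir = globalenv())
  on.exit(rm("predict.fake_model", envir = globalenv()))
  x <- matrix(0, 1, 1)
  m1 <- fake(matrix(c(.6, .4), 1)); m2 <- fake(matrix(c(.2, .8), 1))
  soft <- vote(list(m1, m2), x, "soft")
  expect_equal(soft$class, 1L)
  expect_equal(soft$prob, matrix(c(.4, .6), 1))
  # hard: plurality
  m3 <- fake(matrix(c(.9, .1), 1))
  hard <- vote(list(m3, fake(matrix(c(.7, .3), 1)), m2), x, "hard")
  expect_equal(hard$class, 0L)
  # hard 2-2 tie resolved by mean probability
  tie <- vote(list(fake(matrix(c(.9, .1), 1)), fake(matrix(c(.6, .4), 1)),
                   fake(matrix(c(.1, .9), 1)), fake(matrix(c(.2, .8), 1))),
              x, "hard")
  expect_equal(tie$class, 1L)   # mean prob favors class 1 (.55 vs .45)
  expect_error(vote(list(m1, fake(matrix(c(.2, .3, .5), 1))), x, "soft"),
               "unequal")
})

test_that("a 1-member ensemble reproduces that member exactly", {
  d <- make_blobs(n = 400, seed = 9)
  m <- train_tree(tree_model_config("xgb"), d$x[1:300, ], d$y[1:300],
                  val_x = d$x[301:400, ], val_y = d$y[301:400])
  solo_soft <- vote(list(m), d$x[301:400, ], "soft")
  solo_hard <- vote(list(m), d$x[301:400, ], "hard")
  direct <- predict(m, d$x[301:400, ], type = "class")
  expect_equal(solo_soft$class, direct)
  expect_equal(solo_hard$class, direct)
  expect_equal(solo_soft$prob, predict(m, d$x[301:400, ], type = "prob"))
})

test_that("count_parameters matches exhaustive enumeration of tensors", {
  ns <- asNamespace("news2plus")
  for (cell in c("lstm", "gru")) {
    for (dims in list(c(5, 7, 1), c(3, 4, 2), c(41, 16, 3))) {
      arch <- recurrent_architecture(cell, dims[1], dims[2], dims[3])
      p <- ns$rnn_init(arch, seed = 1)
      walked <- sum(vapply(p$layers,
                           function(l) sum(vapply(l, length, integer(1))),
                           numeric(1))) +
        sum(vapply(p$head, length, integer(1)))
      expect_identical(count_parameters(arch), as.integer(walked),
                       info = paste(cell, paste(dims, collapse = "x")))
    }
  }
  # hand-enumerated minimal LSTM: 4 gates x (1 input + 1 hidden + 2 biases)
  expect_identical(
    count_parameters(recurrent_architecture("lstm", 1, 1, 1), head = FALSE),
    16L)
})
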