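test_that("metric worked examples hold", {
  # perfect predictions
  mr <- compute_metrics(c(0, 1, 2, 3), c(0, 1, 2, 3), diag(4))
  expect_equal(mr$accuracy, 1)
  expect_equal(mr$mcc, 1)
  expect_true(all(mr$per_class$f1 == 1))
  expect_equal(mr$avg_auroc, 1)
  # constant predictor: MCC 0 by the degenerate-denominator convention
  expect_equal(compute_metrics(c(0, 1, 2, 3, 0), rep(0L, 5))$mcc, 0)
  # binary confusion [[2,1],[1,2]]: MCC = 3/9
  expect_equal(mcc_multiclass(matrix(c(2, 1, 1, 2), 2, byrow = TRUE)), 1 / 3)
  expect_error(compute_metrics(0:1, 0:1, matrix(c(.9, .3, .1, .4), 2), k = 2),
               "sum to 1")
})

test_that("aggregates agree with brute-force recomputation on random inputs", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(30:120, 1)
    y <- sample(0:3, n, replace = TRUE)
    p <- sample(0:3, n, replace = TRUE)
    mr <- compute_metrics(y, p)
    cm <- mr$confusion
    expect_equal(sum(cm), n)
    expect_equal(mr$accuracy, mean(y == p))
    # per-class from 2x2 collapses (specificity/sensitivity duality)
    for (c in 0:3) {
      tp <- sum(y == c & p == c); fn <- sum(y == c & p != c)
      fp <- sum(y != c & p == c); tn <- sum(y != c & p != c)
      row <- mr$per_class[class == c]
      expect_equal(row$sensitivity, if (tp + fn) tp / (tp + fn) else 0)
      expect_equal(row$specificity, tn / (tn + fp))
    }
    expect_equal(mr$macro$f1, mean(mr$per_class$f1))
    expect_equal(mr$weighted$precision,
                 sum(mr$per_class$precision * rowSums(cm) / n))
    # MCC from first principles over the confusion matrix
    num <- sum(diag(cm)) * n - sum(rowSums(cm) * colSums(cm))
    den <- sqrt(n^2 - sum(colSums(cm)^2)) * sqrt(n^2 - sum(rowSums(cm)^2))
    expect_equal(mr$mcc, if (den == 0) 0 else num / den)
  }
})

test_that("AUROC behaves like a ranking statistic", {
  set.seed(15)
  n <- 2000
  y <- sample(0:1, n, replace = TRUE)
  perfect <- cbind(1 - y, y)
  mr <- compute_metrics(y, y, perfect, k = 2)
  expect_equal(mr$per_class$auroc, c(1, 1))
  # label-independent scores: AUROC ~ 0.5 within Monte-Carlo error
  s <- runif(n)
  rand <- cbind(1 - s, s)
  mr2 <- compute_metrics(y, as.integer(s > 0.5), rand, k = 2)
  expect_lt(abs(mr2$per_class$auroc[2] - 0.5), 0.05)
  # AUROC equals the Mann-Whitney statistic (independent oracle)
  score <- rnorm(n) + y
  mw <- wilcox.test(score[y == 1], score[y == 0])$statistic /
    (sum(y == 1) * sum(y == 0))
  pr <- cbind(1 - plogis(score), plogis(score))
  mr3 <- compute_metrics(y, as.integer(score > 0.5), pr / rowSums(pr), k = 2)
  expect_equal(mr3$per_class$auroc[2], unname(mw), tolerance = 1e-10)
  # an absent class is excluded from averages with a warning
  expect_warning(
    mr4 <- compute_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1),
                           matrix(c(.7, .7, .2, .1, .2, .2, .6, .7,
                                    .05, .05, .1, .1, .05, .05, .1, .1),
                                  4, 4), k = 4),
    "absent")
  expect_true(is.na(mr4$per_class$auroc[3]))
  expect_false(is.na(mr4$avg_auroc))
})

planted_tabular <- function(n = 1500, seed = 16) {
  set.seed(seed)
  x <- cbind(spo2 = runif(n, 85, 100), heart_rate = runif(n, 60, 120),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  y <- as.integer(cut(x[, "spo2"], c(0, 91, 93, 95, 101))) - 1L
  y <- 3L - y  # low SpO2 -> high severity
  list(x = x, y = y)
}

test_that("importance ranks a planted single-feature signal first", {
  d <- planted_tabular()
  m <- train_tree(tree_model_config("xgb"), d$x[1:1000, ], d$y[1:1000],
                  val_x = d$x[1001:1500, ], val_y = d$y[1001:1500])
  imp <- feature_importance(m)
  expect_equal(names(which.max(imp)), "spo2")
  rep <- importance_report(list(xgb = m), top = 3)
  expect_equal(rep$importance[model == "xgb" & rank == 1]$feature, "spo2")
  # permuted labels: no feature dominates
  set.seed(17)
  yperm <- sample(d$y)
  m0 <- train_tree(tree_model_config("xgb"), d$x[1:1000, ], yperm[1:1000],
                   val_x = d$x[1001:1500, ], val_y = yperm[1001:1500])
  expect_lt(max(feature_importance(m0)), 0.6)
})

test_that("ablation removes signal features but shrugs off noise features", {
  d <- planted_tabular()
  cfg <- tree_model_config("xgb")
  tr <- 1:1000; te <- 1001:1500
  # dropping the planted feature collapses performance
  ab <- ablate(cfg, "spo2", d$x[tr, ], d$y[tr], d$x[te, ], d$y[te],
               val_x = d$x[te, ], val_y = d$y[te])
  expect_lte(ab$ablated$mcc, ab$full$mcc - 0.1)
  # dropping a pure-noise feature changes almost nothing
  ab2 <- ablate(cfg, "noise1", d$x[tr, ], d$y[tr], d$x[te, ], d$y[te],
                val_x = d$x[te, ], val_y = d$y[te])
  expect_lte(abs(ab2$delta_mcc), 0.05)
  # dropping nothing reproduces identical metrics (same seed)
  ab3 <- ablate(cfg, character(0), d$x[tr, ], d$y[tr], d$x[te, ], d$y[te],
                val_x = d$x[te, ], val_y = d$y[te])
  expect_equal(ab3$delta_mcc, 0)
  expect_identical(ab3$full$confusion, ab3$ablated$confusion)
  expect_error(ablate(cfg, "nope", d$x[tr, ], d$y[tr], d$x[te, ], d$y[te]),
               "unknown features")
})

test_that("EDA reproduces the structural correlations of the pipeline", {
  b <- generate_cohort(tiny_cohort_config(n = 5, seed = 19), MX)
  deg <- degrade(b)
  res <- suppressWarnings(preprocess_admissions(deg$observations,
                                                deg$demographics, MX,
                                                seed = 20))
  e <- eda(res, columns = c("map", "diastolic_bp", "systolic_bp",
                            "heart_rate", "spo2", "bmi", "weight", "height"))
  expect_equal(unname(diag(e$correlation)), rep(1, 8))
  # MAP is (SBP + 2 DBP)/3, so it must correlate strongly with DBP
  expect_gt(e$correlation["map", "diastolic_bp"], 0.8)
  expect_equal(sum(e$variance_ratio), 1)
  expect_equal(unname(tail(e$cumulative, 1)), 1)
  # two perfectly correlated features: one component explains everything
  dd <- data.table(a = rnorm(50))
  dd[, b := 2 * a]
  e2 <- eda(dd)
  expect_equal(e2$variance_ratio[1], 1)
  # zero-variance columns are excluded with a warning
  dd[, cst := 1]
  expect_warning(e3 <- eda(dd), "zero-variance")
  expect_equal(e3$excluded, "cst")
})
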