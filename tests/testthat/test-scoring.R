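test_that("age groups are total with left-closed boundaries", {
  expect_equal(assign_age_group(c(0, 0.5, 1, 1.99, 2, 4.99, 5, 11.9, 12,
                                  17.9, 18, 90)),
               c("inf_0_11m", "inf_0_11m", "tod_12_23m", "tod_12_23m",
                 "child_2_4y", "child_2_4y", "child_5_11y", "child_5_11y",
                 "adol_12_17y", "adol_12_17y", "adult", "adult"))
  expect_error(assign_age_group(-1), "non-negative")
  expect_error(assign_population_group(10, TRUE), "pediatric")
  expect_equal(assign_population_group(c(10, 40, 40), c(FALSE, TRUE, FALSE)),
               c("pediatric_no_copd", "adult_copd", "adult_no_copd"))
})

test_that("matrix loading canonicalizes the printed tables and reports edits", {
  expect_s3_class(MX, "news2_matrices")
  corr <- MX$corrections
  expect_gt(nrow(corr), 0)
  # the known printed defects are all captured
  expect_true(any(corr$group == "inf_0_11m" & corr$vital == "diastolic_bp" &
                  corr$type == "overlap"))
  expect_true(any(corr$group == "adol_12_17y" & corr$vital == "diastolic_bp" &
                  corr$type == "gap" & corr$lo == 53 & corr$hi == 62))
  expect_true(any(corr$scope == "severity" & corr$group == "adult_copd" &
                  corr$type == "gap"))
  # canonical bands are disjoint and cover the clamped domain
  b <- MX$tags$bands
  for (key in unique(paste(b$vital, b$group))) {
    bb <- b[paste(vital, group) == key][order(lo)]
    expect_true(all(bb$glo[-1] == bb$ghi[-nrow(bb)] + 1L), info = key)
    dom <- clamp_bounds(bb$vital[1])
    expect_equal(bb$lo[1], unname(dom[1, 1]))
    expect_equal(bb$hi[nrow(bb)], unname(dom[1, 2]))
  }
})

test_that("load_matrices rejects broken configurations", {
  cfg <- printed_config
  cfg$tags$adult$spo2 <- NULL
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, null = "null")
  expect_error(load_matrices(f), "missing the spo2 row")
  # a hand-written disjoint toy matrix needs no corrections
  cfg2 <- printed_config
  cfg2$tags$adult$heart_rate <- list(
    list(level = 3L, side = "low", lo = 0, hi = 59),
    list(level = 0L, side = "baseline", lo = 60, hi = 300))
  jsonlite::write_json(cfg2, f, auto_unbox = TRUE, null = "null")
  m2 <- load_matrices(f)
  expect_false(any(m2$corrections$vital == "heart_rate" &
                   m2$corrections$group == "adult"))
  # a band fully inside a more severe band cannot be canonicalized
  cfg3 <- printed_config
  cfg3$tags$adult$heart_rate <- list(
    list(level = 3L, side = "low", lo = 0, hi = 100),
    list(level = 1L, side = "low", lo = 20, hi = 60),
    list(level = 0L, side = "baseline", lo = 101, hi = 300))
  jsonlite::write_json(cfg3, f, auto_unbox = TRUE, null = "null")
  expect_error(load_matrices(f), "entirely inside")
})

test_that("tag_score matches the printed worked examples", {
  cases <- list(
    list("heart_rate", 150, "adult", 3L),
    list("respiratory_rate", 15, "adult", 0L),
    list("spo2", 93, "child_5_11y", 1L),
    list("temperature", 37.0, "adult", 0L),
    list("spo2", 84, "adult", 3L),
    list("heart_rate", 41, "adult", 2L),
    list("temperature", 39.9, "adult", 3L),
    list("spo2", 99, "adol_12_17y", 0L))  # above-baseline SpO2 scores 0
  for (cs in cases)
    expect_identical(tag_score(cs[[1]], cs[[2]], cs[[3]], MX), cs[[4]],
                     info = paste(cs[[1]], cs[[2]], cs[[3]]))
  expect_error(tag_score("pulse", 60, "adult", MX), "unknown vital")
  expect_error(tag_score("heart_rate", 60, "teens", MX), "unknown age group")
  expect_error(tag_score("spo2", 101, "adult", MX), "outside")
})

test_that("severity_label follows the population-specific bands", {
  expect_identical(severity_label(96, 40, FALSE, MX), 0L)
  expect_identical(severity_label(80, 70, TRUE, MX), 3L)
  expect_identical(severity_label(86, 8, FALSE, MX), 2L)
  expect_identical(severity_label(92, 40, FALSE, MX), 2L)
  expect_identical(severity_label(98, 50, TRUE, MX), 0L)  # annexed COPD gap
  expect_error(severity_label(90, 10, TRUE, MX), "pediatric")
  expect_error(severity_label(101, 40, FALSE, MX), "\\[0, 100\\]")
})

test_that("severity_label is monotone non-increasing in SpO2", {
  for (pop in list(c(40, FALSE), c(40, TRUE), c(8, FALSE))) {
    lab <- severity_label(0:100, pop[1], as.logical(pop[2]), MX)
    expect_true(all(diff(lab) <= 0),
                info = paste("population", pop[1], pop[2]))
  }
})

test_that("tag_vector applies all six vitals in canonical order", {
  rec <- c(respiratory_rate = 15, spo2 = 97, heart_rate = 75,
           systolic_bp = 117, diastolic_bp = 70, temperature = 37)
  expect_identical(unname(tag_vector(rec, "adult", MX)), rep(0L, 6))
  rec2 <- rec; rec2["spo2"] <- 84
  tv <- tag_vector(rec2, "adult", MX)
  expect_identical(unname(tv), c(0L, 3L, 0L, 0L, 0L, 0L))
  rec3 <- rec; rec3["heart_rate"] <- 41; rec3["temperature"] <- 39.9
  tv3 <- tag_vector(rec3, "adult", MX)
  expect_identical(tv3[["heart_rate"]], 2L)
  expect_identical(tv3[["temperature"]], 3L)
  expect_error(tag_vector(rec[-2], "adult", MX), "missing vitals")
})

test_that("scoring is deterministic and dense-grid oracle-equivalent on a sample", {
  for (grp in c("adult", "inf_0_11m")) {
    for (vit in c("heart_rate", "temperature")) {
      gran <- if (vit == "temperature") 0.1 else 1
      dom <- clamp_bounds(vit)
      grid <- seq(dom[1, 1], dom[1, 2], by = gran)
      got <- tag_score(vit, grid, grp, MX)
      expect_identical(got, tag_score(vit, grid, grp, MX))  # deterministic
      oracle <- oracle_tag_level(vit, grp, grid)
      ok <- !is.na(oracle)
      expect_true(all(got[ok] == oracle[ok]), info = paste(vit, grp))
    }
  }
})

test_that("corrections report is exportable as JSON", {
  f <- tempfile(fileext = ".json")
  write_corrections_report(MX, f)
  rep <- jsonlite::fromJSON(f)
  expect_equal(nrow(rep), nrow(MX$corrections))
  expect_true(all(c("scope", "type", "lo", "hi", "resolved_level") %in%
                  names(rep)))
})
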