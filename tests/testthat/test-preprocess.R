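test_that("merge_duplicates merges charttimes and drops identical copies", {
  obs <- data.table(
    patient_id = 1L, admission_id = 1L,
    charttime = c(10, 10, 20, 20),
    vital = c("heart_rate", "spo2", "heart_rate", "heart_rate"),
    value = c(70, 96, 80, 80))
  out <- merge_duplicates(obs)
  expect_equal(nrow(out), 3)                       # identical dup collapsed
  expect_equal(nrow(out[charttime == 10]), 2)      # two vitals, one charttime
  # conflicting values: last by input order wins, with a warning
  obs2 <- rbind(obs, data.table(patient_id = 1L, admission_id = 1L,
                                charttime = 10, vital = "spo2", value = 91))
  expect_warning(out2 <- merge_duplicates(obs2), "conflicting")
  expect_equal(out2[charttime == 10 & vital == "spo2"]$value, 91)
  # empty admission passes through
  expect_equal(nrow(merge_duplicates(obs[0])), 0)
})

test_that("clamp_outliers turns implausible values into missing cells", {
  obs <- toy_obs(times = 0, vitals = c("heart_rate", "spo2", "temperature"),
                 values = c(350, 100, -1))
  out <- clamp_outliers(obs)
  expect_equal(nrow(out), 1)                       # HR 350 and temp -1 gone
  expect_equal(out[vital == "spo2"]$value, 100)    # inclusive boundary kept
  expect_equal(attr(out, "n_clamped"), 2)
  # the dropped cells resurface as missing in the wide observation grid
  wide <- dcast(out, charttime ~ vital, value.var = "value")
  expect_false("heart_rate" %in% names(wide))
})

test_that("interpolate_minutes is linear, grid-regular, and marks rows", {
  adm <- data.table(charttime = c(0, 10), heart_rate = c(60, 70))
  out <- interpolate_minutes(adm, "heart_rate")
  expect_equal(nrow(out), 11)
  expect_equal(out[charttime == 5]$heart_rate, 65)
  expect_equal(out[charttime == 5]$row_interpolated, 1L)
  expect_equal(out[charttime %in% c(0, 10)]$row_interpolated, c(0L, 0L))
  # constant endpoints give a constant fill
  adm2 <- data.table(charttime = c(0, 7), spo2 = c(97, 97))
  expect_true(all(interpolate_minutes(adm2, "spo2")$spo2 == 97))
  # single observation: length-1 series, no grid extension
  out3 <- interpolate_minutes(data.table(charttime = 5, spo2 = 95), "spo2")
  expect_equal(nrow(out3), 1)
  expect_error(interpolate_minutes(data.table(charttime = 1, spo2 = NA_real_),
                                   "spo2"), "complete")
})

test_that("linear interpolation never leaves the observed range; splines can", {
  set.seed(4)
  for (rep in 1:10) {
    tt <- sort(sample(0:120, 8))
    adm <- data.table(charttime = tt, heart_rate = runif(8, 60, 120))
    tab <- validate_interpolation(adm, methods = c("linear", "cubic_spline"))
    lin <- tab[method == "linear"]
    expect_gte(lin$min, min(adm$heart_rate) - 1e-9)
    expect_lte(lin$max, max(adm$heart_rate) + 1e-9)
  }
  # monotone input: linear extremes equal the data extremes
  adm <- data.table(charttime = c(0, 10, 25, 40), spo2 = c(90, 92, 95, 99))
  lin <- validate_interpolation(adm, "linear")
  expect_equal(c(lin$min, lin$max), c(90, 99))
  # sparse oscillation: the cubic spline overshoots the data range
  osc <- data.table(charttime = c(0, 10, 20, 30, 40),
                    heart_rate = c(60, 140, 60, 140, 60))
  sp <- validate_interpolation(osc, "cubic_spline")
  expect_true(sp$max > 140 || sp$min < 60)
})

test_that("derive_physiology computes BMI/MAP and propagates masks", {
  dt <- data.table(height = 175, weight = 70, systolic_bp = 120,
                   diastolic_bp = 80, mask_height = 0L, mask_weight = 1L,
                   mask_systolic_bp = 0L, mask_diastolic_bp = 0L)
  out <- derive_physiology(dt)
  expect_equal(out$bmi, 22.9)
  expect_equal(out$map, 93.3)
  expect_equal(out$mask_bmi, 1L)   # source mask 1 implies derived mask 1
  expect_equal(out$mask_map, 0L)
  expect_warning(derive_physiology(
    data.table(height = 175, weight = 70, systolic_bp = 60,
               diastolic_bp = 80)), "diastolic")
})

test_that("the assembled table has exactly the 41-feature schema", {
  expect_length(feature_schema(), 41)
  b <- generate_cohort(tiny_cohort_config(n = 4), MX)
  deg <- degrade(b)
  res <- suppressWarnings(preprocess_admissions(deg$observations,
                                                deg$demographics, MX,
                                                seed = 9))
  expect_true(all(feature_schema() %in% names(res)))
  expect_equal(ncol(res), 41 + 5)  # + ids, charttime, row_interpolated, label
  expect_false(anyNA(res))
  tags <- as.matrix(res[, paste0("tag_", VITALS), with = FALSE])
  expect_true(all(tags %in% 0:3))
  masks <- as.matrix(res[, grep("^mask_", names(res)), with = FALSE])
  expect_true(all(masks %in% 0:1))
  # interpolated rows are masked for every vital-derived feature
  interp <- res$row_interpolated == 1L
  expect_true(all(masks[interp, "mask_spo2"] == 1L))
  # post-pipeline values respect the clamp bounds
  for (v in VITALS) {
    bnd <- clamp_bounds(v)
    expect_true(all(res[[v]] >= bnd[1, 1] & res[[v]] <= bnd[1, 2]), info = v)
  }
})

test_that("an unknown race maps to an all-zero one-hot with a message", {
  b <- generate_cohort(tiny_cohort_config(n = 3), MX)
  deg <- degrade(b)
  deg$demographics[1, race := "martian"]
  expect_message(
    res <- suppressWarnings(preprocess_admissions(deg$observations,
                                                  deg$demographics, MX,
                                                  seed = 9)),
    "unrecognized race")
  aid <- deg$demographics$admission_id[1]
  rows <- res[res$admission_id == aid]
  expect_true(all(as.matrix(rows[, paste0("race_", RACE_LEVELS),
                                 with = FALSE]) == 0))
})

test_that("cleaning is idempotent", {
  obs <- toy_obs(times = c(0, 10, 10, 30))
  obs$value[2] <- 400  # implausible
  once <- clamp_outliers(merge_duplicates(obs))
  twice <- clamp_outliers(merge_duplicates(copy(once)))
  expect_equal(as.data.frame(once), as.data.frame(twice),
               ignore_attr = TRUE)  # the clamp-count attribute may differ
})

test_that("label shares stay within 5 points across interpolation", {
  b <- generate_cohort(generator_config(n_patients = 10, seed = 3,
                                        adm_meanlog = log(800),
                                        adm_min = 400L, adm_max = 2000L), MX)
  deg <- degrade(b, gap_mean = 5)
  res <- suppressWarnings(preprocess_admissions(deg$observations,
                                                deg$demographics, MX,
                                                seed = 5))
  obs_spo2 <- merge(deg$observations[vital == "spo2" & !is.na(value)],
                    deg$demographics[, .(admission_id, age, copd)],
                    by = "admission_id")
  before <- prop.table(table(factor(
    severity_label(obs_spo2$value, obs_spo2$age, obs_spo2$copd, MX), 0:3)))
  after <- prop.table(table(factor(res$label, 0:3)))
  expect_true(all(abs(before - after) <= 0.05))
})
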