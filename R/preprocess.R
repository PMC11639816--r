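# Mask-aware preprocessing of irregular ICU observations.
#
# Long-format observations (patient_id, admission_id, charttime, vital,
# value) pass through a fixed pipeline: merge duplicates -> clamp implausible
# values to missing -> chained-equation imputation -> minute-level linear
# interpolation -> clamp again -> round to measurement granularity -> derive
# BMI/MAP -> TAG scores and severity labels. Per-cell provenance masks
# (0 observed / 1 synthetic) travel alongside the values throughout.

#' The ten numeric variables that carry provenance masks
#' @format character vector.
#' @export
MASKED_VARS <- c("spo2", "systolic_bp", "diastolic_bp", "respiratory_rate",
                 "temperature", "bmi", "heart_rate", "map", "height", "weight")

#' Race/ethnicity categories one-hot encoded in the feature table
#' @format character vector of length 7.
#' @export
RACE_LEVELS <- c("white", "black_african_american", "hispanic_latino",
                 "asian", "american_indian_alaska_native",
                 "native_hawaiian_pacific_islander", "multiracial")

#' Merge duplicated observation rows
#'
#' Rows recorded at the same charttime within an admission are merged into
#' one (each vital keeping its value); fully identical rows collapse to the
#' most recent occurrence. If two different non-missing values are charted
#' for the same (admission, charttime, vital), the last one by input order
#' wins and a warning is emitted.
#'
#' @param obs long-format observation `data.table` with columns
#'   `patient_id`, `admission_id`, `charttime`, `vital`, `value`.
#' @return deduplicated long-format `data.table`, at most one row per
#'   (admission, charttime, vital).
#' @export
merge_duplicates <- function(obs) {
  obs <- as.data.table(obs)
  req <- c("patient_id", "admission_id", "charttime", "vital", "value")
  if (!all(req %in% names(obs)))
    stop("observations need columns: ", paste(req, collapse = ", "))
  if (nrow(obs) == 0L) return(obs)
  obs <- obs[!is.na(value)]
  if (nrow(obs) == 0L) return(obs)
  obs[, .ord := .I]
  # identical rows: keep the most recent copy
  obs <- obs[obs[, .I[which.max(.ord)],
                 by = .(patient_id, admission_id, charttime, vital, value)]$V1]
  conflicts <- obs[, .N, by = .(admission_id, charttime, vital)][N > 1L]
  if (nrow(conflicts))
    warning(sprintf("%d conflicting (charttime, vital) pairs; keeping last by input order",
                    nrow(conflicts)))
  obs <- obs[obs[, .I[which.max(.ord)],
                 by = .(admission_id, charttime, vital)]$V1]
  obs[, .ord := NULL]
  setorder(obs, patient_id, admission_id, charttime, vital)
  obs[]
}

#' Clamp implausible measurements to missing
#'
#' Values outside the inclusive plausibility bounds (see [clamp_bounds()])
#' are treated as recording errors and become missing cells, to be filled by
#' the imputer. In the long format a missing cell is simply an absent row,
#' so clamped observations are dropped (which also keeps the cleaning stage
#' idempotent).
#'
#' @param obs long-format observation `data.table`.
#' @return the table without the implausible rows; the number of clamped
#'   cells is attached as attribute `"n_clamped"`.
#' @export
clamp_outliers <- function(obs) {
  obs <- as.data.table(obs)
  if (nrow(obs) == 0L) return(obs)
  bounds <- clamp_bounds(obs$vital)
  bad <- !is.na(obs$value) & (obs$value < bounds[, 1] | obs$value > bounds[, 2])
  out <- obs[!bad]
  setattr(out, "n_clamped", sum(bad))
  out[]
}

#' Interpolate an admission to a regular one-minute grid
#'
#' Linear interpolation per vital between consecutive observed charttimes;
#' the grid runs from the first to the last observation (no extrapolation).
#' Minutes that were not observed carry `row_interpolated = 1` and get
#' provenance mask 1 for every vital.
#'
#' @param adm wide `data.table` for one admission: `charttime` plus one
#'   complete (post-imputation) column per vital.
#' @param value_cols columns to interpolate (default: the six vitals present).
#' @return `data.table` on the minute grid with a `row_interpolated` column.
#' @export
interpolate_minutes <- function(adm, value_cols = intersect(VITALS, names(adm))) {
  adm <- as.data.table(adm)
  stopifnot("charttime" %in% names(adm), nrow(adm) >= 1L)
  if (anyNA(adm[, value_cols, with = FALSE]))
    stop("interpolation requires complete (imputed) observations")
  setorder(adm, charttime)
  t0 <- adm$charttime[1]; t1 <- adm$charttime[nrow(adm)]
  grid <- seq(as.integer(t0), as.integer(t1))
  out <- data.table(charttime = grid)
  for (v in value_cols)
    set(out, j = v,
        value = if (nrow(adm) == 1L) adm[[v]]
                else approx(adm$charttime, adm[[v]], xout = grid,
                            method = "linear", ties = "ordered")$y)
  set(out, j = "row_interpolated",
      value = as.integer(!(out$charttime %in% adm$charttime)))
  out[]
}

#' Compare interpolation methods on one admission
#'
#' Diagnostic reproducing the rationale for choosing linear interpolation:
#' evaluates linear, cubic-spline, and global polynomial (orders 3 and 5)
#' interpolants of each vital on the minute grid and reports per-method
#' extremes. Linear interpolation can never leave the convex hull of the
#' observations; spline and polynomial interpolants can and do produce
#' implausible excursions on sparse oscillating data.
#'
#' @param adm wide observation table for one admission (`charttime` + vitals),
#'   at least 4 observed rows.
#' @param methods subset of `c("linear", "cubic_spline", "poly3", "poly5")`.
#' @return `data.table` with columns `vital`, `method`, `min`, `max`.
#' @export
validate_interpolation <- function(adm,
                                   methods = c("linear", "cubic_spline",
                                               "poly3", "poly5")) {
  adm <- as.data.table(adm)
  stopifnot(nrow(adm) >= 4L)
  setorder(adm, charttime)
  grid <- seq(min(adm$charttime), max(adm$charttime))
  vit <- intersect(VITALS, names(adm))
  out <- list()
  for (v in vit) {
    tt <- adm$charttime; yy <- adm[[v]]
    keep <- !is.na(yy); tt <- tt[keep]; yy <- yy[keep]
    if (length(tt) < 4L) next
    for (m in methods) {
      yhat <- switch(m,
        linear = approx(tt, yy, xout = grid, ties = "ordered")$y,
        cubic_spline = splinefun(tt, yy, method = "fmm")(grid),
        poly3 = poly_fit_eval(tt, yy, 3L, grid),
        poly5 = poly_fit_eval(tt, yy, 5L, grid))
      out[[length(out) + 1L]] <- data.table(vital = v, method = m,
                                            min = min(yhat), max = max(yhat))
    }
  }
  rbindlist(out)
}

poly_fit_eval <- function(tt, yy, degree, grid) {
  d <- min(degree, length(tt) - 1L)
  ts <- scale(tt)
  fit <- stats::lm.fit(outer(as.numeric(ts), 0:d, `^`), yy)
  gs <- (grid - attr(ts, "scaled:center")) / attr(ts, "scaled:scale")
  as.numeric(outer(gs, 0:d, `^`) %*% fit$coefficients)
}

#' Derive BMI and mean arterial pressure with mask propagation
#'
#' `BMI = weight_kg / height_m^2`, `MAP = (SBP + 2 DBP) / 3`, both rounded to
#' 0.1. A derived cell's mask is the maximum of its source masks. Minutes
#' where DBP exceeds SBP trigger a warning but MAP is still computed.
#'
#' @param dt table containing `height`, `weight`, `systolic_bp`,
#'   `diastolic_bp` and (if masks are tracked) `mask_` columns for them.
#' @return the table with `bmi`, `map` and their mask columns added.
#' @export
derive_physiology <- function(dt) {
  dt <- as.data.table(dt)
  need <- c("height", "weight", "systolic_bp", "diastolic_bp")
  if (!all(need %in% names(dt)))
    stop("need columns: ", paste(need, collapse = ", "))
  if (any(dt$diastolic_bp > dt$systolic_bp, na.rm = TRUE))
    warning("diastolic above systolic at some minutes; MAP computed anyway")
  dt[, bmi := round(weight / (height / 100)^2, 1)]
  dt[, map := round((systolic_bp + 2 * diastolic_bp) / 3, 1)]
  if ("mask_height" %in% names(dt))
    dt[, mask_bmi := pmax(mask_height, mask_weight)]
  if ("mask_systolic_bp" %in% names(dt))
    dt[, mask_map := pmax(mask_systolic_bp, mask_diastolic_bp)]
  dt[]
}

round_to_granularity <- function(dt) {
  for (v in intersect(c(VITALS, "height", "weight"), names(dt))) {
    g <- if (v %in% c("temperature", "height", "weight")) 0.1 else 1
    set(dt, j = v, value = round(dt[[v]] / g) * g)
  }
  dt
}

clip_to_bounds <- function(dt) {
  for (v in intersect(VITALS, names(dt))) {
    b <- clamp_bounds(v)
    set(dt, j = v, value = pmin(pmax(dt[[v]], b[1, 1]), b[1, 2]))
  }
  dt
}

race_onehot <- function(race) {
  race <- tolower(trimws(as.character(race)))
  m <- matrix(0L, length(race), length(RACE_LEVELS),
              dimnames = list(NULL, paste0("race_", RACE_LEVELS)))
  hit <- match(race, RACE_LEVELS)
  known <- !is.na(hit)
  m[cbind(which(known), hit[known])] <- 1L
  n_unknown <- sum(!known & !race %in% c("undefined", "unknown", "", NA))
  if (n_unknown)
    message(n_unknown, " observations with unrecognized race category mapped to all-zero encoding")
  m
}

#' Names of the 41 model features, in canonical order
#'
#' 12 numeric columns (gender, age, weight, height, BMI, systolic and
#' diastolic BP, MAP, temperature, heart rate, respiratory rate, SpO2),
#' 7 one-hot race/ethnicity indicators, 6 TAG scores, and 16 provenance
#' masks (10 numeric variables + 6 TAGs).
#'
#' @return character vector of length 41.
#' @export
feature_schema <- function() {
  c("gender", "age", "weight", "height", "bmi", "systolic_bp", "diastolic_bp",
    "map", "temperature", "heart_rate", "respiratory_rate", "spo2",
    paste0("race_", RACE_LEVELS),
    paste0("tag_", VITALS),
    paste0("mask_", MASKED_VARS),
    paste0("mask_tag_", VITALS))
}

#' Assemble the model-ready feature table for one or more admissions
#'
#' Joins the minute-grid series with admission demographics, recomputes TAG
#' scores and severity labels from the final (imputed/interpolated/rounded)
#' values, one-hot encodes race, and propagates provenance masks to TAGs.
#' The result has the 41 feature columns of [feature_schema()] plus `label`
#' and bookkeeping columns (`patient_id`, `admission_id`, `charttime`,
#' `row_interpolated`) that are not model features.
#'
#' @param series minute-grid table with the six vitals, `height`, `weight`,
#'   `mask_*` columns, `charttime`, `row_interpolated`, `admission_id`.
#' @param demographics one row per admission: `admission_id`, `patient_id`,
#'   `age`, `gender`, `race`, `copd`.
#' @param matrices a `news2_matrices` object.
#' @return `data.table` with bookkeeping + 41 features + `label`.
#' @export
assemble_features <- function(series, demographics, matrices) {
  dt <- as.data.table(series)
  demo <- as.data.table(demographics)
  demo_cols <- setdiff(c("patient_id", "age", "gender", "race", "copd"),
                       names(dt))
  dt <- merge(dt, demo[, c("admission_id", demo_cols), with = FALSE],
              by = "admission_id", sort = FALSE)
  dt <- derive_physiology(dt)
  sc <- score_table(dt, dt$age, dt$copd, matrices)
  for (j in colnames(sc$tags)) set(dt, j = j, value = sc$tags[, j])
  dt[, label := sc$label]
  for (v in VITALS)
    set(dt, j = paste0("mask_tag_", v), value = dt[[paste0("mask_", v)]])
  rc <- race_onehot(dt$race)
  for (j in colnames(rc)) set(dt, j = j, value = rc[, j])
  dt[, gender := as.numeric(gender %in% c("M", "m", "male", 1))]
  keep <- c("patient_id", "admission_id", "charttime", "row_interpolated",
            feature_schema(), "label")
  missing <- setdiff(keep, names(dt))
  if (length(missing)) stop("assembled table missing: ", paste(missing, collapse = ", "))
  dt[, keep, with = FALSE]
}

#' Run the full preprocessing pipeline on long-format observations
#'
#' Fixed order: merge duplicates, clamp implausible values to missing,
#' chained-equation imputation at observation level, minute-level linear
#' interpolation per admission, clamp to bounds again, round to measurement
#' granularity, derive BMI/MAP, recompute TAG scores and severity labels.
#' Demographic columns (age, gender, height, weight, race) are treated as
#' admission-constant: their masks flag imputation only, never interpolation.
#'
#' @param obs long-format observations (see [merge_duplicates()]).
#' @param demographics admission table: `patient_id`, `admission_id`, `age`,
#'   `gender`, `race`, `height`, `weight`, `copd` (heights/weights may be
#'   `NA`; they are imputed).
#' @param matrices a `news2_matrices` object from [load_matrices()].
#' @param seed seed for the imputer.
#' @return the assembled feature table (see [assemble_features()]); counts of
#'   merged/clamped/imputed/interpolated cells are attached as attribute
#'   `"log"`.
#' @export
preprocess_admissions <- function(obs, demographics, matrices, seed = 42L) {
  demo <- as.data.table(demographics)
  n_in <- nrow(as.data.table(obs))
  obs <- merge_duplicates(obs)
  obs <- clamp_outliers(obs)
  n_clamped <- attr(obs, "n_clamped")

  wide <- dcast(obs, patient_id + admission_id + charttime ~ vital,
                value.var = "value")
  for (v in setdiff(VITALS, names(wide))) wide[, (v) := NA_real_]
  wide <- merge(wide, demo[, .(admission_id, age, height, weight)],
                by = "admission_id", sort = FALSE)
  setorder(wide, patient_id, admission_id, charttime)

  imp_cols <- c(VITALS, "height", "weight")
  imp <- impute_chained(wide[, c(imp_cols, "age"), with = FALSE], seed = seed)
  for (v in imp_cols) set(wide, j = v, value = imp$data[[v]])
  for (v in imp_cols) set(wide, j = paste0("mask_", v), value = imp$mask[, v])
  # demographics are admission-constant: collapse to per-admission medians
  wide[, `:=`(height = median(height), weight = median(weight),
              mask_height = max(mask_height), mask_weight = max(mask_weight)),
       by = admission_id]

  per_adm <- split(wide, by = "admission_id", sorted = TRUE)
  out <- vector("list", length(per_adm))
  for (i in seq_along(per_adm)) {
    a <- per_adm[[i]]
    g <- interpolate_minutes(a[, c("charttime", VITALS), with = FALSE])
    for (v in VITALS) {
      mk <- integer(nrow(g))
      mk[g$row_interpolated == 1L] <- 1L
      mk[match(a$charttime, g$charttime)] <- a[[paste0("mask_", v)]]
      g[, (paste0("mask_", v)) := mk]
    }
    g[, `:=`(admission_id = a$admission_id[1], patient_id = a$patient_id[1],
             height = a$height[1], weight = a$weight[1],
             mask_height = a$mask_height[1], mask_weight = a$mask_weight[1])]
    out[[i]] <- g
  }
  series <- rbindlist(out)
  clip_to_bounds(series)
  round_to_granularity(series)
  res <- assemble_features(series, demo, matrices)
  setattr(res, "log", list(
    n_obs_in = n_in, n_obs_merged = nrow(obs), n_clamped = n_clamped,
    n_imputed = sum(imp$mask), imputer_rounds = imp$rounds,
    n_minutes = nrow(res), n_interpolated_rows = sum(res$row_interpolated)))
  res
}
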