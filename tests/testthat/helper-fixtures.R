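suppressMessages(library(data.table))

# shared canonical matrices (loading is cheap and pure)
MX <- load_matrices()

# a small, fast cohort: short admissions so preprocessing stays quick
tiny_cohort_config <- function(n = 8L, seed = 1L, ...) {
  generator_config(n_patients = n, seed = seed,
                   adm_meanlog = log(400), adm_min = 120L, adm_max = 900L,
                   ...)
}

# one admission of long-format observations built by hand
toy_obs <- function(times = c(0, 10, 20, 30),
                    vitals = VITALS,
                    values = NULL, patient = 1L, admission = 1L) {
  grid <- CJ(charttime = times, vital = vitals)
  base <- c(respiratory_rate = 16, spo2 = 97, heart_rate = 75,
            systolic_bp = 117, diastolic_bp = 70, temperature = 37)
  grid[, value := if (is.null(values)) base[vital] else values]
  data.table(patient_id = patient, admission_id = admission, grid)
}

toy_demo <- function(admission = 1L, patient = 1L, age = 40, copd = FALSE,
                     height = 175, weight = 70, gender = "M",
                     race = "white") {
  data.table(patient_id = patient, admission_id = admission, age = age,
             gender = gender, race = race, height = height, weight = weight,
             copd = copd)
}

# printed (pre-canonicalization) bands straight from the shipped config,
# used by the brute-force scoring oracle
printed_config <- jsonlite::fromJSON(default_matrix_config(),
                                     simplifyVector = FALSE)

# oracle: first matching printed band after a severity-ordered scan;
# NA when no printed band covers the value
oracle_tag_level <- function(vital, grp, values) {
  bands <- printed_config$tags[[grp]][[vital]]
  dom <- clamp_bounds(vital)
  lev <- vapply(bands, function(b) as.integer(b$level), integer(1))
  lo <- vapply(bands, function(b) if (is.null(b$lo)) dom[1, 1] else max(b$lo, dom[1, 1]), numeric(1))
  hi <- vapply(bands, function(b) if (is.null(b$hi)) dom[1, 2] else min(b$hi, dom[1, 2]), numeric(1))
  ord <- order(-lev)
  out <- rep(NA_integer_, length(values))
  for (i in ord) {
    hitidx <- is.na(out) & values >= lo[i] & values <= hi[i]
    out[hitidx] <- lev[i]
  }
  out
}
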