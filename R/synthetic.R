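# Synthetic ICU cohort generator.
#
# The generator emits the statistical world the analysis assumes: irregular
# observation times, six vitals with plausible physiology, ~7.48% missing
# cells, a severity distribution near 76.9/14.5/5.5/3.1%, episode dwell
# medians near 178/29/60 minutes (classes 0/2/3), admission lengths with
# median ~5941 minutes, and demographic proportions matching the study
# population. Severity labels are generated first as a semi-Markov chain
# over adjacent classes; SpO2 is then drawn inside the population-specific
# severity band of the current class, which guarantees that re-labelling the
# ground truth with the scoring module reproduces the intended classes.

#' Synthetic cohort generator configuration
#'
#' Defaults encode the published cohort statistics. The class-1 dwell median
#' and the two free transition probabilities of the adjacent-class
#' semi-Markov chain are derived in closed form from the printed class
#' shares and the printed dwell medians (see the methods vignette); they are
#' constants of the stated world, not tuning knobs.
#'
#' @param n_patients number of patients.
#' @param seed RNG seed; cohorts are byte-identical for a fixed seed.
#' @param age_probs probabilities of the age brackets 12-17, 18-45, 46-65,
#'   66-85, 86+.
#' @param male_prob probability of male gender.
#' @param race_probs named probabilities over race/ethnicity categories.
#' @param copd_prevalence COPD probability among adults (pediatric COPD is
#'   never generated).
#' @param adm_meanlog,adm_sdlog,adm_min,adm_max log-normal admission-length
#'   law (minutes), truncated below/above.
#' @param gap_mean mean minutes between charted observations (exponential
#'   gaps, floored at 1).
#' @param missing_rate per-cell missingness probability.
#' @param dwell_medians per-class episode dwell medians (minutes).
#' @param dwell_sdlog log-normal dwell spread.
#' @param p_1to0,p_2to1 embedded-chain transition probabilities (the
#'   remaining mass goes to the other adjacent class).
#' @param second_admission_prob probability a patient has a second admission.
#' @param mode `"naturalistic"` or `"planted_signal"`.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(
    n_patients = 200L, seed = 42L,
    age_probs = c(a12_17 = 0.00061369, a18_45 = 0.12826202,
                  a46_65 = 0.36345505, a66_85 = 0.41316355,
                  a86plus = 0.09450752),
    male_prob = 0.53866217,
    race_probs = c(white = 0.71371586, undefined = 0.10647438,
                   black_african_american = 0.10524701,
                   hispanic_latino = 0.03973612, asian = 0.03053084,
                   american_indian_alaska_native = 0.00199448,
                   native_hawaiian_pacific_islander = 0.00138079,
                   multiracial = 0.00092053),
    copd_prevalence = 0.15,
    adm_meanlog = log(5941), adm_sdlog = 1.0597, adm_min = 952L,
    adm_max = 254643L,
    gap_mean = 15, missing_rate = 0.0748,
    dwell_medians = c(`0` = 178, `1` = 25.52, `2` = 29, `3` = 60),
    dwell_sdlog = 0.8,
    p_1to0 = 0.7597, p_2to1 = 0.7225,
    second_admission_prob = 0.15,
    mode = c("naturalistic", "planted_signal")) {
  mode <- match.arg(mode)
  if (n_patients < 1L) stop("n_patients must be at least 1")
  stopifnot(abs(sum(age_probs) - 1) < 1e-4, abs(sum(race_probs) - 1) < 1e-4,
            missing_rate >= 0, missing_rate <= 1)
  age_probs <- age_probs / sum(age_probs)
  race_probs <- race_probs / sum(race_probs)
  structure(as.list(environment()), class = "generator_config")
}

# minute-share implied by the semi-Markov chain (used for start states)
chain_shares <- function(cfg) {
  mu <- cfg$dwell_medians * exp(cfg$dwell_sdlog^2 / 2)
  p10 <- cfg$p_1to0; p21 <- cfg$p_2to1
  pi2 <- 1
  pi3 <- pi2 * (1 - p21)
  # solve pi0 = pi1*p10, pi1 = pi0 + pi2*p21  =>  pi1*(1-p10) = pi2 - pi3
  pi1 <- (pi2 - pi3) / (1 - p10)
  pi0 <- pi1 * p10
  pi <- c(pi0, pi1, pi2, pi3)
  sh <- pi * mu
  sh / sum(sh)
}

sample_episode_path <- function(cfg, total_minutes) {
  shares <- chain_shares(cfg)
  state <- sample.int(4L, 1L, prob = shares) - 1L
  t <- 0L
  cls <- integer(0); len <- integer(0)
  while (t < total_minutes) {
    d <- max(1L, round(rlnorm(1, log(cfg$dwell_medians[[as.character(state)]]),
                              cfg$dwell_sdlog)))
    d <- min(d, total_minutes - t)
    cls <- c(cls, state); len <- c(len, d)
    t <- t + d
    state <- switch(as.character(state),
      "0" = 1L,
      "1" = if (runif(1) < cfg$p_1to0) 0L else 2L,
      "2" = if (runif(1) < cfg$p_2to1) 1L else 3L,
      "3" = 2L)
  }
  data.table(class = cls, length = len)
}

ar1 <- function(n, mu, sd_stat, phi = 0.95) {
  if (n == 1L) return(mu + rnorm(1, 0, sd_stat))
  innov <- rnorm(n, 0, sd_stat * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, 0, sd_stat)
  mu + as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# per-vital stationary sd as a fraction of the baseline band width, so that
# excursions into alarm bands happen but clamp violations stay rare
VITAL_SD_FRAC <- c(respiratory_rate = 0.35, heart_rate = 0.4,
                   systolic_bp = 0.6, diastolic_bp = 0.5, temperature = 0.5)

baseline_band <- function(matrices, vital, group) {
  b <- matrices$tags$bands
  sel <- b$vital == vital & b$group == group & b$level == 0L
  c(b$lo[sel][1], b$hi[sel][1])
}

severity_band <- function(matrices, population, class) {
  b <- matrices$severity$bands
  sel <- b$population == population & b$level == class
  c(b$lo[sel][1], b$hi[sel][1])
}

# SpO2 inside the class band: hover near the band's upper (least severe)
# edge, reverting around a point a few percent below it
spo2_for_episode <- function(n, band) {
  lo <- max(band[1], band[2] - 6)
  hi <- band[2]
  mid <- (lo + hi) / 2
  v <- ar1(n, mid, (hi - lo) / 3, phi = 0.9)
  pmin(pmax(round(v), lo), hi)
}

#' Generate a synthetic ICU cohort
#'
#' See [generator_config()] for the statistical targets. Returns the full
#' ground truth (per-minute vitals and labels, episode boundaries) plus the
#' demographics table; pass the bundle to [degrade()] to obtain the
#' irregular, partially missing observation table the preprocessing module
#' consumes.
#'
#' @param config a [generator_config()].
#' @param matrices scoring matrices (default: the bundled ones). The
#'   generator uses the same matrices as the labeller, so scoring the ground
#'   truth reproduces the generated labels exactly.
#' @return object of class `cohort_bundle`: list with `demographics`,
#'   `truth`, `episodes`, `config`, `matrices`.
#' @export
generate_cohort <- function(config = generator_config(),
                            matrices = load_matrices()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  np <- config$n_patients

  bracket <- sample.int(5L, np, replace = TRUE, prob = config$age_probs)
  age_lo <- c(12, 18, 46, 66, 86)[bracket]
  age_hi <- c(17.99, 45.99, 65.99, 85.99, 95)[bracket]
  age <- round(runif(np, age_lo, age_hi), 2)
  gender <- ifelse(runif(np) < config$male_prob, "M", "F")
  race <- names(config$race_probs)[
    sample.int(length(config$race_probs), np, replace = TRUE,
               prob = config$race_probs)]
  copd <- runif(np) < config$copd_prevalence & age >= 18
  height <- round(pmax(50 + 6.5 * pmin(age, 19) + rnorm(np, 0, 7), 45), 1)
  bmi_t <- ifelse(age >= 18, rnorm(np, 26, 4.5), rnorm(np, 17 + 0.4 * age, 2.5))
  weight <- round(pmax(bmi_t, 12) * (height / 100)^2, 1)

  n_adm <- 1L + rbinom(np, 1L, config$second_admission_prob)
  demo <- list(); truth <- list(); episodes <- list()
  adm_id <- 0L
  for (p in seq_len(np)) {
    grp <- assign_age_group(age[p])
    pop <- assign_population_group(age[p], copd[p])
    for (a in seq_len(n_adm[p])) {
      adm_id <- adm_id + 1L
      T_adm <- round(rlnorm(1, config$adm_meanlog, config$adm_sdlog))
      T_adm <- as.integer(min(max(T_adm, config$adm_min), config$adm_max))
      ep <- sample_episode_path(config, T_adm)
      lab <- rep(ep$class, ep$length)
      spo2 <- unlist(lapply(seq_len(nrow(ep)), function(i)
        spo2_for_episode(ep$length[i], severity_band(matrices, pop, ep$class[i]))))
      vit <- list(spo2 = spo2)
      for (v in setdiff(VITALS, "spo2")) {
        bb <- baseline_band(matrices, v, grp)
        mu <- runif(1, bb[1] + 0.25 * diff(bb), bb[2] - 0.25 * diff(bb))
        sdv <- diff(bb) * VITAL_SD_FRAC[[v]]
        gran <- vital_granularity(v)
        x <- round(ar1(T_adm, mu, sdv) / gran) * gran
        b <- clamp_bounds(v)
        vit[[v]] <- pmin(pmax(x, b[1, 1]), b[1, 2])
      }
      truth[[adm_id]] <- data.table(
        patient_id = p, admission_id = adm_id, charttime = seq_len(T_adm) - 1L,
        respiratory_rate = vit$respiratory_rate, spo2 = vit$spo2,
        heart_rate = vit$heart_rate, systolic_bp = vit$systolic_bp,
        diastolic_bp = vit$diastolic_bp, temperature = vit$temperature,
        label = lab)
      ep[, `:=`(admission_id = adm_id,
                start = cumsum(length) - length, end = cumsum(length) - 1L)]
      episodes[[adm_id]] <- ep
      demo[[adm_id]] <- data.table(
        patient_id = p, admission_id = adm_id, age = age[p],
        gender = gender[p], race = race[p], height = height[p],
        weight = weight[p], copd = copd[p])
    }
  }
  structure(list(demographics = rbindlist(demo), truth = rbindlist(truth),
                 episodes = rbindlist(episodes), config = config,
                 matrices = matrices),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  sh <- prop.table(table(factor(x$truth$label, levels = 0:3)))
  cat(sprintf("<cohort: %d patients, %d admissions, %d minutes; label shares %s>\n",
              length(unique(x$demographics$patient_id)),
              nrow(x$demographics), nrow(x$truth),
              paste(sprintf("%.1f%%", 100 * sh), collapse = "/")))
  invisible(x)
}

#' Rewrite SpO2 dynamics so the future label is predictable
#'
#' Planted-signal mode for recovery experiments: for every minute `t >= h`,
#' the severity class at `t` is made a deterministic function of SpO2 and
#' heart rate at `t - h` — a thresholded linear drift: the linear term
#' `beta (hr - hr_ref)` is clipped to +/- 6% and quantized to 2% steps, the
#' drifted saturation `v = spo2 - drift` is classified by the population's
#' severity bands — and SpO2 at `t` is redrawn inside that class's band. A
#' model seeing minute `t` can therefore predict the label at `t + h`
#' perfectly from (SpO2, HR) alone, and ablating those features destroys
#' the signal. Planted cohorts should be generated with
#' `copd_prevalence = 0`: COPD shifts the labelling thresholds but is not
#' among the 41 model features, so a mixed-population planted cohort is not
#' perfectly predictable from the features by construction.
#'
#' @param bundle a naturalistic [generate_cohort()] bundle.
#' @param horizon lead time in minutes (default 5, the prediction window).
#' @param beta heart-rate coefficient of the drift (default 0.25).
#' @return the bundle with rewritten SpO2/labels, `mode = "planted_signal"`,
#'   and the generating rule stored in `$signal`.
#' @export
plant_signal <- function(bundle, horizon = 5L, beta = 0.25) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  set.seed(bundle$config$seed + 1L)
  matrices <- bundle$matrices
  truth <- copy(bundle$truth)
  demo <- bundle$demographics
  out <- vector("list", nrow(demo))
  for (i in seq_len(nrow(demo))) {
    ad <- truth[admission_id == demo$admission_id[i]]
    pop <- assign_population_group(demo$age[i], demo$copd[i])
    grp <- assign_age_group(demo$age[i])
    hr_ref <- mean(baseline_band(matrices, "heart_rate", grp))
    bands <- lapply(0:3, function(c) severity_band(matrices, pop, c))
    # class of every integer SpO2 value, precomputed for the population
    cls_of <- severity_label(0:100, demo$age[i], demo$copd[i], matrices)
    n <- nrow(ad)
    spo2 <- ad$spo2; hr <- ad$heart_rate
    lab <- ad$label
    if (n > horizon) {
      u <- runif(n)  # pre-drawn within-band jitter
      for (t in seq_len(n - horizon)) {
        drift <- 2 * round(min(max(beta * (hr[t] - hr_ref), -6), 6) / 2)
        v <- round(min(max(spo2[t] - drift, 0), 100))
        cls <- cls_of[v + 1L]
        b <- bands[[cls + 1L]]
        lo <- max(b[1], b[2] - 3)
        spo2[t + horizon] <- lo + floor(u[t] * (b[2] - lo + 1))
        lab[t + horizon] <- cls
      }
    }
    set(ad, j = "spo2", value = spo2)
    set(ad, j = "label", value = lab)
    out[[i]] <- ad
  }
  bundle$truth <- rbindlist(out)
  bundle$config$mode <- "planted_signal"
  bundle$signal <- list(
    horizon = as.integer(horizon), beta = beta,
    rule = "class(spo2 - quantized clip(beta*(hr - hr_ref))) at t fixes label at t+horizon")
  bundle
}

#' Degrade ground truth into an irregular, partially missing observation table
#'
#' Subsamples charttimes with exponential gaps (floored at one minute, the
#' first minute always charted) and removes vital cells independently at the
#' configured missing rate. Observed cells equal the ground truth exactly
#' (no observation noise). Height/weight are also dropped from the emitted
#' demographics at the missing rate, so demographic imputation is exercised.
#'
#' @param bundle a [generate_cohort()] bundle.
#' @param gap_mean,missing_rate override the bundle config (optional).
#' @param seed RNG seed (default: derived from the bundle seed).
#' @return list with `observations` (long format: patient_id, admission_id,
#'   charttime, vital, value — `NA` value = missing cell) and `demographics`.
#' @export
degrade <- function(bundle, gap_mean = NULL, missing_rate = NULL, seed = NULL) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  cfg <- bundle$config
  gap_mean <- gap_mean %||% cfg$gap_mean
  missing_rate <- missing_rate %||% cfg$missing_rate
  set.seed(seed %||% (cfg$seed + 2L))
  obs <- list()
  for (aid in bundle$demographics$admission_id) {
    ad <- bundle$truth[admission_id == aid]
    T_adm <- nrow(ad)
    if (gap_mean <= 1) {
      keep <- seq_len(T_adm)
    } else {
      gaps <- pmax(1L, round(rexp(ceiling(2.5 * T_adm / gap_mean) + 10L,
                                  1 / gap_mean)))
      tt <- cumsum(c(0L, gaps))
      keep <- tt[tt < T_adm] + 1L
    }
    sub <- ad[keep]
    long <- melt(sub, id.vars = c("patient_id", "admission_id", "charttime"),
                 measure.vars = VITALS, variable.name = "vital",
                 value.name = "value", variable.factor = FALSE)
    long[runif(.N) < missing_rate, value := NA_real_]
    obs[[length(obs) + 1L]] <- long
  }
  demo <- copy(bundle$demographics)
  demo[runif(.N) < missing_rate, height := NA_real_]
  demo[runif(.N) < missing_rate, weight := NA_real_]
  list(observations = rbindlist(obs), demographics = demo)
}
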