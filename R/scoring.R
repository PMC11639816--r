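#' Score one vital against the canonical TAG bands
#'
#' Values are first rounded to the vital's measurement granularity (integers
#' for rates and pressures and SpO2, 0.1 degrees C for temperature), then
#' looked up in the canonical band set for the given age group. The returned
#' level is 0 (baseline) to 3 (severe deviation). SpO2 has no high side in
#' ambient air: values above the baseline band score 0 via the canonical
#' baseline band, which extends to 100%.
#'
#' @param vital one of [VITALS].
#' @param value numeric vector of measurements in the vital's unit.
#' @param group a single age-group key (see [AGE_GROUPS]).
#' @param matrix a `news2_matrices` object (or its `$tags` element).
#' @return integer vector of TAG levels in 0..3.
#' @examples
#' m <- load_matrices()
#' tag_score("heart_rate", 150, "adult", m)  # 3
#' @export
tag_score <- function(vital, value, group, matrix) {
  tags <- if (inherits(matrix, "news2_matrices")) matrix$tags else matrix
  stopifnot(inherits(tags, "threshold_matrix"))
  if (length(vital) != 1L || !vital %in% VITALS)
    stop("unknown vital: ", paste(vital, collapse = ", "))
  if (length(group) != 1L || !group %in% AGE_GROUPS)
    stop("unknown age group: ", paste(group, collapse = ", "))
  sel <- tags$bands$vital == vital & tags$bands$group == group
  bd <- tags$bands[which(sel)]
  gran <- vital_granularity(vital)
  g <- as.integer(round(value / gran))
  if (anyNA(g)) stop("missing values cannot be scored")
  if (any(g < bd$glo[1] | g > bd$ghi[nrow(bd)]))
    stop(sprintf("value outside the clamped %s domain [%s, %s]",
                 vital, format(bd$lo[1]), format(bd$hi[nrow(bd)])))
  bd$level[findInterval(g, bd$glo)]
}

#' Assign the hypoxemia severity label from SpO2
#'
#' Classifies SpO2 into 0 (normal), 1 (mild), 2 (moderate) or 3 (severe)
#' using the population-specific severity bands: adults without COPD, adults
#' with COPD (lower acceptable baseline), or pediatric patients without COPD.
#' Pediatric patients with COPD are rejected.
#'
#' @param spo2_pct numeric vector of SpO2 percentages in \[0, 100\].
#' @param age_years numeric vector of ages (recycled against `spo2_pct`).
#' @param copd logical vector (recycled).
#' @param matrix a `news2_matrices` object (or its `$severity` element).
#' @return integer vector of severity labels 0..3.
#' @examples
#' m <- load_matrices()
#' severity_label(80, 70, TRUE, m)   # 3: severe for an adult with COPD
#' severity_label(96, 40, FALSE, m)  # 0: normal adult
#' @export
severity_label <- function(spo2_pct, age_years, copd, matrix) {
  sev <- if (inherits(matrix, "news2_matrices")) matrix$severity else matrix
  stopifnot(inherits(sev, "severity_matrix"))
  n <- length(spo2_pct)
  age_years <- rep_len(age_years, n)
  copd <- rep_len(as.logical(copd), n)
  if (anyNA(spo2_pct) || any(spo2_pct < 0) || any(spo2_pct > 100))
    stop("SpO2 must lie in [0, 100]")
  pop <- assign_population_group(age_years, copd)
  g <- as.integer(round(spo2_pct))
  out <- integer(n)
  for (p in unique(pop)) {
    bd <- sev$bands[which(sev$bands$population == p)]
    i <- pop == p
    out[i] <- bd$level[findInterval(g[i], bd$glo)]
  }
  out
}

#' TAG vector for one minute of complete vitals
#'
#' Applies [tag_score()] to each of the six vitals of a single record. The
#' pipeline guarantees completeness (all vitals imputed/interpolated before
#' scoring); a missing vital is a contract violation and raises an error.
#'
#' @param record named numeric vector or one-row list containing all of
#'   [VITALS].
#' @param group a single age-group key.
#' @param matrix a `news2_matrices` object.
#' @return named integer vector of length 6 in the canonical vital order.
#' @export
tag_vector <- function(record, group, matrix) {
  record <- unlist(record)
  missing <- setdiff(VITALS, names(record))
  if (length(missing))
    stop("record is missing vitals: ", paste(missing, collapse = ", "))
  vals <- record[VITALS]
  if (anyNA(vals)) stop("record contains missing vitals (pipeline contract)")
  out <- vapply(VITALS, function(v) tag_score(v, vals[[v]], group, matrix),
                integer(1))
  setNames(as.integer(out), VITALS)
}

# Vectorized table scorer used by the preprocessing pipeline: adds the six
# tag_<vital> columns and the severity label for arbitrary (group, copd) mixes.
score_table <- function(dt, age_years, copd, matrix) {
  stopifnot(inherits(matrix, "news2_matrices"))
  n <- nrow(dt)
  group <- assign_age_group(rep_len(age_years, n))
  copd <- rep_len(as.logical(copd), n)
  tagcols <- matrix(NA_integer_, n, length(VITALS),
                    dimnames = list(NULL, paste0("tag_", VITALS)))
  for (grp in unique(group)) {
    i <- which(group == grp)
    for (v in VITALS)
      tagcols[i, paste0("tag_", v)] <- tag_score(v, dt[[v]][i], grp, matrix)
  }
  lab <- severity_label(dt[["spo2"]], rep_len(age_years, n), copd, matrix)
  list(tags = tagcols, label = lab)
}
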