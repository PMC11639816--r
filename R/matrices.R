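#' @import data.table
#' @importFrom stats approx median quantile rnorm runif sd var prcomp
#'   complete.cases setNames predict cor splinefun rlnorm rbinom rexp
#' @importFrom utils head tail
NULL

#' The six scored vitals, in canonical order
#'
#' Order used by TAG vectors and feature tables: respiratory rate
#' (breaths/min), SpO2 (%), heart rate (bpm), systolic blood pressure (mmHg),
#' diastolic blood pressure (mmHg), temperature (degrees C).
#'
#' @format Character vector of length 6.
#' @export
VITALS <- c("respiratory_rate", "spo2", "heart_rate",
            "systolic_bp", "diastolic_bp", "temperature")

# measurement granularity and plausibility (clamp) domain per vital;
# the clamp bounds double as the scoring domain after canonicalization
vital_granularity <- function(vital) ifelse(vital == "temperature", 0.1, 1)

#' Plausibility bounds per vital
#'
#' Respiratory rate, heart rate and both blood pressures are implausible
#' above 300 or below 0; SpO2 above 100 or below 0; temperature above 60 or
#' below 0. Values outside these inclusive bounds are treated as recording
#' errors and set to missing for imputation.
#'
#' @param vital character vector of vital names (see [VITALS]).
#' @return 2-column matrix of lower/upper bounds.
#' @export
clamp_bounds <- function(vital = VITALS) {
  lo <- rep(0, length(vital))
  hi <- ifelse(vital == "spo2", 100, ifelse(vital == "temperature", 60, 300))
  cbind(lower = lo, upper = hi)
}

# ---- canonicalization -------------------------------------------------------

# Resolve a printed list of bands (possibly overlapping, possibly gappy) into
# disjoint bands that jointly cover [dmin, dmax] on the vital's grid.
# Overlapping points go to the MORE severe band; gap points are annexed by the
# more severe adjacent band (alarm-favouring). Every edit is reported.
canonicalize_bands <- function(level, lo, hi, dmin, dmax, gran) {
  to_grid <- function(v) as.integer(round(v / gran))
  g0 <- to_grid(dmin); g1 <- to_grid(dmax)
  n <- g1 - g0 + 1L
  lo <- ifelse(is.na(lo), dmin, pmax(lo, dmin))
  hi <- ifelse(is.na(hi), dmax, pmin(hi, dmax))
  if (any(lo > hi)) stop("band with lower bound above upper bound")
  gl <- to_grid(lo); gh <- to_grid(hi)

  assigned <- rep(NA_integer_, n)
  ncover <- integer(n)
  for (i in seq_along(level)) {
    idx <- (gl[i] - g0 + 1L):(gh[i] - g0 + 1L)
    ncover[idx] <- ncover[idx] + 1L
    assigned[idx] <- pmax(assigned[idx], level[i], na.rm = TRUE)
  }
  # a printed band wholly shadowed by more severe bands cannot be canonicalized
  for (i in seq_along(level)) {
    idx <- (gl[i] - g0 + 1L):(gh[i] - g0 + 1L)
    if (!any(assigned[idx] == level[i]))
      stop(sprintf("band [%s, %s] level %d lies entirely inside a more severe band",
                   format(lo[i]), format(hi[i]), level[i]))
  }

  runs_of <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts, ends)[r$values, , drop = FALSE]
  }
  corrections <- list()
  ov <- runs_of(ncover > 1L)
  if (nrow(ov)) for (k in seq_len(nrow(ov))) {
    i <- ov[k, 1]:ov[k, 2]
    corrections[[length(corrections) + 1L]] <- data.table(
      type = "overlap", lo = (g0 + ov[k, 1] - 1L) * gran,
      hi = (g0 + ov[k, 2] - 1L) * gran, resolved_level = max(assigned[i]))
  }
  gp <- runs_of(ncover == 0L)
  if (nrow(gp)) for (k in seq_len(nrow(gp))) {
    lft <- if (gp[k, 1] > 1L) assigned[gp[k, 1] - 1L] else NA_integer_
    rgt <- if (gp[k, 2] < n) assigned[gp[k, 2] + 1L] else NA_integer_
    if (is.na(lft) && is.na(rgt)) stop("no printed band covers any point")
    annex <- max(lft, rgt, na.rm = TRUE)
    assigned[gp[k, 1]:gp[k, 2]] <- annex
    corrections[[length(corrections) + 1L]] <- data.table(
      type = "gap", lo = (g0 + gp[k, 1] - 1L) * gran,
      hi = (g0 + gp[k, 2] - 1L) * gran, resolved_level = annex)
  }

  r <- rle(assigned)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  bands <- data.table(
    level = r$values,
    lo = (g0 + starts - 1L) * gran, hi = (g0 + ends - 1L) * gran,
    glo = g0 + starts - 1L, ghi = g0 + ends - 1L)
  list(bands = bands,
       corrections = if (length(corrections)) rbindlist(corrections)
                     else data.table(type = character(), lo = numeric(),
                                     hi = numeric(), resolved_level = integer()))
}

# assign low/baseline/high sides relative to the (unique) level-0 band
band_sides <- function(bands) {
  base <- which(bands$level == 0L)
  if (length(base) != 1L)
    stop("expected exactly one baseline (level 0) band after canonicalization")
  sides <- rep("baseline", nrow(bands))
  sides[seq_len(nrow(bands)) < base] <- "low"
  sides[seq_len(nrow(bands)) > base] <- "high"
  sides
}

# ---- loading ----------------------------------------------------------------

#' Path of the bundled threshold configuration
#' @return path to the package's default scoring-matrix JSON file.
#' @export
default_matrix_config <- function() {
  system.file("extdata", "news2plus_matrices.json", package = "news2plus",
              mustWork = TRUE)
}

#' Load and canonicalize the TAG and severity scoring matrices
#'
#' Reads a layered JSON configuration (vital -> age group -> printed bands,
#' plus SpO2 severity bands per population), validates its schema, and
#' canonicalizes every band list so that bands are pairwise disjoint and
#' jointly cover the vital's plausibility domain at its measurement
#' granularity (integers, 0.1 degrees C for temperature). Printed overlaps
#' resolve to the more severe band and printed gaps are annexed by the
#' adjacent more severe band; both are alarm-favouring choices and every
#' applied edit is returned in a machine-readable corrections report.
#'
#' @param path path to the configuration file; defaults to the bundled one.
#' @return an object of class `news2_matrices`: a list with elements
#'   `tags` (canonical TAG bands, class `threshold_matrix`), `severity`
#'   (canonical SpO2 severity bands, class `severity_matrix`), and
#'   `corrections` (a `data.table` of applied edits).
#' @examples
#' m <- load_matrices()
#' nrow(m$corrections) > 0  # the printed tables contain overlaps and gaps
#' @export
load_matrices <- function(path = default_matrix_config()) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!all(c("tags", "severity") %in% names(cfg)))
    stop("configuration must contain `tags` and `severity` sections")

  corr_all <- list()
  tag_bands <- list()
  for (grp in AGE_GROUPS) {
    if (is.null(cfg$tags[[grp]]))
      stop("tags section is missing age group: ", grp)
    for (vit in VITALS) {
      printed <- cfg$tags[[grp]][[vit]]
      if (is.null(printed) || !length(printed))
        stop(sprintf("tags matrix is missing the %s row for group %s", vit, grp))
      lev <- vapply(printed, function(x) as.integer(x$level), integer(1))
      sid <- vapply(printed, function(x) as.character(x$side), character(1))
      if (vit == "spo2" && any(sid == "high"))
        stop("SpO2 must have no high-side bands (ambient air)")
      lo <- vapply(printed, function(x) if (is.null(x$lo)) NA_real_ else as.numeric(x$lo), numeric(1))
      hi <- vapply(printed, function(x) if (is.null(x$hi)) NA_real_ else as.numeric(x$hi), numeric(1))
      dom <- clamp_bounds(vit)
      gran <- vital_granularity(vit)
      can <- tryCatch(
        canonicalize_bands(lev, lo, hi, dom[1, 1], dom[1, 2], gran),
        error = function(e) stop(sprintf("cannot canonicalize %s / %s: %s",
                                         vit, grp, conditionMessage(e)), call. = FALSE))
      bd <- can$bands
      bd[, side := band_sides(bd)]
      bd[, `:=`(vital = vit, group = grp)]
      tag_bands[[length(tag_bands) + 1L]] <- bd
      if (nrow(can$corrections)) {
        cc <- copy(can$corrections)
        cc[, `:=`(scope = "tag", vital = vit, group = grp)]
        corr_all[[length(corr_all) + 1L]] <- cc
      }
    }
  }
  tag_bands <- rbindlist(tag_bands)
  setcolorder(tag_bands, c("vital", "group", "level", "side", "lo", "hi", "glo", "ghi"))

  sev_bands <- list()
  for (pop in POPULATION_GROUPS) {
    printed <- cfg$severity[[pop]]
    if (is.null(printed) || length(printed) != 4L)
      stop("severity section must contain 4 classes for population: ", pop)
    lev <- vapply(printed, function(x) as.integer(x$class), integer(1))
    if (!setequal(lev, 0:3)) stop("severity classes must be 0..3 for ", pop)
    lo <- vapply(printed, function(x) if (is.null(x$lo)) NA_real_ else as.numeric(x$lo), numeric(1))
    hi <- vapply(printed, function(x) if (is.null(x$hi)) NA_real_ else as.numeric(x$hi), numeric(1))
    can <- canonicalize_bands(lev, lo, hi, 0, 100, 1)
    bd <- can$bands
    # monotonicity: class must be non-increasing in SpO2
    if (any(diff(bd$level) > 0))
      stop("severity classes must be monotone non-increasing in SpO2 for ", pop)
    bd[, `:=`(population = pop, side = NA_character_)]
    sev_bands[[length(sev_bands) + 1L]] <- bd
    if (nrow(can$corrections)) {
      cc <- copy(can$corrections)
      cc[, `:=`(scope = "severity", vital = "spo2", group = pop)]
      corr_all[[length(corr_all) + 1L]] <- cc
    }
  }
  sev_bands <- rbindlist(sev_bands)
  setcolorder(sev_bands, c("population", "level", "lo", "hi", "glo", "ghi", "side"))

  corrections <- if (length(corr_all)) {
    out <- rbindlist(corr_all, use.names = TRUE)
    setcolorder(out, c("scope", "vital", "group", "type", "lo", "hi", "resolved_level"))
    out
  } else {
    data.table(scope = character(), vital = character(), group = character(),
               type = character(), lo = numeric(), hi = numeric(),
               resolved_level = integer())
  }

  tags <- structure(list(bands = tag_bands,
                         provenance = cfg$provenance %||% path,
                         corrections = corrections[scope == "tag"]),
                    class = "threshold_matrix")
  severity <- structure(list(bands = sev_bands,
                             provenance = cfg$provenance %||% path,
                             corrections = corrections[scope == "severity"]),
                        class = "severity_matrix")
  structure(list(tags = tags, severity = severity, corrections = corrections),
            class = "news2_matrices")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the corrections report of a loaded matrix set as JSON
#'
#' @param matrices a `news2_matrices` object from [load_matrices()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corrections_report <- function(matrices, path) {
  stopifnot(inherits(matrices, "news2_matrices"))
  jsonlite::write_json(matrices$corrections, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.news2_matrices <- function(x, ...) {
  cat("NEWS2+ scoring matrices\n")
  cat("  TAG bands:     ", nrow(x$tags$bands), "canonical bands over",
      length(unique(x$tags$bands$group)), "age groups x", length(VITALS), "vitals\n")
  cat("  severity bands:", nrow(x$severity$bands), "bands over",
      length(unique(x$severity$bands$population)), "populations\n")
  cat("  corrections applied:", nrow(x$corrections), "\n")
  invisible(x)
}
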