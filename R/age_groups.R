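#' Age groups used by the age-stratified scoring matrices
#'
#' The per-vital TAG thresholds are stratified into six developmental groups:
#' infants (0-11 months), toddlers (12-23 months), children 2-4 and 5-11
#' years, adolescents 12-17 years, and adults (18 years and over). Boundaries
#' are left-closed, so an age of exactly 2.0 years falls in `child_2_4y` and
#' 18.0 in `adult`.
#'
#' @format A character vector of the six group keys, ordered from youngest
#'   to oldest.
#' @export
AGE_GROUPS <- c("inf_0_11m", "tod_12_23m", "child_2_4y", "child_5_11y",
                "adol_12_17y", "adult")

#' Population groups used by the SpO2 severity matrices
#'
#' Hypoxemia severity thresholds differ for adults without COPD, adults with
#' COPD (whose acceptable baseline SpO2 is lower), and pediatric patients
#' (< 18 years) without COPD. Pediatric patients with COPD are outside the
#' scope of the labelling scheme and are rejected.
#'
#' @format A character vector of the three population keys.
#' @export
POPULATION_GROUPS <- c("adult_no_copd", "adult_copd", "pediatric_no_copd")

#' Map age in years to a scoring age group
#'
#' @param age_years numeric vector of non-negative ages in years.
#' @return character vector of age-group keys (see [AGE_GROUPS]).
#' @examples
#' assign_age_group(c(0.5, 17.9, 18))
#' @export
assign_age_group <- function(age_years) {
  if (!is.numeric(age_years)) stop("`age_years` must be numeric")
  if (anyNA(age_years) || any(age_years < 0))
    stop("ages must be non-negative and non-missing")
  # left-closed bins: [0,1) [1,2) [2,5) [5,12) [12,18) [18,Inf)
  idx <- findInterval(age_years, c(0, 1, 2, 5, 12, 18))
  AGE_GROUPS[idx]
}

#' Map age and COPD status to a severity population group
#'
#' @param age_years numeric vector of ages in years.
#' @param copd logical vector (recycled) flagging chronic obstructive
#'   pulmonary disease.
#' @return character vector of population keys (see [POPULATION_GROUPS]).
#'   Pediatric (< 18 years) patients with COPD raise an error.
#' @export
assign_population_group <- function(age_years, copd) {
  if (anyNA(age_years) || any(age_years < 0))
    stop("ages must be non-negative and non-missing")
  copd <- rep_len(as.logical(copd), length(age_years))
  if (anyNA(copd)) stop("`copd` must be TRUE/FALSE")
  ped <- age_years < 18
  if (any(ped & copd))
    stop("pediatric patients with COPD are not supported by the severity matrices")
  ifelse(ped, "pediatric_no_copd", ifelse(copd, "adult_copd", "adult_no_copd"))
}
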