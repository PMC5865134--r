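#' Age-gender stratum labels
#'
#' The 18 strata used throughout the package for indirect standardisation:
#' males and females crossed with nine 10-year age bands (0-9 through 80+).
#' The order is fixed (all male bands, then all female bands) and every
#' stratified table in the package follows it.
#'
#' @return Character vector of 18 unique labels, e.g. `"male 0-9"`.
#' @export
#' @examples
#' stratum_labels()
stratum_labels <- function() {
  ages <- c("0-9", "10-19", "20-29", "30-39", "40-49",
            "50-59", "60-69", "70-79", "80+")
  as.vector(vapply(c("male", "female"),
                   function(g) paste(g, ages), character(9L)))
}

.age_bands <- function() {
  c("0-9", "10-19", "20-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")
}

#' Default age-gender population pyramid
#'
#' Fixed stratum proportions used to split a region's total population into
#' the 18 age-gender strata. The shape is adult-skewed, loosely following a
#' developed-country resident population: a broad working-age plateau and a
#' tapering tail above 70. Genders are split evenly.
#'
#' @return Named numeric vector over [stratum_labels()], summing to 1.
#' @export
default_age_gender_pyramid <- function() {
  age_props <- c(0.12, 0.12, 0.13, 0.14, 0.14, 0.13, 0.11, 0.07, 0.04)
  p <- rep(age_props / 2, times = 2L)
  setNames(p, stratum_labels())
}

#' Default per-stratum baseline emergency rates
#'
#' Cases per resident over the study window for each age-gender stratum.
#' The age gradient mirrors the strong old-age skew of prehospital
#' diabetic-emergency caseloads (overall about 60-70 cases per 10,000
#' residents over a multi-year window, rising steeply beyond age 60);
#' male rates are set slightly above female rates.
#'
#' @return Named non-negative numeric vector over [stratum_labels()].
#' @export
default_baseline_rates <- function() {
  age_rates <- c(0.0008, 0.0015, 0.0020, 0.0030, 0.0050,
                 0.0080, 0.0120, 0.0200, 0.0300)
  r <- c(age_rates * 1.15, age_rates * 0.85)
  setNames(r, stratum_labels())
}
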