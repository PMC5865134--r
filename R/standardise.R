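#' Standard population rates per age-gender stratum
#'
#' Indirect standardisation step one: the state-wide caseload of each
#' age-gender stratum divided by the state-wide population of that stratum
#' gives the standard rate (SR), in cases per person over the study window.
#'
#' @param state_cases Data frame `stratum`, `cases` covering all 18 strata.
#' @param state_population Data frame `stratum`, `population` covering all
#'   18 strata with population > 0 wherever cases occur.
#' @return Data frame `stratum`, `sr` in [stratum_labels()] order.
#' @export
compute_standard_rates <- function(state_cases, state_population) {
  labs <- stratum_labels()
  cases <- state_cases$cases[match(labs, state_cases$stratum)]
  pop <- state_population$population[match(labs, state_population$stratum)]
  if (anyNA(cases) || anyNA(pop)) stop("tables must cover all 18 strata")
  if (any(cases < 0)) stop("negative caseload")
  if (any(pop <= 0 & cases > 0)) stop("zero population with nonzero cases")
  sr <- ifelse(pop > 0, cases / pop, 0)
  data.frame(stratum = labs, sr = sr, stringsAsFactors = FALSE)
}

#' Expected caseload per region by indirect standardisation
#'
#' Step two: each region's stratified population is multiplied by the
#' stratum standard rates and summed, `E_i = sum_g pop_ig * sr_g`.
#'
#' @param region_pop Long data frame `region_id`, `stratum`, `count`.
#' @param rates Data frame from [compute_standard_rates()].
#' @return Data frame `region_id`, `expected`, `erp` (region total
#'   population).
#' @export
compute_expected <- function(region_pop, rates) {
  labs <- stratum_labels()
  sr <- rates$sr[match(labs, rates$stratum)]
  if (anyNA(sr)) stop("rates must cover all 18 strata")
  ids <- unique(region_pop$region_id)
  pop <- .population_matrix(region_pop, ids, labs)
  data.frame(region_id = ids,
             expected = as.numeric(pop %*% sr),
             erp = as.numeric(rowSums(pop)),
             stringsAsFactors = FALSE)
}

#' Crude standardised incidence ratios
#'
#' `SIR_i = O_i / E_i`. Regions with `E = 0, O = 0` are flagged undefined
#' (`sir_defined = FALSE`, SIR `NA`) rather than silently zeroed; `E = 0`
#' with observed cases is inconsistent with the standardisation that
#' produced `E` and is an error.
#'
#' @param table Data frame with `region_id`, `observed`, `expected`.
#' @return Input columns plus `crude_sir` and `sir_defined`.
#' @export
compute_crude_sir <- function(table) {
  need <- c("region_id", "observed", "expected")
  if (!all(need %in% names(table))) {
    stop("table needs columns region_id, observed, expected")
  }
  if (any(table$observed < 0) || any(table$observed != round(table$observed))) {
    stop("observed must be non-negative integers")
  }
  if (any(table$expected < 0)) stop("expected must be non-negative")
  bad <- table$expected == 0 & table$observed > 0
  if (any(bad)) {
    stop("observed cases with zero expected caseload in region ",
         table$region_id[which(bad)[1L]])
  }
  undef <- table$expected == 0
  if (any(undef)) {
    warning(sum(undef), " region(s) with E = 0 flagged undefined and ",
            "excluded from modelling")
  }
  out <- table
  out$crude_sir <- ifelse(undef, NA_real_, table$observed / table$expected)
  out$sir_defined <- !undef
  out
}

#' Observed case rate per 10,000 residents
#'
#' @param table Data frame with `region_id`, `observed` and `erp`
#'   (estimated residential population, > 0).
#' @return Data frame `region_id`, `case_rate`.
#' @export
#' @examples
#' compute_case_rate(data.frame(region_id = "A", observed = 13, erp = 10000))
compute_case_rate <- function(table) {
  if (!all(c("region_id", "observed", "erp") %in% names(table))) {
    stop("table needs columns region_id, observed, erp")
  }
  if (any(table$erp <= 0)) stop("erp must be positive")
  data.frame(region_id = table$region_id,
             case_rate = 10000 * table$observed / table$erp,
             stringsAsFactors = FALSE)
}
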