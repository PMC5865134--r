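#' Assemble a simulation ground truth
#'
#' Container for the generative parameters of the synthetic BYM model:
#' covariate log-risk coefficients, random-effect precisions, the realised
#' spatial and unstructured effects, and the per-stratum baseline rates.
#' `u` is required to sum to zero within every connected component of the
#' adjacency graph (tolerance 1e-9), as the ICAR constraint demands.
#'
#' @param neighbors A [neighbor_structure()] defining the regions.
#' @param effects List with `u`, `v` as returned by
#'   [simulate_spatial_effects()], or NULL for all-zero effects.
#' @param beta Named list, one entry per covariate: a numeric vector of
#'   per-category log-risk coefficients whose first (reference) element
#'   is 0. Empty list for a null model.
#' @param tau_u,tau_v Positive precisions recorded as truth.
#' @param baseline_rates Named per-stratum rates; see
#'   [default_baseline_rates()].
#' @return Object of class `simulation_truth`.
#' @export
simulation_truth <- function(neighbors, effects = NULL, beta = list(),
                             tau_u = 10, tau_v = 10,
                             baseline_rates = default_baseline_rates()) {
  stopifnot(inherits(neighbors, "neighbor_structure"))
  n <- length(neighbors$region_ids)
  if (tau_u <= 0 || tau_v <= 0) stop("precisions must be positive")
  if (is.null(effects)) {
    effects <- list(u = setNames(rep(0, n), neighbors$region_ids),
                    v = setNames(rep(0, n), neighbors$region_ids))
  }
  if (length(effects$u) != n || length(effects$v) != n) {
    stop("effects must provide u and v for every region")
  }
  comp <- .graph_components(neighbors$neighbors)
  for (c in seq_len(max(comp))) {
    if (abs(sum(effects$u[comp == c])) > 1e-9) {
      stop("u must sum to zero within each connected component")
    }
  }
  if (any(baseline_rates < 0)) stop("baseline rates must be non-negative")
  for (b in beta) {
    if (length(b) < 2L || b[1L] != 0) {
      stop("each beta entry needs >= 2 categories with reference coefficient 0")
    }
  }
  structure(list(region_ids = neighbors$region_ids, beta = beta,
                 tau_u = tau_u, tau_v = tau_v,
                 u = effects$u, v = effects$v,
                 baseline_rates = baseline_rates),
            class = "simulation_truth")
}

#' Simulate stratified Poisson case counts
#'
#' Generates cases at the region-by-stratum level:
#' `O_ig ~ Poisson(pop_ig * rate_g * exp(x_i' beta + u_i + v_i))`,
#' so region totals follow the BYM Poisson model
#' `O_i ~ Poisson(E_i * exp(x_i' beta + u_i + v_i))` with truth-rate
#' expected caseloads `E_i = sum_g pop_ig * rate_g`. State-wide stratum
#' totals (cases and population) are returned alongside the region table so
#' standard rates can be re-derived downstream exactly as an indirect
#' standardisation would from real registry extracts.
#'
#' @param population Long data frame from [generate_population()].
#' @param truth A [simulation_truth()].
#' @param design Optional data frame of per-region covariate categories
#'   (integer codes, 1 = reference), one column per entry of `truth$beta`,
#'   rows aligned with the truth's region order; a `region_id` column, if
#'   present, is matched by id.
#' @param seed Integer seed.
#' @return Object of class `sim_counts`: list with `region_cases`
#'   (`region_id`, `observed`, `expected`, `erp`), `stratum_cases`
#'   (`stratum`, `cases`) and `stratum_population` (`stratum`,
#'   `population`).
#' @export
simulate_counts <- function(population, truth, design = NULL, seed = 1L) {
  stopifnot(inherits(truth, "simulation_truth"))
  labs <- stratum_labels()
  ids <- truth$region_ids
  pop <- .population_matrix(population, ids, labs)
  rates <- truth$baseline_rates[labs]
  if (anyNA(rates)) stop("baseline_rates must cover all 18 strata")
  xb <- rep(0, length(ids))
  if (length(truth$beta)) {
    if (is.null(design)) stop("truth has covariate effects but no design given")
    if (!is.null(design$region_id)) {
      design <- design[match(ids, design$region_id), , drop = FALSE]
      if (anyNA(design[[1L]])) stop("design does not cover all regions")
    }
    for (nm in names(truth$beta)) {
      cat_i <- as.integer(design[[nm]])
      if (is.null(design[[nm]]) || anyNA(cat_i)) {
        stop("design lacks categories for covariate ", nm)
      }
      b <- truth$beta[[nm]]
      if (min(cat_i) < 1L || max(cat_i) > length(b)) {
        stop("design category out of range for covariate ", nm)
      }
      xb <- xb + b[cat_i]
    }
  }
  risk <- exp(xb + as.numeric(truth$u) + as.numeric(truth$v))
  set.seed(as.integer(seed))
  lam <- pop * outer(risk, as.numeric(rates))
  O <- matrix(rpois(length(lam), lam), nrow = nrow(lam))
  structure(list(
    region_cases = data.frame(
      region_id = ids,
      observed = as.integer(rowSums(O)),
      expected = as.numeric(pop %*% as.numeric(rates)),
      erp = as.integer(rowSums(pop)),
      stringsAsFactors = FALSE
    ),
    stratum_cases = data.frame(stratum = labs, cases = as.integer(colSums(O)),
                               stringsAsFactors = FALSE),
    stratum_population = data.frame(stratum = labs,
                                    population = as.integer(colSums(pop)),
                                    stringsAsFactors = FALSE)
  ), class = "sim_counts")
}

# long population table -> regions x strata matrix in canonical order
.population_matrix <- function(population, ids, labs) {
  need <- c("region_id", "stratum", "count")
  if (!all(need %in% names(population))) {
    stop("population needs columns region_id, stratum, count")
  }
  pop <- matrix(0, length(ids), length(labs),
                dimnames = list(ids, labs))
  idx_r <- match(population$region_id, ids)
  idx_s <- match(population$stratum, labs)
  if (anyNA(idx_s)) stop("unknown stratum label in population table")
  keep <- !is.na(idx_r)
  pop[cbind(idx_r[keep], idx_s[keep])] <- population$count[keep]
  if (any(pop < 0)) stop("negative population count")
  covered <- ids %in% population$region_id
  if (!all(covered)) stop("population missing regions: ",
                          paste(head(ids[!covered]), collapse = ", "))
  pop
}
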