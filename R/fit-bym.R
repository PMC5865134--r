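#' Prior specification for the BYM model
#'
#' Defaults follow the diffuse ("uninformative") convention of classic
#' disease-mapping software: Gamma(0.5, 0.0005) on both random-effect
#' precisions and Normal(0, precision 1e-6) on the intercept and every
#' covariate coefficient. All hyperparameters are configurable.
#'
#' @param tau_u,tau_v Length-2 vectors `c(shape, rate)` of the Gamma priors
#'   on the ICAR and unstructured precisions.
#' @param intercept_prec,beta_prec Normal prior precisions (mean 0) on the
#'   intercept and coefficients.
#' @return List of class `bym_priors`.
#' @export
bym_priors <- function(tau_u = c(0.5, 0.0005), tau_v = c(0.5, 0.0005),
                       intercept_prec = 1e-6, beta_prec = 1e-6) {
  if (any(c(tau_u, tau_v) <= 0) || intercept_prec <= 0 || beta_prec <= 0) {
    stop("all hyperparameters must be strictly positive")
  }
  structure(list(tau_u = tau_u, tau_v = tau_v,
                 intercept_prec = intercept_prec, beta_prec = beta_prec),
            class = "bym_priors")
}

#' MCMC run configuration
#'
#' Defaults reproduce a full production run: two chains, 100,000 burn-in
#' sweeps, 500,000 further sweeps with every other draw kept. For test-bench
#' work a much shorter run (e.g. `mcmc_config(burn_in = 5000,
#' n_iter = 20000)`) is adequate for 80-region problems.
#'
#' @param n_chains Number of chains (>= 2 so convergence diagnostics apply).
#' @param burn_in Discarded initial sweeps per chain.
#' @param n_iter Post burn-in sweeps per chain.
#' @param thin Keep every `thin`-th post burn-in sweep.
#' @param seed Integer; chain `k` runs under `seed + k - 1`.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, burn_in = 100000L, n_iter = 500000L,
                        thin = 2L, seed = 1L) {
  if (n_chains < 2L) stop("n_chains must be >= 2 for convergence diagnostics")
  if (thin < 1L) stop("thin must be >= 1")
  if (burn_in < 0L || n_iter < thin) stop("invalid chain lengths")
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_iter = as.integer(n_iter),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' ICAR full conditional for one region
#'
#' Under the intrinsic CAR prior with equal weights, the conditional
#' distribution of `u_i` given the remaining effects is Normal with mean
#' equal to the average of the neighbours' effects and variance
#' `1 / (tau_u * n_i)` where `n_i` is the neighbour count.
#'
#' @param u Current effect vector (one value per region).
#' @param i Region index (1-based).
#' @param neighbors A [neighbor_structure()].
#' @param tau_u Positive ICAR precision.
#' @return List with `mean` and `variance`.
#' @export
#' @examples
#' ns <- neighbor_structure(c("a", "b", "c"), list(2:3, c(1L, 3L), 1:2))
#' icar_full_conditional(c(0, 0.2, 0.4), 1, ns, tau_u = 1)
icar_full_conditional <- function(u, i, neighbors, tau_u) {
  stopifnot(inherits(neighbors, "neighbor_structure"))
  if (tau_u <= 0) stop("tau_u must be positive")
  nb <- neighbors$neighbors[[i]]
  if (length(nb) == 0L) {
    stop("region ", neighbors$region_ids[i],
         " is an island; the ICAR conditional is undefined (degree 0)")
  }
  list(mean = mean(u[nb]), variance = 1 / (tau_u * length(nb)))
}

# Poisson log-likelihood of the region counts at fitted means mu
# (vectorised; the brute-force per-region loop in the tests is its oracle)
.poisson_loglik <- function(observed, mu) {
  if (any(mu < 0)) stop("negative fitted mean")
  sum(observed * log(mu) - mu - lgamma(observed + 1))
}

# design matrix with reference-cell coding from a data frame of categories
# (factors or integer codes; category 1 / first level is the reference)
.build_design <- function(categories, region_ids) {
  if (is.null(categories)) {
    return(list(X = matrix(0, length(region_ids), 0L),
                map = data.frame(covariate = character(0L),
                                 category = character(0L))))
  }
  df <- as.data.frame(categories, stringsAsFactors = FALSE)
  if (!is.null(df$region_id)) {
    idx <- match(region_ids, df$region_id)
    if (anyNA(idx)) stop("design does not cover all regions")
    df <- df[idx, setdiff(names(df), "region_id"), drop = FALSE]
  }
  if (nrow(df) != length(region_ids)) {
    stop("design rows do not match the number of regions")
  }
  cols <- list(); map_cov <- character(0L); map_cat <- character(0L)
  for (nm in names(df)) {
    f <- df[[nm]]
    if (!is.factor(f)) f <- factor(f)
    if (nlevels(f) < 2L) stop("covariate ", nm, " has a single category")
    m <- model.matrix(~f)[, -1L, drop = FALSE]
    colnames(m) <- paste0(nm, ":", levels(f)[-1L])
    cols[[nm]] <- m
    map_cov <- c(map_cov, rep(nm, ncol(m)))
    map_cat <- c(map_cat, levels(f)[-1L])
  }
  X <- do.call(cbind, cols)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("design columns are linearly dependent")
  }
  list(X = X, map = data.frame(covariate = map_cov, category = map_cat,
                               stringsAsFactors = FALSE))
}

#' Fit the BYM spatial Poisson model by MCMC
#'
#' Fits `O_i ~ Poisson(mu_i)`, `log mu_i = log E_i + alpha + x_i' beta +
#' u_i + v_i` with an intrinsic CAR prior on `u` (re-centred to zero mean
#' per connected component every sweep; island regions have `u_i` fixed at
#' 0 and rely on `v_i`) and iid Normal effects `v`. Sampling is
#' Metropolis-within-Gibbs: conjugate Gamma draws for the two precisions
#' and adaptive random-walk Metropolis for the intercept, coefficients and
#' each random effect, with step sizes adapted during burn-in only.
#'
#' @param cases Data frame with `region_id`, `observed` and `expected`
#'   (all `expected` > 0). Rows are matched to `neighbors` by id.
#' @param neighbors A [neighbor_structure()] covering every region in
#'   `cases`.
#' @param design Optional per-region covariate categories (data frame of
#'   factors/integer codes, first level = reference; may carry a
#'   `region_id` column for alignment).
#' @param priors A [bym_priors()].
#' @param config An [mcmc_config()].
#' @return Object of class `bym_fit`: per-chain thinned draws of
#'   `intercept`, `beta`, `u`, `v`, `tau_u`, `tau_v`, plus the model data
#'   and coefficient map. Use [summarize_posterior()], [compute_dic()] and
#'   [convergence_diagnostics()] on it.
#' @export
fit_bym <- function(cases, neighbors, design = NULL,
                    priors = bym_priors(), config = mcmc_config()) {
  stopifnot(inherits(neighbors, "neighbor_structure"),
            inherits(priors, "bym_priors"),
            inherits(config, "mcmc_config"))
  need <- c("region_id", "observed", "expected")
  if (!all(need %in% names(cases))) {
    stop("cases needs columns region_id, observed, expected")
  }
  idx <- match(neighbors$region_ids, cases$region_id)
  if (anyNA(idx)) {
    stop("adjacency covers regions absent from cases: ",
         paste(head(neighbors$region_ids[is.na(idx)]), collapse = ", "))
  }
  if (!all(cases$region_id %in% neighbors$region_ids)) {
    stop("cases contain regions absent from the adjacency")
  }
  cases <- cases[idx, , drop = FALSE]
  if (any(cases$expected <= 0)) {
    stop("all modelled regions need expected > 0 (exclude undefined-SIR ",
         "regions first)")
  }
  if (any(cases$observed < 0)) stop("negative observed count")
  ids <- neighbors$region_ids
  n <- length(ids)

  des <- .build_design(design, ids)
  comp <- .graph_components(neighbors$neighbors)
  deg <- vapply(neighbors$neighbors, length, integer(1L))
  # ICAR rank: for each component with >= 2 members, size - 1; islands drop out
  icar_rank <- sum(vapply(seq_len(max(comp)), function(c) {
    s <- sum(comp == c)
    if (s >= 2L) s - 1L else 0L
  }, integer(1L)))
  adj <- unlist(lapply(neighbors$neighbors, function(v) v - 1L))
  adj_ptr <- c(0L, cumsum(deg))

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    chains[[ch]] <- bym_chain_cpp(
      as.integer(cases$observed), as.numeric(cases$expected), des$X,
      as.integer(adj), as.integer(adj_ptr), as.integer(comp - 1L),
      as.numeric(icar_rank),
      priors$tau_u[1L], priors$tau_u[2L], priors$tau_v[1L], priors$tau_v[2L],
      priors$intercept_prec, priors$beta_prec,
      config$burn_in, config$n_iter, config$thin)
    colnames(chains[[ch]]$beta) <- colnames(des$X)
    colnames(chains[[ch]]$u) <- ids
    colnames(chains[[ch]]$v) <- ids
  }
  structure(list(chains = chains, cases = cases, region_ids = ids,
                 design = des$X, coef_map = des$map,
                 neighbors = neighbors, priors = priors, config = config),
            class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("bym_fit:", length(x$region_ids), "regions,",
      ncol(x$design), "coefficient(s),",
      length(x$chains), "chains x", nrow(x$chains[[1L]]$u), "kept draws\n")
  invisible(x)
}

# linear predictor eta draws (pooled across chains): ndraws x n matrix
.eta_draws <- function(fit) {
  do.call(rbind, lapply(fit$chains, function(ch) {
    eta <- ch$intercept + ch$u + ch$v
    if (ncol(ch$beta)) eta <- eta + ch$beta %*% t(fit$design)
    eta
  }))
}

# pooled draws of one named scalar/indexed parameter as iterations x chains
.param_matrix <- function(fit, component, index = NULL) {
  sapply(fit$chains, function(ch) {
    x <- ch[[component]]
    if (is.matrix(x)) x[, index] else x
  })
}
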