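# Shared fixtures: all test data is generated in code at run time.

# chain settings for test-bench fits (short but diagnostically usable)
desk_config <- function(seed = 1L) {
  mcmc_config(burn_in = 5000L, n_iter = 20000L, thin = 2L, seed = seed)
}
quick_config <- function(seed = 1L) {
  mcmc_config(burn_in = 1500L, n_iter = 6000L, thin = 2L, seed = seed)
}

# cache Queen structures per lattice size (they are deterministic)
.ns_cache <- new.env(parent = emptyenv())
grid_ns <- function(n_rows, n_cols) {
  key <- paste0(n_rows, "x", n_cols)
  if (is.null(.ns_cache[[key]])) {
    .ns_cache[[key]] <- queen_adjacency(generate_lattice(n_rows, n_cols))
  }
  .ns_cache[[key]]
}

# Full synthetic study: lattice, population, effects, counts, and the
# standardised case table ready for fit_bym().
make_study <- function(seed, n_rows = 8L, n_cols = 10L, beta = list(),
                       design = NULL, tau_u = 10, tau_v = 10,
                       null_effects = FALSE,
                       total_range = c(20000L, 100000L)) {
  lat <- generate_lattice(n_rows, n_cols)
  ns <- grid_ns(n_rows, n_cols)
  pop <- generate_population(lat, total_range = total_range, seed = seed)
  eff <- if (null_effects) NULL
         else simulate_spatial_effects(ns, tau_u, tau_v, seed = seed + 1L)
  tr <- simulation_truth(ns, eff, beta = beta, tau_u = tau_u, tau_v = tau_v)
  sim <- simulate_counts(pop, tr, design = design, seed = seed + 2L)
  sr <- compute_standard_rates(sim$stratum_cases, sim$stratum_population)
  ex <- compute_expected(pop, sr)
  cases <- data.frame(region_id = ex$region_id,
                      observed = sim$region_cases$observed,
                      expected = ex$expected,
                      erp = ex$erp,
                      stringsAsFactors = FALSE)
  list(lattice = lat, ns = ns, population = pop, truth = tr, sim = sim,
       rates = sr, cases = cases)
}

# random guillotine subdivision of the unit square into axis-aligned
# rectangles; shared cut coordinates are exactly equal doubles
random_rect_tiling <- function(n_rects, seed) {
  set.seed(seed)
  rects <- list(c(0, 1, 0, 1))  # x0 x1 y0 y1
  while (length(rects) < n_rects) {
    k <- sample.int(length(rects), 1L)
    r <- rects[[k]]
    if (runif(1) < 0.5) {
      cut <- runif(1, r[1] + 0.2 * (r[2] - r[1]), r[2] - 0.2 * (r[2] - r[1]))
      a <- c(r[1], cut, r[3], r[4]); b <- c(cut, r[2], r[3], r[4])
    } else {
      cut <- runif(1, r[3] + 0.2 * (r[4] - r[3]), r[4] - 0.2 * (r[4] - r[3]))
      a <- c(r[1], r[2], r[3], cut); b <- c(r[1], r[2], cut, r[4])
    }
    rects[[k]] <- a
    rects[[length(rects) + 1L]] <- b
  }
  polys <- lapply(rects, function(r) {
    cbind(c(r[1], r[2], r[2], r[1], r[1]), c(r[3], r[3], r[4], r[4], r[3]))
  })
  names(polys) <- sprintf("T%03d", seq_along(polys))
  list(polys = polys, rects = rects)
}

# independent Queen oracle for rectangle tilings: two rectangles touch iff
# their closed x- and y-intervals both intersect
rect_queen_oracle <- function(rects) {
  n <- length(rects)
  nb <- rep(list(integer(0L)), n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- rects[[i]]; b <- rects[[j]]
      if (max(a[1], b[1]) <= min(a[2], b[2]) + 1e-12 &&
          max(a[3], b[3]) <= min(a[4], b[4]) + 1e-12) {
        nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
      }
    }
  }
  nb
}

# correlation of covariate values across adjacent region pairs
neighbour_pair_cor <- function(values, ns) {
  ii <- integer(0L); jj <- integer(0L)
  for (i in seq_along(ns$neighbors)) {
    ii <- c(ii, rep(i, length(ns$neighbors[[i]])))
    jj <- c(jj, ns$neighbors[[i]])
  }
  cor(values[ii], values[jj])
}

# hand-built bym_fit carcass for posterior/DIC unit tests
fake_fit <- function(intercept_draws, observed, expected, n_regions = 1L) {
  k <- length(intercept_draws)
  ch <- list(intercept = intercept_draws,
             beta = matrix(0, k, 0L),
             u = matrix(0, k, n_regions),
             v = matrix(0, k, n_regions),
             tau_u = rep(1, k), tau_v = rep(1, k))
  structure(list(chains = list(ch),
                 cases = data.frame(region_id = as.character(seq_len(n_regions)),
                                    observed = observed, expected = expected),
                 region_ids = as.character(seq_len(n_regions)),
                 design = matrix(0, n_regions, 0L),
                 coef_map = data.frame(covariate = character(0L),
                                       category = character(0L))),
            class = "bym_fit")
}
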