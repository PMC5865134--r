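test_that("lattice geometry is deterministic with correct Queen degrees", {
  lat <- generate_lattice(2, 2)
  expect_length(lat$region_id, 4L)
  deg <- lengths(queen_adjacency(lat)$neighbors)
  expect_true(all(deg == 3L))  # corner touch counts on a 2x2 grid

  strip <- generate_lattice(1, 5)
  dstrip <- lengths(queen_adjacency(strip)$neighbors)
  expect_equal(dstrip, c(1L, 2L, 2L, 2L, 1L))  # path graph

  big <- generate_lattice(8, 10)
  expect_length(big$region_id, 80L)
  dbig <- lengths(queen_adjacency(big)$neighbors)
  interior <- big$grid_row %in% 2:7 & big$grid_col %in% 2:9
  expect_true(all(dbig[interior] == 8L))
  expect_identical(generate_lattice(3, 4), generate_lattice(3, 4))

  expect_error(generate_lattice(0, 5), "positive")
  expect_error(generate_lattice(1, 3), "at least 4")
})

test_that("population generation partitions totals and respects the seed", {
  lat <- generate_lattice(2, 3)
  p1 <- generate_population(lat, c(1000L, 5000L), seed = 42)
  p2 <- generate_population(lat, c(1000L, 5000L), seed = 42)
  expect_identical(p1, p2)

  totals <- tapply(p1$count, p1$region_id, sum)
  expect_true(all(totals >= 1000L & totals <= 5000L))
  expect_true(all(p1$count >= 0L))
  expect_equal(sort(unique(p1$stratum)), sort(stratum_labels()))

  pd <- generate_population(lat, c(1000L, 1000L), seed = 7)
  expect_true(all(tapply(pd$count, pd$region_id, sum) == 1000L))

  expect_error(generate_population(lat, c(10L, 5L)), "total_range")
})

test_that("covariate surfaces show the requested spatial correlation", {
  lat <- generate_lattice(8, 10)
  ns <- grid_ns(8, 10)
  for (s in 1:4) {
    x0 <- generate_covariates(lat, 1, spatial_corr = 0, seed = s)
    expect_lt(abs(neighbour_pair_cor(x0$X1, ns)), 0.2)
  }
  for (s in 1:3) {
    x9 <- generate_covariates(lat, 1, spatial_corr = 0.9, seed = s)
    expect_gt(neighbour_pair_cor(x9$X1, ns), 0.4)
  }
  expect_identical(generate_covariates(lat, 2, 0.5, seed = 3),
                   generate_covariates(lat, 2, 0.5, seed = 3))
  expect_error(generate_covariates(lat, 1, spatial_corr = 1), "spatial_corr")
  expect_error(generate_covariates(lat, 1, spatial_corr = -0.1), "spatial_corr")
})

test_that("ICAR draws are component-centred with the right scale", {
  # disconnected graph: two disjoint paths
  ns2 <- neighbor_structure(letters[1:6],
                            list(2L, c(1L, 3L), 2L, 5L, c(4L, 6L), 5L))
  eff <- simulate_spatial_effects(ns2, tau_u = 5, tau_v = 5, seed = 1)
  expect_lt(abs(sum(eff$u[1:3])), 1e-9)
  expect_lt(abs(sum(eff$u[4:6])), 1e-9)

  ns <- grid_ns(8, 10)
  effv <- simulate_spatial_effects(ns, tau_u = 1, tau_v = 1e12, seed = 2)
  expect_lt(max(abs(effv$v)), 1e-4)

  # empirical Var(v) ~ 1/tau_v pooled over many draws
  vs <- unlist(lapply(1:50, function(s) {
    simulate_spatial_effects(grid_ns(10, 20), 1, tau_v = 4, seed = s)$v
  }))
  expect_lt(abs(var(vs) - 0.25) / 0.25, 0.1)

  # quadform of draws ~ chi-square with icar-rank dof: E[tau * u'Qu] = rank
  qf <- vapply(1:200, function(s) {
    icar_quadform(simulate_spatial_effects(ns, tau_u = 3, tau_v = 1,
                                           seed = s)$u, ns) * 3
  }, numeric(1))
  expect_lt(abs(mean(qf) - 79) / 79, 0.06)

  expect_error(simulate_spatial_effects(ns, -1, 1), "positive")
})

test_that("icar_quadform matches the dense structure-matrix oracle", {
  ns <- grid_ns(3, 3)
  Q <- matrix(0, 9, 9)
  for (i in 1:9) {
    Q[i, i] <- length(ns$neighbors[[i]])
    Q[i, ns$neighbors[[i]]] <- -1
  }
  set.seed(5)
  for (k in 1:10) {
    u <- rnorm(9)
    expect_equal(icar_quadform(u, ns), drop(t(u) %*% Q %*% u),
                 tolerance = 1e-12)
  }
})

test_that("simulated counts follow the generative Poisson model", {
  lat <- generate_lattice(4, 5)
  ns <- grid_ns(4, 5)
  pop <- generate_population(lat, c(20000L, 60000L), seed = 9)
  tr <- simulation_truth(ns)  # beta = 0, u = v = 0

  ratios <- vapply(1:200, function(r) {
    sim <- simulate_counts(pop, tr, seed = r)
    sum(sim$region_cases$observed) / sum(sim$region_cases$expected)
  }, numeric(1))
  expect_gte(mean(ratios), 0.98)
  expect_lte(mean(ratios), 1.02)

  # bit-for-bit reproducibility
  expect_identical(simulate_counts(pop, tr, seed = 3),
                   simulate_counts(pop, tr, seed = 3))

  # zero expected -> zero observed, always
  zpop <- data.frame(region_id = rep(c("a", "b", "c", "d"), each = 18L),
                     stratum = rep(stratum_labels(), 4L),
                     count = c(rep(0L, 18L), rep(100L, 54L)))
  nsz <- neighbor_structure(c("a", "b", "c", "d"),
                            list(2L, c(1L, 3L), c(2L, 4L), 3L))
  trz <- simulation_truth(nsz)
  for (s in 1:5) {
    simz <- simulate_counts(zpop, trz, seed = s)
    expect_identical(simz$region_cases$observed[1L], 0L)
    expect_identical(simz$region_cases$expected[1L], 0)
  }

  # category effect scales mean O/E by exp(beta) relative to reference
  des <- data.frame(region_id = lat$region_id, g = rep(1:2, 10L))
  trb <- simulation_truth(ns, beta = list(g = c(0, 0.4)))
  oe <- vapply(1:30, function(r) {
    sim <- simulate_counts(pop, trb, design = des, seed = 100 + r)
    rc <- sim$region_cases
    in2 <- des$g == 2
    (sum(rc$observed[in2]) / sum(rc$expected[in2])) /
      (sum(rc$observed[!in2]) / sum(rc$expected[!in2]))
  }, numeric(1))
  expect_lt(abs(mean(oe) - exp(0.4)) / exp(0.4), 0.05)

  # truth validation
  expect_error(simulation_truth(ns, list(u = rep(1, 20), v = rep(0, 20))),
               "sum to zero")
  expect_error(
    simulation_truth(ns, baseline_rates = setNames(rep(-1, 18),
                                                   stratum_labels())),
    "non-negative")
})
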