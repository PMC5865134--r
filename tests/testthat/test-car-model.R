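test_that("ICAR full conditional matches the dense-precision oracle", {
  ns <- neighbor_structure(c("a", "b", "c"), list(2:3, c(1L, 3L), 1:2))
  fc <- icar_full_conditional(c(0, 0.2, 0.4), 1, ns, tau_u = 1)
  expect_equal(fc$mean, 0.3)
  expect_equal(fc$variance, 0.5)

  expect_equal(icar_full_conditional(rep(0, 3), 2, ns, 7)$mean, 0)
  expect_lt(icar_full_conditional(c(0, 0.2, 0.4), 1, ns, 1e12)$variance, 1e-11)

  # oracle: condition the joint N(0, (tau Q)^-) density by completing the
  # square in the dense precision matrix
  ns5 <- grid_ns(2, 3)
  tau <- 2.5
  Q <- matrix(0, 6, 6)
  for (i in 1:6) {
    Q[i, i] <- length(ns5$neighbors[[i]])
    Q[i, ns5$neighbors[[i]]] <- -1
  }
  set.seed(4)
  u <- rnorm(6)
  for (i in 1:6) {
    fc <- icar_full_conditional(u, i, ns5, tau)
    expect_equal(fc$mean, -sum(Q[i, -i] * u[-i]) / Q[i, i], tolerance = 1e-12)
    expect_equal(fc$variance, 1 / (tau * Q[i, i]), tolerance = 1e-12)
  }

  isl <- neighbor_structure(c("a", "b", "c"),
                            list(2L, 1L, integer(0L)))
  expect_error(icar_full_conditional(c(0, 0, 0), 3, isl, 1), "island")
})

test_that("Poisson log-likelihood matches a per-region brute-force loop", {
  set.seed(12)
  O <- rpois(10, 20)
  mu <- runif(10, 5, 40)
  oracle <- 0
  for (i in 1:10) oracle <- oracle + dpois(O[i], mu[i], log = TRUE)
  expect_equal(carmap:::.poisson_loglik(O, mu), oracle, tolerance = 1e-10)
})

test_that("Gelman-Rubin statistic behaves at its analytic anchors", {
  # identical chains: B = 0, so the classic statistic is sqrt((n-1)/n) ~ 1
  x <- rnorm(500)
  expect_equal(gelman_rubin(cbind(x, x))$rhat, sqrt(499 / 500))
  expect_equal(gelman_rubin(cbind(x, x))$rhat, 1.0, tolerance = 0.01)

  set.seed(3)
  far <- cbind(rnorm(200, 0), rnorm(200, 100))
  gr <- gelman_rubin(far)
  W <- mean(apply(far, 2, var))
  B <- 200 * var(colMeans(far))
  expect_equal(gr$rhat, sqrt((199 / 200 * W + B / 200) / W), tolerance = 1e-12)
  expect_gt(gr$rhat, 1.1)

  set.seed(8)
  same <- matrix(rnorm(20000), ncol = 2)
  expect_lt(gelman_rubin(same)$rhat, 1.05)
  expect_true(all(diff(gelman_rubin(same)$trajectory$iteration) > 0))

  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "two chains")
  expect_error(gelman_rubin(matrix(rnorm(8), ncol = 2)), "length >= 10")
})

test_that("batch-means MC error tracks iid and autocorrelated draws", {
  set.seed(15)
  ok <- 0L
  for (k in 1:5) {
    x <- rnorm(5000)
    iid <- sd(x) / sqrt(5000)
    ok <- ok + (abs(mc_error(x) - iid) / iid < 0.3)
  }
  expect_gte(ok, 4L)

  expect_equal(mc_error(rep(2.5, 500)), 0)

  set.seed(16)
  bigger <- 0L
  for (k in 1:5) {
    ar <- as.numeric(arima.sim(list(ar = 0.9), 5000))
    bigger <- bigger + (mc_error(ar) > 1.5 * sd(ar) / sqrt(5000))
  }
  expect_gte(bigger, 4L)

  expect_error(mc_error(rnorm(50)), "100 draws")
})

test_that("DIC components match the closed-form Poisson deviance oracle", {
  # two-draw toy: one region, O = 2, mu in {1, 3}
  fit <- fake_fit(log(c(1, 3)), observed = 2L, expected = 1)
  d <- compute_dic(fit)
  dev <- function(mu) -2 * (2 * log(mu) - mu - log(2))
  dbar <- (dev(1) + dev(3)) / 2
  dhat <- dev(2)
  expect_equal(d$dbar, dbar, tolerance = 1e-12)
  expect_equal(d$dhat, dhat, tolerance = 1e-12)
  expect_equal(d$pd, dbar - dhat, tolerance = 1e-12)
  expect_equal(d$dic, 2 * dbar - dhat, tolerance = 1e-12)

  # degenerate posterior: no spread, pd = 0, dic = dbar
  dg <- compute_dic(fake_fit(c(log(2), log(2)), observed = 2L, expected = 1))
  expect_equal(dg$pd, 0)
  expect_equal(dg$dic, dg$dbar)
})

test_that("posterior summaries follow the percentile rule", {
  draws <- matrix((1:1000) / 100, ncol = 1)
  s <- summarize_posterior(draws, region_ids = "r1")
  expect_equal(s$sir, 5.005)
  # linear-interpolation order-statistics oracle, computed by hand:
  # h = (n-1) p + 1 -> x[floor(h)] + frac(h) * (x[floor(h)+1] - x[floor(h)])
  expect_equal(s$lower, 0.25 + 0.975 * 0.01, tolerance = 1e-12)
  expect_equal(s$upper, 9.75 + 0.025 * 0.01, tolerance = 1e-12)

  const <- summarize_posterior(matrix(rep(2, 50), ncol = 1),
                               region_ids = "r1")
  expect_equal(const$lower, const$upper)
  expect_equal(const$sir, 2)

  # boundary convention: lower bound exactly 1 is not elevated
  ones <- summarize_posterior(matrix(rep(1, 50), ncol = 1), region_ids = "r1")
  expect_false(ones$elevated)

  expect_error(summarize_posterior(matrix(numeric(0), ncol = 1)), "draws")
})

test_that("the BYM sampler keeps u centred and recovers strong signals", {
  st <- make_study(seed = 51, n_rows = 4, n_cols = 5, null_effects = TRUE,
                   total_range = c(5000L, 20000L))
  cases <- st$cases
  # one region with a five-fold elevated caseload among nulls
  cases$observed[7L] <- as.integer(round(5 * cases$expected[7L]))
  fit <- fit_bym(cases, st$ns, config = quick_config(seed = 2))

  for (ch in fit$chains) {
    expect_lt(max(abs(rowMeans(ch$u))), 1e-9)  # per-sweep centring
  }
  s <- summarize_posterior(fit)
  expect_true(s$elevated[7L])
  expect_gt(s$sir[7L], 2)
  # the spike stays localised: no other region is pulled anywhere near it,
  # and at most a couple of nulls flag on ordinary Poisson noise
  expect_true(all(s$sir[-7L] < 2))
  expect_lte(sum(s$elevated[-7L]), 2L)
})

test_that("u draws are centred per component on disconnected maps", {
  left <- generate_lattice(2, 2)
  right <- generate_lattice(2, 2)
  polys <- c(left$polygons,
             setNames(lapply(right$polygons, function(m) {
               m[, 1] <- m[, 1] + 5; m
             }), paste0("S", right$region_id)))
  ns <- queen_adjacency(polys)
  expect_equal(neighbor_summary(ns)$n_components, 2L)
  cases <- data.frame(region_id = ns$region_ids,
                      observed = rpois(8, 50), expected = rep(50, 8))
  fit <- fit_bym(cases, ns, config = quick_config(seed = 4))
  comp <- neighbor_summary(ns)$component
  for (ch in fit$chains) {
    for (cc in 1:2) {
      expect_lt(max(abs(rowMeans(ch$u[, comp == cc]))), 1e-9)
    }
  }
})

test_that("independent seeds give posterior summaries within MC error", {
  st <- make_study(seed = 52, n_rows = 4, n_cols = 5)
  f1 <- fit_bym(st$cases, st$ns, config = desk_config(seed = 11))
  f2 <- fit_bym(st$cases, st$ns, config = desk_config(seed = 99))
  for (f in list(f1, f2)) expect_s3_class(f, "bym_fit")
  a1 <- unlist(lapply(f1$chains, `[[`, "intercept"))
  a2 <- unlist(lapply(f2$chains, `[[`, "intercept"))
  expect_lt(abs(mean(a1) - mean(a2)), 3 * (mc_error(a1) + mc_error(a2)))
  s1 <- summarize_posterior(f1); s2 <- summarize_posterior(f2)
  expect_lt(max(abs(s1$sir - s2$sir) / s1$sir), 0.05)
})

test_that("smoothing shrinks small-count regions toward the null", {
  hits <- 0L; total <- 0L
  for (r in 1:12) {
    st <- make_study(seed = 600 + r, n_rows = 4, n_cols = 5,
                     null_effects = TRUE, total_range = c(500L, 2000L))
    fit <- fit_bym(st$cases, st$ns, config = quick_config(seed = r))
    s <- summarize_posterior(fit)
    crude <- st$cases$observed / st$cases$expected
    low <- which.min(st$cases$expected)
    total <- total + 1L
    hits <- hits + (abs(s$sir[low] - 1) < abs(crude[low] - 1))
  }
  expect_gte(hits / total, 0.9)
})

test_that("fit_bym validates its inputs", {
  st <- make_study(seed = 53, n_rows = 2, n_cols = 2)
  bad <- st$cases; bad$expected[1L] <- 0
  expect_error(fit_bym(bad, st$ns, config = quick_config()), "expected > 0")
  expect_error(fit_bym(st$cases[-1L, ], st$ns, config = quick_config()),
               "absent")
  expect_error(mcmc_config(n_chains = 1L), "n_chains")
  expect_error(bym_priors(tau_u = c(0, 1)), "positive")
})
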