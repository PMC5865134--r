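test_that("quintile categorisation balances, honours printed cut-points", {
  q <- quintile_categorise(1:10)
  expect_equal(as.integer(table(q$category)), rep(2L, 5L))
  expect_length(q$boundaries, 4L)

  # published socioeconomic-index cut-points: value below the first cut is
  # category 1, a value equal to the top cut belongs to category 5
  irsd <- c(957.20, 983.35, 999.52, 1037.75)
  q1 <- quintile_categorise(c(950, 1037.75), boundaries = irsd, name = "IRSD")
  expect_equal(q1$category, c(1L, 5L))

  expect_error(quintile_categorise(rep(1, 10)), "distinct")
  expect_error(quintile_categorise(1:10, boundaries = c(3, 2, 5, 7)),
               "increasing")
})

test_that("quintile membership is invariant to affine rescaling", {
  set.seed(9)
  for (k in 1:5) {
    x <- rnorm(80)
    expect_identical(quintile_categorise(x)$category,
                     quintile_categorise(3.7 * x + 11)$category)
  }
})

test_that("pre-categorised covariates bypass quintile computation", {
  aria <- precategorised(rep(1:6, length.out = 20), name = "ARIA",
                         direction = "1 = major city")
  expect_null(aria$boundaries)
  expect_equal(max(aria$category), 6L)
  expect_error(precategorised(c(0L, 1L), "bad"), "invalid")
})

test_that("a correlated index family is reduced to its representative", {
  fam <- c("IRSD", "IRSAD", "IEO", "IER")
  nms <- c("ethnicity", "IRSAD", "IRSD", "IEO", "IER", "vehicle")
  kept <- select_seifa_representative(nms, fam, "IRSD")
  expect_identical(kept, c("ethnicity", "IRSD", "vehicle"))
  expect_identical(select_seifa_representative("IRSD", "IRSD", "IRSD"), "IRSD")
  expect_error(select_seifa_representative(nms, fam, "XYZ"), "not in the family")
  expect_error(select_seifa_representative(c("a", "b"), fam, "IRSD"),
               "not found")
})

test_that("univariable screening ranks covariates by DIC", {
  st <- make_study(seed = 71, n_rows = 4, n_cols = 5, null_effects = TRUE,
                   beta = list(A = c(0, 0.8)),
                   design = data.frame(region_id = grid_ns(4, 5)$region_ids,
                                       A = rep(1:2, 10L)))
  cats <- list(A = rep(1:2, 10L))
  scr1 <- univariable_screen(st$cases, st$ns, cats,
                             config = quick_config(seed = 1))
  expect_length(scr1, 1L)  # single covariate in, single fit out
  expect_true(is.finite(scr1[[1L]]$dic))
  expect_equal(scr1[[1L]]$table$ratio[1L], 1)  # reference category

  # significance flags agree between log scale and ratio scale
  tab <- scr1[[1L]]$table
  nonref <- !is.na(tab$lower)
  expect_identical(tab$significant[nonref],
                   tab$lower[nonref] > 1 | tab$upper[nonref] < 1)

  # a failing covariate is reported, not fatal
  cats2 <- list(A = rep(1:2, 10L), broken = rep(1L, 20L))
  expect_warning(scr2 <- univariable_screen(st$cases, st$ns, cats2,
                                            config = quick_config(seed = 1)),
                 "broken")
  broken <- Filter(function(f) !is.null(f$error), scr2)
  expect_length(broken, 1L)
  expect_identical(broken[[1L]]$name, "broken")
})

test_that("the predictive covariate outranks null covariates by DIC", {
  wins <- 0L
  for (r in 1:3) {
    set.seed(900 + r)
    des <- data.frame(region_id = grid_ns(4, 5)$region_ids,
                      A = sample(rep(1:2, 10L)))
    st <- make_study(seed = 900 + r, n_rows = 4, n_cols = 5,
                     null_effects = TRUE, beta = list(A = c(0, 0.8)),
                     design = des)
    cats <- list(A = des$A,
                 B = sample(rep(1:2, 10L)),
                 C = sample(rep(1:2, 10L)))
    scr <- univariable_screen(st$cases, st$ns, cats,
                              config = quick_config(seed = r))
    wins <- wins + (scr[[1L]]$name == "A")
  }
  expect_gte(wins, 2L)
})

test_that("stepwise selection retains a single significant covariate", {
  set.seed(81)
  des <- data.frame(region_id = grid_ns(4, 5)$region_ids,
                    A = sample(rep(1:2, 10L)))
  st <- make_study(seed = 81, n_rows = 4, n_cols = 5, null_effects = TRUE,
                   beta = list(A = c(0, 0.9)), design = des)
  scr <- univariable_screen(st$cases, st$ns, list(A = des$A),
                            config = quick_config(seed = 1))
  sw <- stepwise_multivariable(st$cases, st$ns, scr,
                               config = quick_config(seed = 2))
  expect_identical(sw$included, "A")
  expect_true(any(sw$table$significant[sw$table$covariate == "A"]))
  expect_true(is.finite(sw$dic))
  expect_identical(sw$steps$covariate, "A")
  expect_true(sw$steps$retained)
})

test_that("an all-null stepwise run may fall back to intercept-only", {
  set.seed(82)
  st <- make_study(seed = 82, n_rows = 4, n_cols = 5, null_effects = TRUE)
  scr <- univariable_screen(st$cases, st$ns,
                            list(B = sample(rep(1:2, 10L))),
                            config = quick_config(seed = 3))
  sw <- tryCatch(stepwise_multivariable(st$cases, st$ns, scr,
                                        config = quick_config(seed = 4)),
                 warning = function(w) {
                   expect_match(conditionMessage(w), "intercept-only")
                   suppressWarnings(
                     stepwise_multivariable(st$cases, st$ns, scr,
                                            config = quick_config(seed = 4)))
                 })
  expect_s3_class(sw, "stepwise_fit")
  expect_true(length(sw$included) %in% c(0L, 1L))
})
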