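#' Generate a rectangular region lattice
#'
#' Builds a grid of unit-square regions used as a synthetic stand-in for an
#' administrative map (the default analysis scale, an 8 x 10 lattice of 80
#' regions, approximates a state of ~79 local government areas). Cells are
#' laid out row-major; cell (r, c) occupies the unit square with lower-left
#' corner (c - 1, r - 1).
#'
#' @param n_rows,n_cols Positive integers; `n_rows * n_cols` must be >= 4.
#' @return An object of class `region_lattice`: a list with `region_id`
#'   (character), `grid_row`, `grid_col`, `n_rows`, `n_cols` and `polygons`
#'   (named list of closed coordinate rings, one 5 x 2 matrix per region).
#' @export
#' @examples
#' lat <- generate_lattice(2, 2)
#' lat$region_id
generate_lattice <- function(n_rows, n_cols) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      !is.finite(n_rows) || !is.finite(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != as.integer(n_rows) || n_cols != as.integer(n_cols)) {
    stop("n_rows and n_cols must be positive integers")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols
  if (n < 4L) stop("lattice must contain at least 4 regions")
  grid_row <- rep(seq_len(n_rows), each = n_cols)
  grid_col <- rep(seq_len(n_cols), times = n_rows)
  region_id <- sprintf("R%03d", seq_len(n))
  polygons <- vector("list", n)
  for (i in seq_len(n)) {
    x0 <- grid_col[i] - 1; y0 <- grid_row[i] - 1
    polygons[[i]] <- cbind(
      x = c(x0, x0 + 1, x0 + 1, x0, x0),
      y = c(y0, y0, y0 + 1, y0 + 1, y0)
    )
  }
  names(polygons) <- region_id
  structure(
    list(region_id = region_id, grid_row = grid_row, grid_col = grid_col,
         n_rows = n_rows, n_cols = n_cols, polygons = polygons),
    class = "region_lattice"
  )
}

#' @export
print.region_lattice <- function(x, ...) {
  cat("region_lattice:", x$n_rows, "x", x$n_cols, "grid,",
      length(x$region_id), "unit-square regions\n")
  invisible(x)
}

#' Generate stratified region populations
#'
#' Draws a total resident population for every region uniformly from
#' `total_range` and splits it across the 18 age-gender strata by
#' multinomial sampling with fixed pyramid proportions. The default range
#' (20,000 - 100,000) gives expected caseloads of a few hundred per region
#' under [default_baseline_rates()], matching the scale at which real
#' prehospital caseloads are mapped.
#'
#' @param lattice A `region_lattice` (or any object with a `region_id`
#'   character vector).
#' @param total_range Length-2 integer vector, min >= 18.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param pyramid Named stratum proportions summing to 1; see
#'   [default_age_gender_pyramid()].
#' @return Long-format data frame with columns `region_id`, `stratum`,
#'   `count`; 18 rows per region, strata in [stratum_labels()] order.
#' @export
generate_population <- function(lattice, total_range = c(20000L, 100000L),
                                seed = 1L,
                                pyramid = default_age_gender_pyramid()) {
  ids <- if (inherits(lattice, "region_lattice")) lattice$region_id
         else as.character(lattice$region_id)
  if (length(ids) == 0L) stop("lattice has no regions")
  if (length(total_range) != 2L || any(total_range < 18) ||
      total_range[1] > total_range[2]) {
    stop("total_range must be an increasing pair with min >= 18")
  }
  labs <- stratum_labels()
  if (!identical(sort(names(pyramid)), sort(labs)) ||
      abs(sum(pyramid) - 1) > 1e-8) {
    stop("pyramid must be named over the 18 strata and sum to 1")
  }
  pyramid <- pyramid[labs]
  set.seed(as.integer(seed))
  n <- length(ids)
  totals <- sample.int(total_range[2] - total_range[1] + 1L, n,
                       replace = TRUE) + total_range[1] - 1L
  counts <- vapply(totals,
                   function(t) as.integer(rmultinom(1L, t, pyramid)),
                   integer(18L))
  data.frame(
    region_id = rep(ids, each = 18L),
    stratum = rep(labs, times = n),
    count = as.integer(counts),
    stringsAsFactors = FALSE
  )
}

#' Generate spatially correlated area-level covariates
#'
#' Produces continuous covariate surfaces over the lattice, emulating
#' area-level indices such as socioeconomic scores or ethnic composition.
#' Independent standard-normal noise is smoothed over the Queen adjacency
#' graph: `x = (1 - rho) (I - rho * Wbar)^-1 z`, where `Wbar` is the
#' row-standardised adjacency matrix, so `spatial_corr = rho = 0` returns
#' iid noise and values near 1 give strongly clustered surfaces. Each
#' covariate is standardised to zero mean, unit variance.
#'
#' @param lattice A `region_lattice`.
#' @param n_covariates Number of covariates (>= 1).
#' @param spatial_corr Smoothing weight in \[0, 1).
#' @param seed Integer seed.
#' @return Data frame: `region_id` plus columns `X1`, `X2`, ...
#' @export
generate_covariates <- function(lattice, n_covariates = 1L,
                                spatial_corr = 0, seed = 1L) {
  if (n_covariates < 1) stop("n_covariates must be >= 1")
  if (spatial_corr < 0 || spatial_corr >= 1) {
    stop("spatial_corr must lie in [0, 1)")
  }
  ns <- queen_adjacency(lattice)
  n <- length(ns$region_ids)
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n * n_covariates), n, n_covariates)
  if (spatial_corr > 0) {
    Wbar <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- ns$neighbors[[i]]
      if (length(nb)) Wbar[i, nb] <- 1 / length(nb)
    }
    x <- (1 - spatial_corr) * solve(diag(n) - spatial_corr * Wbar, z)
  } else {
    x <- z
  }
  x <- scale(x)
  out <- data.frame(region_id = ns$region_ids, stringsAsFactors = FALSE)
  for (k in seq_len(n_covariates)) out[[paste0("X", k)]] <- as.numeric(x[, k])
  out
}
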