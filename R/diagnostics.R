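#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-or-more-chain diagnostic: with `m` chains of length `n`,
#' within-chain variance `W` (mean of chain variances) and between-chain
#' variance `B = n * var(chain means)`,
#' `Rhat = sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1 indicate the
#' chains have mixed; a trajectory of `Rhat` over growing prefixes is
#' returned for Brooks-Gelman-Rubin-style visual inspection.
#'
#' @param chains Matrix (iterations x chains) or list of equal-length
#'   numeric vectors; at least two chains of length >= 10.
#' @param n_points Number of prefix checkpoints in the trajectory.
#' @return List with `rhat` and `trajectory` (data frame `iteration`,
#'   `rhat`).
#' @export
#' @examples
#' x <- matrix(rnorm(2000), ncol = 2)
#' gelman_rubin(x)$rhat
gelman_rubin <- function(chains, n_points = 20L) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("need at least two chains")
  n <- nrow(chains)
  if (n < 10L) stop("chains must have length >= 10")
  rhat_at <- function(m) {
    x <- chains[seq_len(m), , drop = FALSE]
    W <- mean(apply(x, 2L, var))
    B <- m * var(colMeans(x))
    if (W == 0) return(1)
    sqrt(((m - 1) / m * W + B / m) / W)
  }
  pts <- unique(round(seq(10L, n, length.out = min(n_points, n - 9L))))
  list(rhat = rhat_at(n),
       trajectory = data.frame(iteration = pts,
                               rhat = vapply(pts, rhat_at, numeric(1L))))
}

#' Batch-means Monte Carlo standard error
#'
#' Splits the draws into 50 equal consecutive batches (trailing remainder
#' dropped) and reports `sd(batch means) / sqrt(50)` -- an autocorrelation-
#' robust standard error of the posterior-mean estimate. The usual
#' convergence check requires it below 5% of the posterior SD.
#'
#' @param draws Numeric vector of >= 100 MCMC draws of one parameter.
#' @return Non-negative scalar.
#' @export
mc_error <- function(draws) {
  n <- length(draws)
  if (n < 100L) stop("need at least 100 draws for batch means")
  nb <- 50L
  m <- n %/% nb
  bm <- colMeans(matrix(draws[seq_len(nb * m)], nrow = m))
  sd(bm) / sqrt(nb)
}

#' Convergence diagnostics for a fitted BYM model
#'
#' Gelman-Rubin statistic and batch-means MC error (with its ratio to the
#' posterior SD) for every monitored parameter: intercept, each covariate
#' coefficient, both precisions, and each region's smoothed SIR.
#'
#' @param fit A [fit_bym()] result.
#' @return Data frame: `parameter`, `rhat`, `mc_error`, `post_sd`,
#'   `mc_error_ratio`.
#' @export
convergence_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  mats <- list(intercept = .param_matrix(fit, "intercept"),
               tau_u = .param_matrix(fit, "tau_u"),
               tau_v = .param_matrix(fit, "tau_v"))
  for (j in seq_len(ncol(fit$design))) {
    mats[[colnames(fit$design)[j]]] <- .param_matrix(fit, "beta", j)
  }
  sir <- lapply(fit$chains, function(ch) {
    eta <- ch$intercept + ch$u + ch$v
    if (ncol(ch$beta)) eta <- eta + ch$beta %*% t(fit$design)
    exp(eta)
  })
  for (i in seq_along(fit$region_ids)) {
    mats[[paste0("sir[", fit$region_ids[i], "]")]] <-
      sapply(sir, function(s) s[, i])
  }
  out <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    pooled <- as.numeric(m)
    psd <- sd(pooled)
    mce <- mc_error(pooled)
    data.frame(parameter = nm,
               rhat = gelman_rubin(m)$rhat,
               mc_error = mce,
               post_sd = psd,
               mc_error_ratio = if (psd > 0) mce / psd else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
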