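#' Summarise smoothed SIRs from a fitted BYM model
#'
#' For each region the smoothed standardised incidence ratio draws are
#' `SIR_i = mu_i / E_i = exp(alpha + x_i' beta + u_i + v_i)`. The point
#' estimate is the posterior median and the 95% credible interval the
#' equal-tailed 2.5/97.5 percentiles (linear interpolation) across chains
#' pooled after burn-in and thinning. A region is flagged `elevated` when
#' the lower CrI bound strictly exceeds 1.
#'
#' @param fit A [fit_bym()] result (or a ndraws x n matrix of SIR draws
#'   with `region_ids` supplied).
#' @param prob Credible-interval mass (default 0.95).
#' @param region_ids Region ids when `fit` is a bare matrix.
#' @return Data frame of class `sir_summary`: `region_id`, `sir`, `lower`,
#'   `upper`, `elevated`.
#' @export
summarize_posterior <- function(fit, prob = 0.95, region_ids = NULL) {
  if (inherits(fit, "bym_fit")) {
    draws <- exp(.eta_draws(fit))
    region_ids <- fit$region_ids
  } else {
    draws <- as.matrix(fit)
    if (is.null(region_ids)) region_ids <- colnames(draws)
    if (is.null(region_ids)) region_ids <- as.character(seq_len(ncol(draws)))
  }
  if (nrow(draws) == 0L) stop("no posterior draws")
  a <- (1 - prob) / 2
  qs <- apply(draws, 2L, quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
  out <- data.frame(region_id = region_ids,
                    sir = qs[2L, ], lower = qs[1L, ], upper = qs[3L, ],
                    stringsAsFactors = FALSE)
  out$elevated <- out$lower > 1
  class(out) <- c("sir_summary", "data.frame")
  out
}

#' Deviance information criterion for a fitted BYM model
#'
#' Poisson deviance `D(mu) = -2 sum_i [O_i log mu_i - mu_i - log(O_i!)]`;
#' `Dbar` is its posterior mean over the pooled draws, `Dhat` the deviance
#' at the posterior mean of `mu`, `pD = Dbar - Dhat` the effective number
#' of parameters, and `DIC = Dbar + pD = 2 Dbar - Dhat`. Smaller is better.
#'
#' @param fit A [fit_bym()] result.
#' @return List of class `dic_result`: `dbar`, `dhat`, `pd`, `dic`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "bym_fit"))
  mu <- exp(.eta_draws(fit))
  mu <- sweep(mu, 2L, fit$cases$expected, `*`)
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("non-positive or non-finite fitted mean in posterior draws")
  }
  O <- fit$cases$observed
  dev_of <- function(m) -2 * .poisson_loglik(O, m)
  devs <- apply(mu, 1L, dev_of)
  dbar <- mean(devs)
  dhat <- dev_of(colMeans(mu))
  structure(list(dbar = dbar, dhat = dhat, pd = dbar - dhat,
                 dic = 2 * dbar - dhat),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC %.2f (Dbar %.2f, pD %.2f)\n", x$dic, x$dbar, x$pd))
  invisible(x)
}

#' Posterior coefficient table on the SIR-ratio scale
#'
#' Per-category rate ratios `exp(beta)` against the reference category,
#' with equal-tailed 95% CrIs and a significance flag (CrI excluding 0 on
#' the log scale, equivalently the ratio CrI excluding 1).
#'
#' @param fit A [fit_bym()] result with covariates.
#' @param prob Credible-interval mass.
#' @return Data frame: `covariate`, `category`, `ratio`, `lower`, `upper`,
#'   `significant`; reference categories are included with ratio 1.
#' @export
coef_table <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "bym_fit"))
  p <- ncol(fit$design)
  if (p == 0L) {
    return(data.frame(covariate = character(0L), category = character(0L),
                      ratio = numeric(0L), lower = numeric(0L),
                      upper = numeric(0L), significant = logical(0L)))
  }
  a <- (1 - prob) / 2
  beta <- do.call(rbind, lapply(fit$chains, `[[`, "beta"))
  rows <- list()
  for (cov in unique(fit$coef_map$covariate)) {
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = cov, category = "1 (reference)", ratio = 1,
      lower = NA_real_, upper = NA_real_, significant = FALSE,
      stringsAsFactors = FALSE)
    for (j in which(fit$coef_map$covariate == cov)) {
      q <- quantile(beta[, j], probs = c(a, 0.5, 1 - a), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cov, category = fit$coef_map$category[j],
        ratio = exp(q[2L]), lower = exp(q[1L]), upper = exp(q[3L]),
        significant = q[1L] > 0 || q[3L] < 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
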