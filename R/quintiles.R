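#' Quintile categorisation of an area-level covariate
#'
#' Divides a continuous covariate into `n_categories` ordered categories at
#' its 20/40/60/80 percentiles (linear-interpolation percentile rule).
#' Assignment is left-closed on the upper side: a value equal to a cut
#' point belongs to the upper category, matching the conventional
#' "category 1: < b1, ..., category 5: >= b4" presentation of area-index
#' tables.
#'
#' @param values Numeric vector, one value per region; at least
#'   `n_categories` distinct values.
#' @param n_categories Number of categories (default 5 = quintiles).
#' @param name Covariate name carried through to model output.
#' @param direction Optional human-readable label for category 1 (e.g.
#'   `"1 = most disadvantage"`).
#' @param boundaries Optional externally given cut points (length
#'   `n_categories - 1`, strictly increasing) overriding the percentile
#'   computation -- used when a covariate arrives with published cut-offs.
#' @return Object of class `quintile_categorisation`: list with `name`,
#'   `boundaries`, `category` (integer in 1..n per region), `direction`.
#' @export
#' @examples
#' quintile_categorise(1:10)$category  # two regions per category
quintile_categorise <- function(values, n_categories = 5L, name = "covariate",
                                direction = NULL, boundaries = NULL) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing covariate values")
  if (is.null(boundaries)) {
    if (length(unique(values)) < n_categories) {
      stop("need at least ", n_categories, " distinct values")
    }
    probs <- seq_len(n_categories - 1L) / n_categories
    boundaries <- as.numeric(quantile(values, probs, names = FALSE))
  } else {
    if (length(boundaries) != n_categories - 1L) {
      stop("boundaries must have length n_categories - 1")
    }
  }
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  category <- findInterval(values, boundaries) + 1L
  structure(list(name = name, boundaries = boundaries,
                 category = category, direction = direction),
            class = "quintile_categorisation")
}

#' @export
print.quintile_categorisation <- function(x, ...) {
  cat("quintile_categorisation '", x$name, "': ",
      length(x$boundaries) + 1L, " categories, cut points ",
      paste(signif(x$boundaries, 6L), collapse = ", "), "\n", sep = "")
  if (!is.null(x$direction)) cat("  ", x$direction, "\n", sep = "")
  invisible(x)
}

#' Wrap a pre-categorised covariate
#'
#' Some covariates arrive with externally defined categories (e.g. a
#' six-class remoteness index) rather than being cut at quintiles; this
#' wraps them in the same container so the regression machinery treats
#' them uniformly.
#'
#' @param category Integer category codes (1 = reference).
#' @param name Covariate name.
#' @param direction Optional label for category 1.
#' @return A `quintile_categorisation` with `boundaries = NULL`.
#' @export
precategorised <- function(category, name, direction = NULL) {
  category <- as.integer(category)
  if (anyNA(category) || min(category) < 1L) stop("invalid category codes")
  structure(list(name = name, boundaries = NULL,
                 category = category, direction = direction),
            class = "quintile_categorisation")
}
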