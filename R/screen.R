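#' Univariable covariate screening by spatial regression
#'
#' Fits one BYM model per covariate (reference-cell coding against
#' category 1) and returns the fits ranked by ascending DIC -- the order
#' in which the stepwise multivariable procedure will consider them. A
#' failure in one covariate's fit is reported and does not abort the
#' screen.
#'
#' @param cases Data frame `region_id`, `observed`, `expected`.
#' @param neighbors A [neighbor_structure()].
#' @param categorisations Named list of [quintile_categorise()] /
#'   [precategorised()] objects (or bare category vectors) aligned with
#'   `neighbors$region_ids`.
#' @param priors A [bym_priors()].
#' @param config An [mcmc_config()].
#' @return List of class `covariate_screen`; each element has `name`,
#'   `table` (per-category ratios, CrIs, significance), `dic`, `category`
#'   and `error` (NULL on success). Sorted by DIC, failed fits last.
#' @export
univariable_screen <- function(cases, neighbors, categorisations,
                               priors = bym_priors(), config = mcmc_config()) {
  if (!length(categorisations)) stop("no covariates supplied")
  nm <- names(categorisations)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- vapply(categorisations, function(q) {
      if (inherits(q, "quintile_categorisation")) q$name else NA_character_
    }, character(1L))
    if (anyNA(nm)) stop("categorisations must be named")
    names(categorisations) <- nm
  }
  fits <- lapply(nm, function(name) {
    q <- categorisations[[name]]
    cat_i <- if (inherits(q, "quintile_categorisation")) q$category
             else as.integer(q)
    if (length(cat_i) != length(neighbors$region_ids)) {
      return(list(name = name, table = NULL, dic = Inf, category = cat_i,
                  error = "categorisation does not cover all regions"))
    }
    res <- tryCatch({
      design <- data.frame(x = factor(cat_i))
      names(design) <- name
      fit <- fit_bym(cases, neighbors, design, priors, config)
      list(name = name, table = coef_table(fit),
           dic = compute_dic(fit)$dic, category = cat_i, error = NULL)
    }, error = function(e) {
      warning("covariate ", name, " failed: ", conditionMessage(e))
      list(name = name, table = NULL, dic = Inf, category = cat_i,
           error = conditionMessage(e))
    })
    res
  })
  fits <- fits[order(vapply(fits, `[[`, numeric(1L), "dic"))]
  structure(fits, class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  cat("univariable screen (", length(x), " covariates, ascending DIC):\n",
      sep = "")
  for (f in x) {
    cat(sprintf("  %-20s DIC %s%s\n", f$name,
                if (is.finite(f$dic)) sprintf("%.2f", f$dic) else "failed",
                if (is.null(f$error)) "" else paste0("  [", f$error, "]")))
  }
  invisible(x)
}

#' Select one representative from a correlated covariate family
#'
#' Overlapping indices (e.g. the four SEIFA socioeconomic indices) are
#' reduced to a single configured representative before multivariable
#' modelling; the remaining family members are dropped from the ranked
#' list.
#'
#' @param screen A [univariable_screen()] result (or character vector of
#'   covariate names).
#' @param family Character vector of family member names.
#' @param representative The member to keep.
#' @return The screen (or name vector) with the non-representative family
#'   members removed.
#' @export
select_seifa_representative <- function(screen, family,
                                        representative = "IRSD") {
  nms <- if (is.character(screen)) screen
         else vapply(screen, `[[`, character(1L), "name")
  if (!representative %in% family) {
    stop("representative '", representative, "' is not in the family")
  }
  if (!representative %in% nms) {
    stop("representative '", representative, "' not found among covariates")
  }
  drop <- nms %in% setdiff(family, representative)
  out <- if (is.character(screen)) screen[!drop] else screen[!drop]
  if (!is.character(screen)) class(out) <- class(screen)
  out
}

#' Stepwise multivariable spatial regression ordered by DIC
#'
#' Starting from the univariable DIC ranking, covariates are added to the
#' joint BYM model one at a time (lowest univariable DIC first). After
#' each addition the newcomer is retained if and only if at least one of
#' its category coefficients has a 95% CrI excluding zero on the log scale;
#' otherwise it is removed and not revisited. Covariates enter and leave
#' as whole blocks, and earlier acceptances are never re-examined
#' (forward-only selection).
#'
#' @param cases,neighbors,priors,config As in [univariable_screen()].
#' @param screen A `covariate_screen` (ranked); failed fits are skipped.
#' @return List of class `stepwise_fit`: `included` (names in entry
#'   order), `table` (final-model coefficient table), `dic`, `fit` (the
#'   final [fit_bym()] object), `steps` (per-candidate decision log).
#'   An intercept-only outcome (nothing retained) is flagged with
#'   `included = character(0)`.
#' @export
stepwise_multivariable <- function(cases, neighbors, screen,
                                   priors = bym_priors(),
                                   config = mcmc_config()) {
  stopifnot(inherits(screen, "covariate_screen"))
  ranked <- Filter(function(f) is.null(f$error), screen)
  if (!length(ranked)) stop("ranked covariate list is empty")
  included <- character(0L)
  cats <- list()
  best_fit <- NULL
  steps <- list()
  for (f in ranked) {
    trial <- c(cats, setNames(list(factor(f$category)), f$name))
    design <- as.data.frame(trial)
    names(design) <- names(trial)
    fit <- fit_bym(cases, neighbors, design, priors, config)
    tab <- coef_table(fit)
    keep <- any(tab$significant[tab$covariate == f$name])
    steps[[length(steps) + 1L]] <- data.frame(
      covariate = f$name, univariable_dic = f$dic,
      retained = keep, stringsAsFactors = FALSE)
    if (keep) {
      included <- c(included, f$name)
      cats <- trial
      best_fit <- fit
    }
  }
  if (is.null(best_fit)) {
    warning("no covariate retained; final model is intercept-only")
    best_fit <- fit_bym(cases, neighbors, NULL, priors, config)
  }
  structure(list(included = included,
                 table = coef_table(best_fit),
                 dic = compute_dic(best_fit)$dic,
                 fit = best_fit,
                 steps = do.call(rbind, steps)),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("stepwise spatial regression: ",
      if (length(x$included)) paste(x$included, collapse = " + ")
      else "(intercept only)",
      sprintf("; DIC %.2f\n", x$dic), sep = "")
  invisible(x)
}
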