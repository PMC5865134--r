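#' Percent change in risk implied by an SIR
#'
#' `(sir - 1) * 100`: the signed percentage by which an area's risk
#' differs from the standard population (SIR 0.70 = 30% reduced risk,
#' SIR 2.02 = 102% increased risk). The exact value is returned; round to
#' the nearest integer for display.
#'
#' @param sir Positive SIR (vectorised).
#' @return Signed percentage(s), exact.
#' @export
#' @examples
#' round(percent_risk_change(c(0.70, 1, 2.02)))
percent_risk_change <- function(sir) {
  if (any(!is.finite(sir)) || any(sir <= 0)) stop("sir must be positive")
  (sir - 1) * 100
}

#' Case-mix summary of individual case records
#'
#' Totals, counts and percentages by outcome type and gender (one decimal
#' place), and the median and interquartile range of age
#' (linear-interpolation percentiles). Records with missing type or gender
#' are tallied in an `"unknown"` bucket, never dropped; missing ages are
#' excluded from the age summary with their count reported.
#'
#' @param records Data frame with columns `type`, `gender`, `age`.
#' @return List of class `case_mix_summary`: `n_total`, `by_type` and
#'   `by_gender` (data frames with `count`, `percent`), `age_median`,
#'   `age_iqr` (length 2), `age_missing`.
#' @export
case_mix_summary <- function(records) {
  if (!nrow(records)) stop("no case records")
  if (!all(c("type", "gender", "age") %in% names(records))) {
    stop("records need columns type, gender, age")
  }
  bucket <- function(x) {
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- "unknown"
    x
  }
  n <- nrow(records)
  tab <- function(x) {
    t <- table(bucket(x))
    data.frame(level = names(t), count = as.integer(t),
               percent = round(100 * as.integer(t) / n, 1L),
               stringsAsFactors = FALSE)
  }
  age <- records$age[!is.na(records$age)]
  structure(list(
    n_total = n,
    by_type = tab(records$type),
    by_gender = tab(records$gender),
    age_median = if (length(age)) median(age) else NA_real_,
    age_iqr = if (length(age)) as.numeric(quantile(age, c(0.25, 0.75)))
              else c(NA_real_, NA_real_),
    age_missing = n - length(age)
  ), class = "case_mix_summary")
}

#' @export
print.case_mix_summary <- function(x, ...) {
  cat("case mix:", x$n_total, "cases\n")
  for (part in c("by_type", "by_gender")) {
    d <- x[[part]]
    cat(" ", sub("^by_", "", part), ":",
        paste(sprintf("%s %d (%.1f%%)", d$level, d$count, d$percent),
              collapse = ", "), "\n")
  }
  cat(sprintf("  age median [IQR]: %g [%g, %g]\n",
              x$age_median, x$age_iqr[1L], x$age_iqr[2L]))
  invisible(x)
}

#' Export smoothed SIRs as choropleth-ready GeoJSON
#'
#' Writes an RFC 7946 FeatureCollection of region polygons, each feature
#' carrying `region_id`, the smoothed SIR, CrI bounds and the elevated
#' flag as properties, at full numeric precision.
#'
#' @param geometry A `region_lattice` or named list of closed coordinate
#'   rings covering every region in `summary`.
#' @param summary A [summarize_posterior()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_sir_geojson <- function(geometry, summary, path) {
  polys <- if (inherits(geometry, "region_lattice")) geometry$polygons
           else geometry
  missing <- setdiff(summary$region_id, names(polys))
  if (length(missing)) {
    stop("no geometry for region(s): ", paste(missing, collapse = ", "))
  }
  features <- lapply(seq_len(nrow(summary)), function(i) {
    id <- summary$region_id[i]
    ring <- unname(lapply(seq_len(nrow(polys[[id]])), function(r) {
      as.numeric(polys[[id]][r, ])
    }))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(region_id = id,
                           sir = summary$sir[i],
                           lower = summary$lower[i],
                           upper = summary$upper[i],
                           elevated = summary$elevated[i]))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection",
                                features = features),
                           auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Combined per-region SIR table
#'
#' One row per region in the layout of a supplementary caseload table:
#' observed cases, case rate per 10,000 residents, expected caseload,
#' crude SIR, smoothed SIR with CrI, and the elevated flag. Written (when
#' `path` is given) as CSV with full-precision decimal printing so a
#' re-import reproduces the numbers bit-for-bit.
#'
#' @param crude Data frame from [compute_crude_sir()] including a
#'   `case_rate` column (see [compute_case_rate()]) or an `erp` column
#'   from which it is derived.
#' @param smoothed A [summarize_posterior()] result aligned by region id.
#' @param path Optional CSV output path.
#' @return The combined data frame (columns `region_id`, `observed`,
#'   `case_rate`, `expected`, `crude_sir`, `smoothed_sir`, `lower`,
#'   `upper`, `elevated`), invisibly when written.
#' @export
sir_table <- function(crude, smoothed, path = NULL) {
  if (!all(smoothed$region_id %in% crude$region_id) ||
      !all(crude$region_id %in% smoothed$region_id)) {
    stop("crude and smoothed tables cover different regions")
  }
  crude <- crude[match(smoothed$region_id, crude$region_id), , drop = FALSE]
  if (is.null(crude$case_rate)) {
    crude$case_rate <- compute_case_rate(crude)$case_rate
  }
  out <- data.frame(region_id = smoothed$region_id,
                    observed = crude$observed,
                    case_rate = crude$case_rate,
                    expected = crude$expected,
                    crude_sir = crude$crude_sir,
                    smoothed_sir = smoothed$sir,
                    lower = smoothed$lower,
                    upper = smoothed$upper,
                    elevated = smoothed$elevated,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    printed <- out
    for (cl in names(printed)) {
      if (is.double(printed[[cl]])) {
        printed[[cl]] <- sprintf("%.17g", printed[[cl]])
      }
    }
    write.csv(printed, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
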