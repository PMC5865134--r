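#' Export a region lattice as GeoJSON
#'
#' FeatureCollection of Polygons with `region_id`, `grid_row`, `grid_col`
#' properties.
#'
#' @param lattice A `region_lattice`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_lattice_geojson <- function(lattice, path) {
  stopifnot(inherits(lattice, "region_lattice"))
  features <- lapply(seq_along(lattice$region_id), function(i) {
    m <- lattice$polygons[[i]]
    ring <- unname(lapply(seq_len(nrow(m)), function(r) as.numeric(m[r, ])))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(region_id = lattice$region_id[i],
                           grid_row = lattice$grid_row[i],
                           grid_col = lattice$grid_col[i]))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection",
                                features = features),
                           auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read region polygons from a GeoJSON FeatureCollection
#'
#' Accepts Polygon features whose properties carry a `region_id`; only the
#' outer ring is used. The returned named list of coordinate rings feeds
#' directly into [queen_adjacency()].
#'
#' @param path GeoJSON file path.
#' @return Named list of closed n x 2 coordinate matrices.
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$type) || g$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  polys <- list()
  for (f in g$features) {
    if (is.null(f$geometry$type) || f$geometry$type != "Polygon") {
      stop("only Polygon features are supported")
    }
    id <- f$properties$region_id
    if (is.null(id)) stop("feature lacks a region_id property")
    ring <- f$geometry$coordinates[[1L]]
    polys[[as.character(id)]] <-
      do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
  }
  polys
}

#' Write a full synthetic dataset to disk
#'
#' Plain-text export of one simulated study: population, covariate and
#' case CSVs, ground-truth JSON, and the lattice GeoJSON -- everything a
#' downstream standardisation/model run reads.
#'
#' @param dir Output directory (created if absent).
#' @param lattice A `region_lattice`.
#' @param population Long population data frame.
#' @param counts A `sim_counts` object.
#' @param truth A `simulation_truth`.
#' @param covariates Optional covariate data frame.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, lattice, population, counts, truth,
                             covariates = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(population, file.path(dir, "population.csv"), row.names = FALSE)
  write.csv(counts$region_cases, file.path(dir, "region_cases.csv"),
            row.names = FALSE)
  write.csv(counts$stratum_cases, file.path(dir, "stratum_cases.csv"),
            row.names = FALSE)
  write.csv(counts$stratum_population, file.path(dir, "stratum_population.csv"),
            row.names = FALSE)
  if (!is.null(covariates)) {
    write.csv(covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  }
  tr <- list(beta = truth$beta, tau_u = truth$tau_u, tau_v = truth$tau_v,
             u = as.list(setNames(as.numeric(truth$u), names(truth$u))),
             v = as.list(setNames(as.numeric(truth$v), names(truth$v))),
             baseline_rates = as.list(truth$baseline_rates))
  writeLines(jsonlite::toJSON(tr, auto_unbox = TRUE, digits = NA),
             file.path(dir, "truth.json"))
  export_lattice_geojson(lattice, file.path(dir, "lattice.geojson"))
  invisible(dir)
}
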