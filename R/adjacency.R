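#' Construct a neighbour structure
#'
#' Validated container for an areal adjacency graph with equal (binary)
#' weights, the structure used by the intrinsic CAR prior. Symmetry and the
#' absence of self-neighbours are enforced at construction.
#'
#' @param region_ids Character vector of unique region identifiers.
#' @param neighbors List (one element per region) of integer vectors of
#'   neighbour positions (1-based indices into `region_ids`).
#' @return Object of class `neighbor_structure` with elements `region_ids`
#'   and `neighbors` (sorted index vectors).
#' @export
neighbor_structure <- function(region_ids, neighbors) {
  region_ids <- as.character(region_ids)
  n <- length(region_ids)
  if (anyDuplicated(region_ids)) stop("duplicate region ids")
  if (length(neighbors) != n) stop("neighbors must have one entry per region")
  neighbors <- lapply(neighbors, function(v) sort(unique(as.integer(v))))
  for (i in seq_len(n)) {
    nb <- neighbors[[i]]
    if (length(nb) && (min(nb) < 1L || max(nb) > n)) {
      stop("neighbour index out of range for region ", region_ids[i])
    }
    if (i %in% nb) stop("self-neighbour at region ", region_ids[i])
    for (j in nb) {
      if (!(i %in% neighbors[[j]])) {
        stop("asymmetric adjacency: ", region_ids[i], " lists ",
             region_ids[j], " but not vice versa")
      }
    }
  }
  structure(list(region_ids = region_ids, neighbors = neighbors),
            class = "neighbor_structure")
}

#' @export
print.neighbor_structure <- function(x, ...) {
  s <- neighbor_summary(x)
  cat("neighbor_structure:", length(x$region_ids), "regions;",
      "degree median", s$median_degree, "range",
      paste0("[", s$min_degree, ", ", s$max_degree, "];"),
      s$n_components, "component(s)\n")
  invisible(x)
}

# snap a coordinate to the 1e-9 grid used for exact-geometry comparisons
.snap <- function(x) round(x * 1e9)

# TRUE if point p lies on the closed segment a-b (snapped integer coords)
.on_segment <- function(p, a, b) {
  cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  if (cross != 0) return(FALSE)
  p[1] >= min(a[1], b[1]) && p[1] <= max(a[1], b[1]) &&
    p[2] >= min(a[2], b[2]) && p[2] <= max(a[2], b[2])
}

# any vertex of ring A on the boundary of ring B (snapped coords)
.touches_one_way <- function(A, B) {
  nb <- nrow(B)
  for (v in seq_len(nrow(A) - 1L)) {
    p <- A[v, ]
    for (e in seq_len(nb - 1L)) {
      if (.on_segment(p, B[e, ], B[e + 1L, ])) return(TRUE)
    }
  }
  FALSE
}

#' Queen-contiguity adjacency from region polygons
#'
#' Two regions are neighbours if their boundaries share at least one point
#' -- a common edge segment or a single corner (the Queen rule). All
#' neighbour pairs receive equal weight. Coordinates are snapped to a 1e-9
#' grid before comparison, so exact tilings (lattices, guillotine rectangle
#' subdivisions) are handled without geometric tolerance tuning.
#'
#' @param polygons A `region_lattice`, or a named list of closed coordinate
#'   rings (n x 2 matrices whose first and last rows coincide). Names are
#'   the region ids and must be unique.
#' @return A [neighbor_structure()].
#' @export
#' @examples
#' queen_adjacency(generate_lattice(2, 2))  # every cell has 3 neighbours
queen_adjacency <- function(polygons) {
  if (inherits(polygons, "region_lattice")) polygons <- polygons$polygons
  ids <- names(polygons)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("polygons must be a named list with unique region ids")
  }
  n <- length(polygons)
  rings <- lapply(polygons, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2L || nrow(m) < 4L) stop("each polygon needs >= 3 vertices")
    apply(m, 2L, .snap)
  })
  bbox <- t(vapply(rings, function(m) {
    c(min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2]))
  }, numeric(4L)))
  neighbors <- rep(list(integer(0L)), n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (bbox[i, 1] > bbox[j, 2] || bbox[j, 1] > bbox[i, 2] ||
          bbox[i, 3] > bbox[j, 4] || bbox[j, 3] > bbox[i, 4]) next
      if (.touches_one_way(rings[[i]], rings[[j]]) ||
          .touches_one_way(rings[[j]], rings[[i]])) {
        neighbors[[i]] <- c(neighbors[[i]], j)
        neighbors[[j]] <- c(neighbors[[j]], i)
      }
    }
  }
  neighbor_structure(ids, neighbors)
}

#' Write a neighbour structure to a GAL file
#'
#' GeoDa-dialect GAL: a header line with the region count, then for each
#' region a line `id degree` followed by a line of neighbour ids
#' (blank for islands).
#'
#' @param ns A [neighbor_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(ns, path) {
  stopifnot(inherits(ns, "neighbor_structure"))
  ids <- ns$region_ids
  lines <- character(1L + 2L * length(ids))
  lines[1L] <- as.character(length(ids))
  k <- 2L
  for (i in seq_along(ids)) {
    nb <- ns$neighbors[[i]]
    lines[k] <- paste(ids[i], length(nb))
    lines[k + 1L] <- paste(ids[nb], collapse = " ")
    k <- k + 2L
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a neighbour structure from a GAL file
#'
#' Accepts both the bare-count header written by [write_gal()] and the
#' four-token GeoDa header (`0 n shapefile key`). Symmetry is validated;
#' an asymmetric file is rejected naming the offending pair.
#'
#' @param path GAL file path.
#' @return A [neighbor_structure()].
#' @export
read_gal <- function(path) {
  raw <- readLines(path)
  if (!length(raw)) stop("empty GAL file")
  head_tok <- strsplit(trimws(raw[1L]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(
    if (length(head_tok) >= 2L) head_tok[2L] else head_tok[1L]))
  if (is.na(n) || n < 1L) stop("line 1: malformed GAL header")
  if (length(raw) < 1L + 2L * n) stop("GAL file truncated: expected ", n,
                                      " region records")
  ids <- character(n); degs <- integer(n); nb_ids <- vector("list", n)
  for (i in seq_len(n)) {
    li <- 2L * i
    tok <- strsplit(trimws(raw[li]), "\\s+")[[1L]]
    if (length(tok) != 2L || is.na(suppressWarnings(as.integer(tok[2L])))) {
      stop("line ", li, ": expected 'id degree', got '", raw[li], "'")
    }
    ids[i] <- tok[1L]
    degs[i] <- as.integer(tok[2L])
    nb_line <- trimws(raw[li + 1L])
    nb_ids[[i]] <- if (nzchar(nb_line)) strsplit(nb_line, "\\s+")[[1L]]
                   else character(0L)
    if (length(nb_ids[[i]]) != degs[i]) {
      stop("line ", li + 1L, ": region ", ids[i], " declares degree ",
           degs[i], " but lists ", length(nb_ids[[i]]), " neighbours")
    }
  }
  if (anyDuplicated(ids)) stop("duplicate region ids in GAL file")
  neighbors <- lapply(nb_ids, function(v) {
    idx <- match(v, ids)
    if (anyNA(idx)) stop("unknown neighbour id: ", v[which(is.na(idx))[1L]])
    idx
  })
  neighbor_structure(ids, neighbors)
}

# connected components by breadth-first search; integer label per region
.graph_components <- function(neighbors) {
  n <- length(neighbors)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      fresh <- neighbors[[i]][comp[neighbors[[i]]] == 0L]
      comp[fresh] <- cur
      queue <- c(queue, fresh)
    }
  }
  comp
}

#' Summarise a neighbour structure
#'
#' Degree order statistics and connected-component count -- the figures a
#' disease-mapping analysis reports about its adjacency graph (e.g. a
#' median of five neighbours ranging one to nine for Victorian LGAs).
#'
#' @param ns A [neighbor_structure()].
#' @return List: `median_degree`, `min_degree`, `max_degree`,
#'   `n_components`, `degrees` (named integer vector), `component`
#'   (integer label per region).
#' @export
neighbor_summary <- function(ns) {
  stopifnot(inherits(ns, "neighbor_structure"))
  deg <- vapply(ns$neighbors, length, integer(1L))
  comp <- .graph_components(ns$neighbors)
  list(median_degree = median(deg), min_degree = min(deg),
       max_degree = max(deg), n_components = max(comp),
       degrees = setNames(deg, ns$region_ids), component = comp)
}
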