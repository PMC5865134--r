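#' Simulate BYM random effects with known ground truth
#'
#' Draws the spatially structured effect `u` from the intrinsic CAR
#' (ICAR) distribution with precision matrix `tau_u * (D - W)` via the
#' eigendecomposition pseudo-inverse (an exact draw on the subspace
#' orthogonal to the null space), re-centred to zero mean within each
#' connected component of the adjacency graph, and the unstructured effect
#' `v` iid Normal(0, 1/tau_v). Island regions (degree 0) receive `u = 0`.
#'
#' @param neighbors A [neighbor_structure()].
#' @param tau_u,tau_v Positive precisions.
#' @param seed Integer seed.
#' @return List with numeric vectors `u` and `v` (named by region id).
#' @export
simulate_spatial_effects <- function(neighbors, tau_u, tau_v, seed = 1L) {
  stopifnot(inherits(neighbors, "neighbor_structure"))
  n <- length(neighbors$region_ids)
  if (n == 0L) stop("neighbour structure has no regions")
  if (tau_u <= 0 || tau_v <= 0) stop("precisions must be positive")
  set.seed(as.integer(seed))
  Q <- .icar_structure_matrix(neighbors)
  e <- eigen(Q, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-10
  u <- rep(0, n)
  if (any(pos)) {
    z <- rnorm(sum(pos))
    u <- as.numeric(e$vectors[, pos, drop = FALSE] %*%
                      (z / sqrt(tau_u * e$values[pos])))
  }
  comp <- .graph_components(neighbors$neighbors)
  for (c in seq_len(max(comp))) {
    m <- comp == c
    u[m] <- u[m] - mean(u[m])
  }
  deg <- vapply(neighbors$neighbors, length, integer(1L))
  u[deg == 0L] <- 0
  v <- rnorm(n, 0, 1 / sqrt(tau_v))
  list(u = setNames(u, neighbors$region_ids),
       v = setNames(v, neighbors$region_ids))
}

# D - W: the ICAR structure matrix (graph Laplacian with equal weights)
.icar_structure_matrix <- function(neighbors) {
  n <- length(neighbors$region_ids)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- neighbors$neighbors[[i]]
    Q[i, i] <- length(nb)
    Q[i, nb] <- -1
  }
  Q
}

#' ICAR quadratic form
#'
#' Computes `u' (D - W) u = sum over neighbour pairs (u_i - u_j)^2`, the
#' kernel of the ICAR log density (-2 log-density up to a constant, scaled
#' by the precision). Evaluated pairwise without forming the dense matrix.
#'
#' @param u Numeric vector of effects, one per region.
#' @param neighbors A [neighbor_structure()].
#' @return Non-negative scalar.
#' @export
icar_quadform <- function(u, neighbors) {
  stopifnot(inherits(neighbors, "neighbor_structure"))
  if (length(u) != length(neighbors$region_ids)) {
    stop("u must have one value per region")
  }
  s <- 0
  for (i in seq_along(u)) {
    for (j in neighbors$neighbors[[i]]) {
      if (j > i) s <- s + (u[i] - u[j])^2
    }
  }
  s
}
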