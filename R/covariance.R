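#' Density grid for the threshold sweep
#'
#' Graph metrics are computed at every density of this grid and summed into
#' an area-under-curve summary. The default sweeps 20% (the lowest density
#' at which group covariance graphs remain fully connected) to 60% (above
#' which positive-edge budgets run out) in steps of 1%, i.e. 41 grid points.
#'
#' @param rho_min,rho_max,step Grid bounds and spacing, all in (0, 1].
#' @return Numeric vector of densities with class `density_grid`.
#' @export
density_grid <- function(rho_min = 0.20, rho_max = 0.60, step = 0.01) {
  if (!(rho_min > 0 && rho_min <= rho_max && rho_max <= 1))
    stop("need 0 < rho_min <= rho_max <= 1")
  n <- (rho_max - rho_min) / step
  if (abs(n - round(n)) > 1e-8)
    stop("step does not divide the density range")
  grid <- rho_min + step * seq(0L, round(n))
  structure(grid, class = "density_grid")
}

.check_variance <- function(M, what) {
  sds <- apply(M, 2L, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad))
    stop("zero-variance region(s) in ", what, " (correlation undefined): ",
         paste(colnames(M)[bad] %||% bad, collapse = ", "))
  invisible(sds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.new_covariance_graph <- function(weights, directed, property_pair, group) {
  P <- nrow(weights)
  npairs <- if (directed) P * (P - 1L) else P * (P - 1L) / 2
  pos <- if (directed) sum(weights > 0) else sum(weights[upper.tri(weights)] > 0)
  structure(list(weights = weights, directed = directed,
                 property_pair = property_pair, group = group,
                 retained_fraction = pos / npairs),
            class = "covariance_graph")
}

#' Same-property structural covariance graph of one group
#'
#' Correlates every pair of regions across the subjects of one group
#' (Pearson), zeroes the diagonal, and excludes negative edges by setting
#' them to zero — negative covariance carries no meaning for the weighted
#' graph metrics used downstream. The share of surviving edges is recorded
#' as `retained_fraction`.
#'
#' @param M Residualized subjects x regions matrix (one group, one property).
#' @param property Label stored with the graph.
#' @param group Group label stored with the graph.
#' @return A `covariance_graph`: symmetric nonnegative `weights` with zero
#'   diagonal, `directed = FALSE`, and `retained_fraction` (share of
#'   unordered region pairs with positive weight).
#' @examples
#' M <- matrix(rnorm(300), 30, 10)
#' g <- structural_covariance(M)
#' isSymmetric(g$weights); g$retained_fraction
#' @export
structural_covariance <- function(M, property = "property", group = "group") {
  M <- as.matrix(M)
  if (nrow(M) < 3L) stop("need at least 3 subjects")
  .check_variance(M, deparse(substitute(M)))
  W <- stats::cor(M)
  W[W < 0] <- 0
  diag(W) <- 0
  dimnames(W) <- list(colnames(M), colnames(M))
  .new_covariance_graph(W, directed = FALSE,
                        property_pair = c(property, property), group = group)
}

#' Cross-property covariance graph (directed) of one group
#'
#' Correlates property 1 in region i with property 2 in region j across the
#' same subjects, for all ordered region pairs, yielding an asymmetric
#' matrix: entry (i, j) measures how property 2 elsewhere covaries with
#' property 1 here. Self-loops (the diagonal) are zeroed and negative edges
#' excluded, as in the same-property graphs.
#'
#' @param M1,M2 Residualized subjects x regions matrices over the same
#'   subjects (aligned rows) and the same cortical regions.
#' @param property_pair Length-2 label, e.g. `c("CT", "SA")`.
#' @param group Group label.
#' @return A directed `covariance_graph`.
#' @export
cross_property_covariance <- function(M1, M2, property_pair = c("m1", "m2"),
                                      group = "group") {
  M1 <- as.matrix(M1); M2 <- as.matrix(M2)
  if (nrow(M1) < 3L) stop("need at least 3 subjects")
  if (!identical(dim(M1), dim(M2)))
    stop("M1 and M2 must have identical dimensions")
  if (!is.null(rownames(M1)) && !is.null(rownames(M2)) &&
      !identical(rownames(M1), rownames(M2)))
    stop("subject rows of M1 and M2 are not aligned")
  .check_variance(M1, "M1"); .check_variance(M2, "M2")
  W <- stats::cor(M1, M2)
  diag(W) <- 0
  W[W < 0] <- 0
  dimnames(W) <- list(colnames(M1), colnames(M2))
  .new_covariance_graph(W, directed = TRUE, property_pair = property_pair,
                        group = group)
}

#' @export
print.covariance_graph <- function(x, ...) {
  cat(sprintf("%s covariance graph [%s], group %s: %d regions, %.1f%% edges retained\n",
              if (x$directed) "Directed cross-property" else "Structural",
              paste(x$property_pair, collapse = "->"), x$group,
              nrow(x$weights), 100 * x$retained_fraction))
  invisible(x)
}

# Positive edges sorted by descending weight, ties by ascending (row, col).
# Shared by threshold_to_density(), density_sweep() and the permutation
# engine; `emax` counts unordered pairs for undirected graphs, ordered pairs
# for directed ones.
.sorted_edges <- function(W, directed) {
  P <- nrow(W)
  keep <- if (directed) W > 0 & row(W) != col(W) else W > 0 & row(W) < col(W)
  idx <- which(keep)
  i <- ((idx - 1L) %% P) + 1L
  j <- ((idx - 1L) %/% P) + 1L
  w <- W[idx]
  o <- order(-w, i, j)
  list(i = i[o], j = j[o], w = w[o], P = P,
       emax = if (directed) P * (P - 1L) else P * (P - 1L) / 2L)
}

# round(rho * E_max) with halves rounding up and a relative epsilon so that
# binary-representation fuzz in rho (e.g. 0.35 * 90 = 31.4999...96) cannot
# shift the count
.edge_count_at <- function(rho, emax) as.integer(floor(rho * emax + 0.5 + 1e-9))

.assert_feasible <- function(n_pos, k, emax, context = NULL) {
  if (k > n_pos)
    stop("density infeasible", if (!is.null(context)) paste0(" (", context, ")"),
         ": requested ", k, " edges but only ", n_pos,
         " positive edges exist; maximum feasible density is ",
         format(n_pos / emax, digits = 4L))
}

.adjacency_from_edges <- function(es, k) {
  A <- matrix(0, es$P, es$P)
  if (k > 0L) {
    sel <- seq_len(k)
    A[cbind(es$i[sel], es$j[sel])] <- es$w[sel]
  }
  A
}

#' Threshold a covariance graph to a target density
#'
#' Keeps the `round(rho * E_max)` strongest positive edges (`E_max` is the
#' number of unordered region pairs for undirected graphs, ordered pairs for
#' directed ones; halves round up) and zeroes the rest, preserving the
#' surviving weights.
#' Ties at the cut are broken by descending weight, then ascending (row,
#' column) index, so the result is fully deterministic and edge sets are
#' nested across densities.
#'
#' @param g A `covariance_graph`.
#' @param rho Target density in (0, 1].
#' @return Weighted adjacency matrix (same dimnames as `g$weights`).
#' @export
threshold_to_density <- function(g, rho) {
  stopifnot(inherits(g, "covariance_graph"))
  if (!(rho > 0 && rho <= 1)) stop("rho must lie in (0, 1]")
  es <- .sorted_edges(g$weights, g$directed)
  k <- .edge_count_at(rho, es$emax)
  .assert_feasible(length(es$w), k, es$emax)
  A <- .adjacency_from_edges(es, k)
  if (!g$directed) A <- A + t(A)
  dimnames(A) <- dimnames(g$weights)
  A
}

#' Sweep a covariance graph across a density grid
#'
#' @param g A `covariance_graph`.
#' @param grid A [density_grid()].
#' @param check_connected If `TRUE`, error unless the adjacency at the
#'   lowest density is fully connected (the guard applied to observed group
#'   graphs; nestedness then guarantees connectedness over the whole grid).
#' @return Named list of weighted adjacencies, one per grid density; edge
#'   sets are nested from low to high density.
#' @export
density_sweep <- function(g, grid = density_grid(), check_connected = FALSE) {
  stopifnot(inherits(g, "covariance_graph"))
  es <- .sorted_edges(g$weights, g$directed)
  ks <- .edge_count_at(as.numeric(grid), es$emax)
  .assert_feasible(length(es$w), max(ks), es$emax)
  out <- vector("list", length(grid))
  A <- matrix(0, es$P, es$P)
  dimnames(A) <- dimnames(g$weights)
  prev <- 0L
  for (gi in seq_along(ks)) {
    if (ks[gi] > prev) {
      sel <- (prev + 1L):ks[gi]
      A[cbind(es$i[sel], es$j[sel])] <- es$w[sel]
      if (!g$directed) A[cbind(es$j[sel], es$i[sel])] <- es$w[sel]
      prev <- ks[gi]
    }
    out[[gi]] <- A
  }
  names(out) <- format(as.numeric(grid), digits = 3L)
  if (check_connected && !is_fully_connected(out[[1L]]))
    stop("graph is not fully connected at the lowest density ",
         format(grid[1L], digits = 3L),
         " (group ", g$group, ", ", paste(g$property_pair, collapse = "->"), ")")
  out
}

# connected-component labels by breadth-first search on the (weak) adjacency
.component_labels <- function(A) {
  P <- nrow(A)
  B <- (A != 0) | (t(A) != 0)
  labels <- integer(P)
  comp <- 0L
  for (s in seq_len(P)) {
    if (labels[s]) next
    comp <- comp + 1L
    frontier <- s
    labels[s] <- comp
    while (length(frontier)) {
      nb <- which(.neighbors_of(B, frontier) & labels == 0L)
      labels[nb] <- comp
      frontier <- nb
    }
  }
  labels
}

# rows `frontier` of logical matrix B collapsed by any(): neighbors of the set
.neighbors_of <- function(B, frontier) {
  if (length(frontier) == 1L) B[frontier, ] else colSums(B[frontier, , drop = FALSE]) > 0L
}

#' Is a graph fully (weakly) connected?
#'
#' @param adjacency Square nonnegative matrix; direction is ignored
#'   (weak connectivity) so the same guard applies to directed graphs.
#' @return `TRUE` iff one connected component spans all nodes.
#' @export
is_fully_connected <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (any(adjacency < 0)) stop("adjacency must be nonnegative")
  all(.component_labels(adjacency) == 1L)
}
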