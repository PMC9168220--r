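#' Weighted nodal degree
#'
#' Degree of region p is the sum of the weights of its incident edges. For
#' directed adjacencies use [in_out_degree()] instead.
#'
#' @param adjacency Symmetric nonnegative matrix.
#' @return Named numeric vector, one value per region.
#' @export
weighted_degree <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency)))
    stop("adjacency is not symmetric; use in_out_degree() for directed graphs")
  if (any(adjacency < 0)) stop("adjacency must be nonnegative")
  rowSums(adjacency)
}

# core clustering computation on a thresholded weighted adjacency whose
# weights were rescaled by the graph's maximum weight (Onnela geometric-mean
# triangle intensity; toolbox-default weighted variant)
.clustering_onnela <- function(A) {
  mx <- max(A)
  if (mx == 0) return(numeric(nrow(A)))
  Tm <- (A / mx)^(1 / 3)
  cyc3 <- rowSums((Tm %*% Tm) * Tm)      # diag(Tm^3): closed 3-walk intensity
  K <- rowSums(A > 0)                    # binary degree
  C <- numeric(nrow(A))
  ok <- K >= 2L
  C[ok] <- cyc3[ok] / (K[ok] * (K[ok] - 1L))
  C
}

#' Weighted clustering coefficient
#'
#' How interconnected a node's direct neighborhood is. Weighted variant:
#' the mean geometric triangle intensity, computed on weights rescaled by
#' the maximum weight of the graph; for binary (0/1) graphs this reduces to
#' the classical triangle-count clustering coefficient. Nodes with fewer
#' than two neighbors get 0.
#'
#' @param adjacency Symmetric nonnegative matrix.
#' @param binary If `TRUE`, binarize the adjacency first (sensitivity
#'   variant).
#' @return Named numeric vector per region, each in `[0, 1]`.
#' @export
clustering_coefficient <- function(adjacency, binary = FALSE) {
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency))) stop("adjacency is not symmetric")
  if (any(adjacency < 0)) stop("adjacency must be nonnegative")
  if (binary) adjacency <- (adjacency > 0) + 0
  out <- .clustering_onnela(adjacency)
  names(out) <- rownames(adjacency)
  out
}

# leading eigenvector of a connected nonnegative symmetric block, oriented
# nonnegative, unit Euclidean norm
.perron_vector <- function(A) {
  v <- eigen(A, symmetric = TRUE)$vectors[, 1L]
  v <- abs(v)                            # Perron-Frobenius: strictly positive
  v / sqrt(sum(v^2))
}

#' Eigenvector centrality
#'
#' Participation of each region in the graph's dominant eigen-structure:
#' the leading eigenvector of the weighted adjacency, oriented nonnegative
#' and scaled to unit Euclidean norm. Uniquely defined (Perron-Frobenius)
#' only on connected graphs; disconnected graphs either raise an error or,
#' with `on_disconnected = "per_component"` (used for degenerate permuted
#' graphs so the permutation null is not biased by discarding them), get a
#' leading eigenvector per connected component, each unit-normalized.
#'
#' @param adjacency Symmetric nonnegative matrix.
#' @param on_disconnected `"error"` (default) or `"per_component"`.
#' @return Named nonnegative numeric vector per region.
#' @export
eigenvector_centrality <- function(adjacency,
                                   on_disconnected = c("error", "per_component")) {
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency))) stop("adjacency is not symmetric")
  if (any(adjacency < 0)) stop("adjacency must be nonnegative")
  on_disconnected <- match.arg(on_disconnected)
  labels <- .component_labels(adjacency)
  out <- numeric(nrow(adjacency))
  if (max(labels) > 1L) {
    if (on_disconnected == "error")
      stop("graph is disconnected (", max(labels),
           " components); eigenvector centrality is not uniquely defined")
    for (comp in seq_len(max(labels))) {
      idx <- which(labels == comp)
      out[idx] <- if (length(idx) == 1L) 0
        else .perron_vector(adjacency[idx, idx, drop = FALSE])
    }
  } else {
    out <- .perron_vector(adjacency)
  }
  names(out) <- rownames(adjacency)
  out
}

#' In- and out-degree of a directed covariance graph
#'
#' In-degree of region j is the j-th column sum (how strongly the second
#' property at j depends on the first property elsewhere); out-degree is the
#' j-th row sum (how strongly the first property at j drives the second
#' property elsewhere). Total in- and out-degree are always equal.
#'
#' @param adjacency Square nonnegative matrix with zero diagonal (self-loops
#'   are excluded from cross-property graphs).
#' @return List with numeric vectors `in_degree` and `out_degree`.
#' @export
in_out_degree <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (any(adjacency < 0)) stop("adjacency must be nonnegative")
  if (any(diag(adjacency) != 0))
    stop("nonzero diagonal: self-loops are excluded from cross-property graphs")
  list(in_degree = colSums(adjacency), out_degree = rowSums(adjacency))
}

#' Reduce a metric-versus-density curve to its area under the curve
#'
#' The AUC summary is the plain sum of the metric values over the grid
#' points (equivalently the sum of differences, when applied to a
#' difference curve: summing then differencing and differencing then
#' summing agree exactly, by linearity). Its magnitude therefore scales
#' with the number of grid points.
#'
#' @param values Numeric regions x grid-points matrix (or a vector for a
#'   single region).
#' @return Numeric vector with one AUC per region.
#' @export
auc_over_densities <- function(values) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  if (ncol(values) < 1L) stop("curve needs at least one grid point")
  rowSums(values)
}

#' Metric curves of one covariance graph across the density grid
#'
#' Thresholds the graph at every grid density and evaluates the requested
#' per-region metrics, returning one regions x grid-points matrix per
#' metric. Same-property (undirected) graphs support `degree`, `clustering`
#' and `eigencentrality`; directed graphs support `in_degree` and
#' `out_degree`.
#'
#' @param g A `covariance_graph`.
#' @param grid A [density_grid()].
#' @param metrics Character vector of metric names; defaults to all metrics
#'   valid for the graph's directedness.
#' @param on_disconnected Passed to [eigenvector_centrality()]; permuted
#'   graphs use `"per_component"`.
#' @return Named list of regions x grid-points matrices.
#' @export
metric_curves <- function(g, grid = density_grid(), metrics = NULL,
                          on_disconnected = c("error", "per_component")) {
  stopifnot(inherits(g, "covariance_graph"))
  on_disconnected <- match.arg(on_disconnected)
  valid <- if (g$directed) c("in_degree", "out_degree")
           else c("degree", "clustering", "eigencentrality")
  metrics <- metrics %||% valid
  if (!all(metrics %in% valid))
    stop("invalid metric(s) for this graph: ",
         paste(setdiff(metrics, valid), collapse = ", "))
  es <- .sorted_edges(g$weights, g$directed)
  ks <- .edge_count_at(as.numeric(grid), es$emax)
  .assert_feasible(length(es$w), max(ks), es$emax,
                   context = paste0("group ", g$group))
  .sweep_metric_curves(es, ks, directed = g$directed, metrics = metrics,
                       on_disconnected = on_disconnected,
                       region_names = rownames(g$weights),
                       grid_names = format(as.numeric(grid), digits = 3L))
}

# Incremental density sweep over a pre-sorted edge list. Edge sets are
# nested across the grid, so the adjacency is grown in place; eigenvector
# centrality is warm-started from the previous density's vector (power
# iteration) once the graph is connected, falling back to a dense
# eigendecomposition per component otherwise.
.sweep_metric_curves <- function(es, ks, directed, metrics, on_disconnected,
                                 region_names = NULL, grid_names = NULL) {
  P <- es$P
  G <- length(ks)
  out <- lapply(metrics, function(m) {
    mat <- matrix(NA_real_, P, G, dimnames = list(region_names, grid_names))
    mat
  })
  names(out) <- metrics
  A <- matrix(0, P, P)
  prev <- 0L
  ec_prev <- NULL
  connected <- FALSE
  do_clust <- "clustering" %in% metrics
  if (do_clust) {
    # incremental Onnela clustering: adding edge (i, j) with rescaled
    # cube-root weight u changes the closed-3-walk intensity by
    # 2*u*Tm[p,i]*Tm[p,j] at bystander nodes p and by 2*u*(Tm^2)[i,j] at
    # the endpoints (Tm taken before the update)
    tw <- (es$w / es$w[1L])^(1 / 3)
    Tm <- matrix(0, P, P)
    cyc3 <- numeric(P)
    Kdeg <- numeric(P)
  }
  for (gi in seq_len(G)) {
    if (ks[gi] > prev) {
      sel <- (prev + 1L):ks[gi]
      if (do_clust) {
        for (m in sel) {
          i <- es$i[m]; j <- es$j[m]; u <- tw[m]
          ti <- Tm[, i]; tj <- Tm[, j]
          s <- sum(ti * tj)
          cyc3 <- cyc3 + (2 * u) * (ti * tj)
          cyc3[i] <- cyc3[i] + 2 * u * s
          cyc3[j] <- cyc3[j] + 2 * u * s
          Tm[i, j] <- Tm[j, i] <- u
          Kdeg[i] <- Kdeg[i] + 1
          Kdeg[j] <- Kdeg[j] + 1
        }
      }
      A[cbind(es$i[sel], es$j[sel])] <- es$w[sel]
      if (!directed) A[cbind(es$j[sel], es$i[sel])] <- es$w[sel]
      prev <- ks[gi]
    }
    if ("degree" %in% metrics) out$degree[, gi] <- rowSums(A)
    if ("in_degree" %in% metrics) out$in_degree[, gi] <- colSums(A)
    if ("out_degree" %in% metrics) out$out_degree[, gi] <- rowSums(A)
    if (do_clust) {
      C <- numeric(P)
      ok <- Kdeg >= 2
      C[ok] <- cyc3[ok] / (Kdeg[ok] * (Kdeg[ok] - 1))
      out$clustering[, gi] <- C
    }
    if ("eigencentrality" %in% metrics) {
      if (!connected) {
        labels <- .component_labels(A)
        connected <- max(labels) == 1L   # stays connected as edges are added
      }
      if (connected && !is.null(ec_prev)) {
        ec <- .power_iterate(A, ec_prev)
      } else if (connected) {
        ec <- .perron_vector(A)
      } else {
        if (on_disconnected == "error")
          stop("graph is disconnected (", max(labels), " components) at a ",
               "sweep density; rerun with on_disconnected = \"per_component\"")
        ec <- numeric(P)
        for (comp in seq_len(max(labels))) {
          idx <- which(labels == comp)
          ec[idx] <- if (length(idx) == 1L) 0
            else .perron_vector(A[idx, idx, drop = FALSE])
        }
      }
      out$eigencentrality[, gi] <- ec
      ec_prev <- if (connected) ec else NULL
    }
  }
  out
}

# power iteration warm-started at v0; deterministic, with dense fallback
# (the fallback also covers bipartite-degenerate spectra, where plain power
# iteration oscillates instead of converging)
.power_iterate <- function(A, v0, tol = 1e-10, max_iter = 80L) {
  v <- v0
  for (it in seq_len(max_iter)) {
    v2 <- A %*% v
    nrm <- sqrt(sum(v2^2))
    if (nrm == 0) return(.perron_vector(A))
    v2 <- v2 / nrm
    if (max(abs(v2 - v)) < tol) return(as.numeric(v2))
    v <- v2
  }
  .perron_vector(A)                      # slow convergence: exact fallback
}
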