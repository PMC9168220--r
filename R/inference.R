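#' Specify a group contrast for permutation inference
#'
#' The two canonical contrasts are `HC_minus_ETpre` (controls minus
#' patients pre-intervention) and `ETpost_minus_ETpre` (patients after
#' minus before intervention); arbitrary group pairs are allowed. The null
#' distribution is built by shuffling subjects across the two groups:
#' either unrestricted reassignment preserving group sizes, or — for paired
#' designs — independent pre/post label swaps within each subject pair.
#'
#' @param name Contrast label. For the canonical names the groups are
#'   implied; otherwise supply `group_a` and `group_b`.
#' @param group_a,group_b Group labels; `delta = AUC(group_a) - AUC(group_b)`.
#' @param n_permutations Number of null realizations (default 8000).
#' @param shuffle_scheme `"unrestricted"` or `"paired_swap"`.
#' @return A list of class `contrast_spec`.
#' @export
contrast_spec <- function(name, group_a = NULL, group_b = NULL,
                          n_permutations = 8000L,
                          shuffle_scheme = c("unrestricted", "paired_swap")) {
  shuffle_scheme <- match.arg(shuffle_scheme)
  if (is.null(group_a)) {
    known <- list(HC_minus_ETpre = c("HC", "ET_pre"),
                  ETpost_minus_ETpre = c("ET_post", "ET_pre"))
    if (!name %in% names(known))
      stop("unknown contrast name '", name,
           "'; supply group_a and group_b explicitly")
    group_a <- known[[name]][1L]
    group_b <- known[[name]][2L]
  }
  if (identical(group_a, group_b)) stop("contrast groups must be distinct")
  if (n_permutations < 1L) stop("n_permutations must be at least 1")
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 n_permutations = as.integer(n_permutations),
                 shuffle_scheme = shuffle_scheme),
            class = "contrast_spec")
}

#' Enumerate the analysis subcases
#'
#' The full analysis spans 15 subcases: each same-property graph (`CT`,
#' `SA`, `MC`, over all 87 regions, non-cortical volumes appended) crossed
#' with degree, clustering and eigenvector centrality, plus each ordered
#' property pair's directed cross-property graph (`CT_SA`, `CT_MC`,
#' `SA_MC`, cortical regions only) crossed with in- and out-degree.
#'
#' @param properties Same-property graph labels present in the cohort.
#' @param pairs List of length-2 property pairs for cross-property graphs.
#' @return data.frame with columns `subcase`, `type`, `property1`,
#'   `property2`, `metric`.
#' @export
sca_subcases <- function(properties = c("CT", "SA", "MC"),
                         pairs = list(c("CT", "SA"), c("CT", "MC"),
                                      c("SA", "MC"))) {
  same <- expand.grid(property1 = properties,
                      metric = c("degree", "clustering", "eigencentrality"),
                      stringsAsFactors = FALSE)
  same$property2 <- same$property1
  same$type <- "same"
  cross <- if (length(pairs)) {
    cr <- expand.grid(pair = seq_along(pairs),
                      metric = c("in_degree", "out_degree"),
                      stringsAsFactors = FALSE)
    data.frame(property1 = vapply(pairs[cr$pair], `[`, "", 1L),
               property2 = vapply(pairs[cr$pair], `[`, "", 2L),
               metric = cr$metric, type = "cross",
               stringsAsFactors = FALSE)
  }
  out <- rbind(same[, c("property1", "property2", "metric", "type")], cross)
  out$case <- ifelse(out$type == "same", out$property1,
                     paste(out$property1, out$property2, sep = "_"))
  out$subcase <- paste(out$case, out$metric, sep = ".")
  rownames(out) <- NULL
  out[, c("subcase", "case", "type", "property1", "property2", "metric")]
}

# Assemble the graph cases a contrast needs: for each same-property case the
# pooled residual matrix (cortical property columns + non-cortical volumes),
# for each cross case the two aligned cortical matrices. Pooled rows are in
# canonical (alphabetical) group order, independent of contrast direction,
# so that reversing a contrast maps onto the identical pooled rows and the
# null negates exactly.
.build_cases <- function(cohort, spec, subcases, refit_confounds = TRUE) {
  for (g in c(spec$group_a, spec$group_b))
    if (is.null(cohort$data[[g]]))
      stop("cohort has no group '", g, "'")
  a_first <- spec$group_a <= spec$group_b
  g1 <- if (a_first) spec$group_a else spec$group_b
  g2 <- if (a_first) spec$group_b else spec$group_a
  d1 <- cohort$data[[g1]]
  d2 <- cohort$data[[g2]]
  has_vol <- "VOL" %in% names(d1)
  pool <- function(p, vol) {
    M1 <- d1[[p]]; M2 <- d2[[p]]
    if (is.null(M1)) stop("property '", p, "' missing from cohort")
    if (vol && has_vol) {
      M1 <- cbind(M1, d1$VOL)
      M2 <- cbind(M2, d2$VOL)
    }
    rbind(M1, M2)
  }
  cases <- list()
  for (cs in unique(subcases$case)) {
    rows <- subcases[subcases$case == cs, ]
    metrics <- unique(rows$metric)
    if (rows$type[1L] == "same") {
      cases[[cs]] <- list(name = cs, type = "same",
                          M = pool(rows$property1[1L], vol = TRUE),
                          metrics = metrics)
    } else {
      cases[[cs]] <- list(name = cs, type = "cross",
                          M1 = pool(rows$property1[1L], vol = FALSE),
                          M2 = pool(rows$property2[1L], vol = FALSE),
                          metrics = metrics)
    }
  }
  n1 <- nrow(d1[[1L]])
  n2 <- nrow(d2[[1L]])
  covs <- NULL
  if (refit_confounds) {
    sub <- cohort$subjects
    covs <- rbind(sub[sub$group == g1, c("age", "gender", "total_gmv")],
                  sub[sub$group == g2, c("age", "gender", "total_gmv")])
    if (nrow(covs) != n1 + n2)
      stop("subject table does not align with the data tables")
  }
  n_a <- if (a_first) n1 else n2
  n_b <- if (a_first) n2 else n1
  idx_a_obs <- if (a_first) seq_len(n1) else n1 + seq_len(n2)
  list(cases = cases, n_a = n_a, n_b = n_b, n1 = n1, n2 = n2,
       a_first = a_first, idx_a_obs = idx_a_obs, covs = covs)
}

# degree-type AUC straight from the sorted edge list: edge of rank m is
# present at every grid point whose edge budget reaches m, so its AUC
# contribution is weight * (number of such grid points). O(E) per graph.
.degree_auc_fast <- function(es, ks, directed) {
  G <- length(ks)
  kmax <- ks[G]
  auc_from <- function(nodes, contrib) {
    acc <- numeric(es$P)
    t1 <- rowsum(contrib, nodes)
    acc[as.integer(rownames(t1))] <- t1
    acc
  }
  if (kmax == 0L) {
    z <- numeric(es$P)
    return(if (directed) list(in_degree = z, out_degree = z)
           else list(degree = z))
  }
  m <- seq_len(kmax)
  cnt <- G - findInterval(m - 1L, ks)
  contrib <- es$w[m] * cnt
  if (directed)
    list(in_degree = auc_from(es$j[m], contrib),
         out_degree = auc_from(es$i[m], contrib))
  else
    list(degree = auc_from(c(es$i[m], es$j[m]), c(contrib, contrib)))
}

# per-case AUC vectors for one subject-row assignment; NULL if density
# infeasible (caller redraws the assignment). When `covs` is given
# (strict/refit mode) the confound regression is re-fit within the
# pseudo-group before correlating.
.case_auc <- function(case, rows, grid, ks_cache, on_disconnected,
                      covs = NULL) {
  take <- function(M) {
    M <- M[rows, , drop = FALSE]
    if (!is.null(covs)) M <- residualize(M, covs[rows, , drop = FALSE])
    M
  }
  W <- if (case$type == "same") {
    stats::cor(take(case$M))
  } else {
    stats::cor(take(case$M1), take(case$M2))
  }
  if (anyNA(W))
    stop("undefined correlation (zero-variance region) in case ", case$name)
  if (case$type == "cross") diag(W) <- 0
  directed <- case$type == "cross"
  es <- .sorted_edges(W, directed)
  ks <- ks_cache[[as.character(es$emax)]]
  if (is.null(ks)) ks <- .edge_count_at(as.numeric(grid), es$emax)
  if (max(ks) > length(es$w)) return(NULL)          # density infeasible
  degree_only <- all(case$metrics %in% c("degree", "in_degree", "out_degree"))
  if (degree_only) {
    .degree_auc_fast(es, ks, directed)[case$metrics]
  } else {
    curves <- .sweep_metric_curves(es, ks, directed, case$metrics,
                                   on_disconnected)
    lapply(curves, rowSums)
  }
}

# delta AUC per subcase for one assignment (idx_a = pooled rows of group_a)
.delta_for_assignment <- function(built, idx_a, grid, ks_cache,
                                  on_disconnected) {
  S <- built$n_a + built$n_b
  idx_b <- setdiff(seq_len(S), idx_a)
  out <- list()
  for (case in built$cases) {
    auc_a <- .case_auc(case, idx_a, grid, ks_cache, on_disconnected,
                       covs = built$covs)
    if (is.null(auc_a)) return(NULL)
    auc_b <- .case_auc(case, idx_b, grid, ks_cache, on_disconnected,
                       covs = built$covs)
    if (is.null(auc_b)) return(NULL)
    for (m in case$metrics)
      out[[paste(case$name, m, sep = ".")]] <- auc_a[[m]] - auc_b[[m]]
  }
  out
}

.region_names_for_case <- function(case) {
  if (case$type == "same") colnames(case$M) else colnames(case$M1)
}

#' Observed per-region AUC differences for a contrast
#'
#' Runs the covariance-graph / metric / AUC chain on the actual group
#' assignment and differences the two groups' per-region AUC values, for
#' every requested subcase.
#'
#' @param cohort A residualized `sca_cohort` (see [residualize_cohort()];
#'   non-residualized cohorts are residualized on the fly).
#' @param contrast A [contrast_spec()] or canonical contrast name.
#' @param grid A [density_grid()].
#' @param subcases Subcase table from [sca_subcases()]; defaults to all
#'   subcases supported by the cohort's properties.
#' @param check_connected Verify that each observed group graph is fully
#'   connected at the lowest grid density.
#' @param refit_confounds Strict confound handling: keep the cohort raw and
#'   re-fit the confound regression inside each (pseudo-)group. For the
#'   observed contrast this coincides with the default (residualize once
#'   within the observed groups); it changes only how permutation nulls are
#'   built.
#' @return Named list: per subcase, the per-region `AUC(a) - AUC(b)` vector.
#' @export
observed_contrast <- function(cohort, contrast, grid = density_grid(),
                              subcases = NULL, check_connected = TRUE,
                              refit_confounds = TRUE) {
  spec <- if (inherits(contrast, "contrast_spec")) contrast
          else contrast_spec(contrast)
  if (!refit_confounds) cohort <- residualize_cohort(cohort)
  subcases <- subcases %||% .default_subcases(cohort)
  built <- .build_cases(cohort, spec, subcases, refit_confounds)
  if (check_connected) .check_min_density_connectivity(built, spec, grid)
  delta <- .delta_for_assignment(built, built$idx_a_obs, grid,
                                 ks_cache = list(),
                                 on_disconnected = if (check_connected)
                                   "error" else "per_component")
  if (is.null(delta))
    stop("density infeasible for an observed group graph; lower rho_max")
  for (case in built$cases)
    for (m in case$metrics) {
      key <- paste(case$name, m, sep = ".")
      names(delta[[key]]) <- .region_names_for_case(case)
    }
  delta
}

.default_subcases <- function(cohort) {
  props <- intersect(c("CT", "SA", "MC"), names(cohort$data[[1L]]))
  if (!length(props)) props <- setdiff(names(cohort$data[[1L]]), "VOL")
  pairs <- if (length(props) >= 2L) utils::combn(props, 2L, simplify = FALSE)
           else list()
  sca_subcases(properties = props, pairs = pairs)
}

# Full-connectivity guard at the lowest sweep density, applied to the
# observed same-property graphs (eigenvector centrality requires a
# connected graph there; the in/out-degree sums used on directed
# cross-property graphs are defined regardless of connectedness).
.check_min_density_connectivity <- function(built, spec, grid) {
  idx_a <- built$idx_a_obs
  idx_b <- setdiff(seq_len(built$n1 + built$n2), idx_a)
  for (case in built$cases) {
    if (case$type != "same") next
    for (side in list(c(spec$group_a, "a"), c(spec$group_b, "b"))) {
      rows <- if (side[2L] == "a") idx_a else idx_b
      M <- case$M[rows, , drop = FALSE]
      if (!is.null(built$covs))
        M <- residualize(M, built$covs[rows, , drop = FALSE])
      W <- stats::cor(M)
      es <- .sorted_edges(W, directed = FALSE)
      k <- .edge_count_at(grid[1L], es$emax)
      .assert_feasible(length(es$w), k, es$emax,
                       context = paste0("case ", case$name, ", group ", side[1L]))
      if (!is_fully_connected(.adjacency_from_edges(es, k)))
        stop("covariance graph of group ", side[1L], " (case ", case$name,
             ") is disconnected at the lowest density ",
             format(grid[1L], digits = 3L),
             "; raise rho_min or inspect the input data")
    }
  }
  invisible(TRUE)
}

# role-symmetric pseudo-group draw: the sampled subset always plays the
# alphabetically first group, so reversing a contrast negates every null
# delta exactly and leaves |delta|-based p-values unchanged
.draw_assignment <- function(spec, built) {
  if (spec$shuffle_scheme == "paired_swap") {
    if (built$n1 != built$n2)
      stop("paired_swap requires equal group sizes (paired design)")
    n <- built$n1
    flip <- stats::runif(n) < 0.5
    first_set <- ifelse(flip, n + seq_len(n), seq_len(n))
    if (built$a_first) first_set
    else ifelse(flip, seq_len(n), n + seq_len(n))
  } else {
    S <- built$n1 + built$n2
    sub <- sort(sample.int(S, built$n1))
    if (built$a_first) sub else setdiff(seq_len(S), sub)
  }
}

#' Permutation null distribution of the AUC differences
#'
#' Reruns the full covariance-graph / metric / AUC chain
#' `n_permutations` times with subjects randomly reassigned to two
#' pseudo-groups of the original sizes (or, under `paired_swap`, with
#' pre/post labels flipped independently per subject pair), recording each
#' pseudo delta. Assignments under which a pseudo-group graph cannot reach
#' the highest grid density are redrawn (at most 10 attempts each; the
#' count is reported in the `n_regenerated` attribute) so the null always
#' has exactly `n_permutations` rows.
#'
#' @inheritParams observed_contrast
#' @param seed Integer seed; the null is bit-reproducible given
#'   (cohort, contrast, grid, seed).
#' @param assignments Optional list of pre-specified row-index vectors for
#'   group_a (overrides random shuffling; used for audits). Indices refer
#'   to the pooled subject rows, which concatenate the two groups in
#'   alphabetical group-label order.
#' @return Named list: per subcase, an `n_permutations` x regions matrix.
#' @export
permutation_null <- function(cohort, contrast, grid = density_grid(),
                             subcases = NULL, seed = 1L,
                             assignments = NULL, refit_confounds = TRUE) {
  spec <- if (inherits(contrast, "contrast_spec")) contrast
          else contrast_spec(contrast)
  if (!refit_confounds) cohort <- residualize_cohort(cohort)
  subcases <- subcases %||% .default_subcases(cohort)
  built <- .build_cases(cohort, spec, subcases, refit_confounds)
  if (spec$shuffle_scheme == "paired_swap" && !is.null(cohort$subjects)) {
    sa <- cohort$subjects$pair_id[cohort$subjects$group == spec$group_a]
    sb <- cohort$subjects$pair_id[cohort$subjects$group == spec$group_b]
    if (length(sa) != length(sb) || any(sa == "") || any(sa != sb))
      stop("paired_swap requires both groups to hold the same pairs ",
           "in the same row order")
  }
  n_perm <- if (!is.null(assignments)) length(assignments)
            else spec$n_permutations
  ks_cache <- list()
  for (case in built$cases) {
    P <- if (case$type == "same") ncol(case$M) else ncol(case$M1)
    emax <- if (case$type == "cross") P * (P - 1L) else P * (P - 1L) / 2L
    ks_cache[[as.character(emax)]] <- .edge_count_at(as.numeric(grid), emax)
  }
  null <- list()
  for (sc in subcases$subcase) null[[sc]] <- vector("list", n_perm)
  n_regenerated <- 0L
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      delta <- NULL
      for (attempt in seq_len(10L)) {
        idx_a <- if (!is.null(assignments)) assignments[[b]]
                 else .draw_assignment(spec, built)
        delta <- .delta_for_assignment(built, idx_a, grid, ks_cache,
                                       on_disconnected = "per_component")
        if (!is.null(delta)) break
        if (!is.null(assignments))
          stop("supplied assignment ", b, " is density-infeasible")
        n_regenerated <- n_regenerated + 1L
      }
      if (is.null(delta))
        stop("permutation ", b, ": no density-feasible assignment in 10 attempts")
      for (sc in names(delta)) null[[sc]][[b]] <- delta[[sc]]
    }
  })
  out <- lapply(null, function(rows) do.call(rbind, rows))
  for (case in built$cases)
    for (m in case$metrics) {
      key <- paste(case$name, m, sep = ".")
      colnames(out[[key]]) <- .region_names_for_case(case)
    }
  attr(out, "n_regenerated") <- n_regenerated
  out
}

#' Two-sided permutation p-values with the add-one estimate
#'
#' `p = (1 + #\{permutations: |null| >= |observed|\}) / (n_permutations + 1)`,
#' which never returns zero and is exact under exchangeability.
#'
#' @param delta Observed per-region delta vector.
#' @param null Permutations x regions null matrix.
#' @return Per-region p-values in `(0, 1]`.
#' @export
permutation_pvalues <- function(delta, null) {
  null <- as.matrix(null)
  if (length(delta) != ncol(null))
    stop("delta length does not match null columns")
  exceed <- colSums(abs(null) >= matrix(abs(delta), nrow(null),
                                        length(delta), byrow = TRUE))
  p <- (1 + exceed) / (nrow(null) + 1)
  names(p) <- names(delta)
  p
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values. With `scope = "pooled_across_subcases"` all
#' regions of all subcases of one contrast are adjusted jointly (for the
#' full analysis, 9 x 87 + 6 x 68 = 1191 tests per contrast); with
#' `"per_subcase"` each subcase is adjusted on its own.
#'
#' @param p Named list of per-subcase p-value vectors (or one vector).
#' @param scope `"pooled_across_subcases"` or `"per_subcase"`.
#' @return Object shaped like `p`, with q-values.
#' @export
fdr_correct <- function(p, scope = c("pooled_across_subcases", "per_subcase")) {
  scope <- match.arg(scope)
  if (!is.list(p)) return(stats::p.adjust(p, method = "BH"))
  if (scope == "per_subcase") return(lapply(p, stats::p.adjust, method = "BH"))
  flat <- unlist(p, use.names = FALSE)
  q <- stats::p.adjust(flat, method = "BH")
  out <- p
  at <- 0L
  for (sc in names(p)) {
    out[[sc]] <- q[at + seq_along(p[[sc]])]
    names(out[[sc]]) <- names(p[[sc]])
    at <- at + length(p[[sc]])
  }
  out
}

#' Fit the structural covariance network contrast analysis
#'
#' The top-level fitting function: residualizes the cohort (unless already
#' done), builds each group's same-property and cross-property covariance
#' graphs, sweeps the density grid, reduces metric curves to per-region
#' AUCs, computes observed group differences for every subcase of every
#' contrast, builds permutation nulls by subject shuffling, and derives
#' two-sided add-one p-values with Benjamini-Hochberg q-values.
#'
#' @param cohort An `sca_cohort`.
#' @param contrasts Character vector of canonical contrast names, or list of
#'   [contrast_spec()] objects.
#' @param grid A [density_grid()].
#' @param n_permutations Null realizations per contrast (overrides the
#'   specs' value when given as names; default 8000).
#' @param shuffle_scheme Passed to [contrast_spec()] for named contrasts.
#' @param fdr_scope See [fdr_correct()].
#' @param subcases Subcase table ([sca_subcases()]); default: all subcases
#'   the cohort supports.
#' @param alpha1,alpha2 Reporting significance tiers (defaults 0.01, 0.001).
#' @param seed Integer seed driving all permutation randomness.
#' @param check_connected Guard observed graphs' connectivity at the lowest
#'   density.
#' @param refit_confounds Strict confound handling; see
#'   [observed_contrast()].
#' @return An object of class `sca`; see [summary.sca()], [coef.sca()],
#'   [plot.sca()].
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_cortical = 12, n_noncortical = 0,
#'                                         seed = 3))
#' # small graphs may disconnect at 20% density, hence the disabled guard
#' fit <- sca(cohort, contrasts = "HC_minus_ETpre", n_permutations = 50,
#'            subcases = sca_subcases("CT", pairs = list()), seed = 3,
#'            check_connected = FALSE)
#' head(summary(fit))
#' @export
sca <- function(cohort, contrasts = c("HC_minus_ETpre", "ETpost_minus_ETpre"),
                grid = density_grid(), n_permutations = 8000L,
                shuffle_scheme = c("unrestricted", "paired_swap"),
                fdr_scope = c("pooled_across_subcases", "per_subcase"),
                subcases = NULL, alpha1 = 0.01, alpha2 = 0.001,
                seed = 1L, check_connected = TRUE,
                refit_confounds = TRUE) {
  stopifnot(inherits(cohort, "sca_cohort"))
  shuffle_scheme <- match.arg(shuffle_scheme)
  fdr_scope <- match.arg(fdr_scope)
  if (!refit_confounds) cohort <- residualize_cohort(cohort)
  subcases <- subcases %||% .default_subcases(cohort)
  specs <- lapply(contrasts, function(ct) {
    if (inherits(ct, "contrast_spec")) ct
    else contrast_spec(ct, n_permutations = n_permutations,
                       shuffle_scheme = shuffle_scheme)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  seeds <- .substreams(seed, paste0("contrast.", names(specs)))
  fits <- lapply(names(specs), function(nm) {
    spec <- specs[[nm]]
    delta <- observed_contrast(cohort, spec, grid, subcases,
                               check_connected = check_connected,
                               refit_confounds = refit_confounds)
    null <- permutation_null(cohort, spec, grid, subcases,
                             seed = seeds[[paste0("contrast.", nm)]],
                             refit_confounds = refit_confounds)
    p <- mapply(permutation_pvalues, delta, null[names(delta)],
                SIMPLIFY = FALSE)
    q <- fdr_correct(p, scope = fdr_scope)
    list(spec = spec, delta = delta, null = null, p = p, q = q,
         n_regenerated = attr(null, "n_regenerated"))
  })
  names(fits) <- names(specs)
  structure(list(contrasts = fits, subcases = subcases, grid = grid,
                 alpha1 = alpha1, alpha2 = alpha2, fdr_scope = fdr_scope,
                 atlas = cohort$atlas, seed = as.integer(seed),
                 call = match.call()),
            class = "sca")
}

#' Long-format significance report of a fitted analysis
#'
#' One row per (contrast, subcase, region) with the observed AUC
#' difference, permutation p, FDR q and significance tier (`"alpha2"` if
#' `q < alpha2`, `"alpha1"` if `q < alpha1`, else `"ns"`), sorted by q.
#'
#' @param fit An `sca` fit.
#' @return List with data.frames `full` and `significant` (rows with
#'   `q < alpha1`).
#' @export
significance_report <- function(fit) {
  stopifnot(inherits(fit, "sca"))
  sub <- fit$subcases
  rows <- lapply(names(fit$contrasts), function(nm) {
    cf <- fit$contrasts[[nm]]
    do.call(rbind, lapply(sub$subcase, function(sc) {
      info <- sub[sub$subcase == sc, ]
      data.frame(contrast = nm, region = names(cf$delta[[sc]]),
                 property_pair = paste(unique(c(info$property1,
                                                info$property2)),
                                       collapse = "/"),
                 metric = info$metric, subcase = sc,
                 delta_auc = unname(cf$delta[[sc]]),
                 p = unname(cf$p[[sc]]), q = unname(cf$q[[sc]]),
                 stringsAsFactors = FALSE)
    }))
  })
  full <- do.call(rbind, rows)
  full$tier <- ifelse(full$q < fit$alpha2, "alpha2",
                      ifelse(full$q < fit$alpha1, "alpha1", "ns"))
  full <- full[order(full$q, full$p, full$subcase, full$region), ]
  rownames(full) <- NULL
  list(full = full, significant = full[full$tier != "ns", ])
}
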