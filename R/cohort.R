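#' Configuration of the synthetic morphometric cohort generator
#'
#' Parameterizes a latent-factor Gaussian model of regional morphometry for
#' three groups: healthy controls (`HC`) and an intervention cohort measured
#' twice on the same subjects (`ET_pre`, `ET_post`). Each property (cortical
#' thickness `CT`, surface area `SA`, mean curvature `MC` over the cortical
#' parcels; volume `VOL` over the non-cortical parcels) is generated as
#' `value = mean + unit * (loadings %*% factors + noise) + confound effects`,
#' where a subject-level factor shared across properties induces
#' cross-property coupling and a per-pair shared component ties `ET_pre` to
#' `ET_post`.
#'
#' @param n_hc,n_et Group sizes (controls; patients, measured pre and post).
#' @param n_cortical,n_noncortical Atlas dimensions (see [region_atlas()]).
#' @param n_factors Global latent factors per property, all with positive
#'   mean loading so that, as in empirical structural covariance, most
#'   region pairs correlate positively.
#' @param loading_scale Multiplier on all factor loadings (global and
#'   community); `0` yields independent regions (pure noise).
#' @param loading_sd Standard deviation of the global factor loadings
#'   around their mean (0.5), before scaling by `loading_scale`.
#' @param community_loading Loading of the overlapping community-block
#'   factors (consecutive blocks of `community_size` regions, half-block
#'   stride, so every region belongs to two communities). These emulate the
#'   lobe-level covariance communities of real morphometry and keep the
#'   thresholded graphs connected at low densities; `0` disables them.
#' @param community_size Regions per community block.
#' @param cross_property_coupling Scalar in `[0, 1]`: correlation between the
#'   factor scores of any two properties, realized through a factor shared by
#'   all properties.
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise, on the latent (unit-free) scale. Must be positive.
#' @param confound_betas Named list with one numeric vector
#'   `c(age, gender, gmv)` per property, giving linear confound effects on
#'   the natural scale of that property (per year, per gender level, per
#'   mm^3 of total gray-matter volume). `NULL` disables confound effects.
#' @param pre_post_subject_correlation Correlation in `[0, 1]` between a
#'   subject's latent factor scores before and after the intervention.
#' @param planted_effects List of effects created by [planted_effect()];
#'   each multiplies the factor loadings of a region set in one group only.
#' @param gmv_mean,gmv_sd Moments of total gray-matter volume (mm^3).
#' @param seed Integer seed; one global seed is expanded into independent
#'   substreams (loadings, confounds, factors, noise) so that enlarging one
#'   block does not perturb the others.
#' @return A validated list of class `cohort_config`.
#' @seealso [simulate_cohort()], [planted_effect()]
#' @export
cohort_config <- function(n_hc = 29L, n_et = 34L,
                          n_cortical = 68L, n_noncortical = 19L,
                          n_factors = 4L, loading_scale = 1,
                          loading_sd = 0.08,
                          community_loading = 1.2, community_size = 8L,
                          cross_property_coupling = 0.75, noise_sd = 1,
                          confound_betas = NULL,
                          pre_post_subject_correlation = 0.7,
                          planted_effects = list(),
                          gmv_mean = 6e5, gmv_sd = 6e4,
                          seed = 1L) {
  cfg <- list(
    n_hc = as.integer(n_hc), n_et = as.integer(n_et),
    n_cortical = as.integer(n_cortical),
    n_noncortical = as.integer(n_noncortical),
    n_factors = as.integer(n_factors), loading_scale = loading_scale,
    loading_sd = loading_sd,
    community_loading = community_loading,
    community_size = as.integer(community_size),
    cross_property_coupling = cross_property_coupling, noise_sd = noise_sd,
    confound_betas = confound_betas,
    pre_post_subject_correlation = pre_post_subject_correlation,
    planted_effects = planted_effects,
    gmv_mean = gmv_mean, gmv_sd = gmv_sd,
    seed = as.integer(seed))
  if (cfg$n_hc < 2L || cfg$n_et < 2L)
    stop("group sizes must be at least 2")
  if (cfg$n_cortical < 2L)
    stop("need at least 2 cortical regions")
  if (cfg$n_factors < 1L)
    stop("need at least one latent factor")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be a positive real")
  if (loading_sd < 0 || community_loading < 0)
    stop("loading_sd and community_loading must be nonnegative")
  if (cfg$community_size < 2L) stop("community_size must be at least 2")
  if (cross_property_coupling < 0 || cross_property_coupling > 1)
    stop("cross_property_coupling must lie in [0, 1]")
  if (pre_post_subject_correlation < 0 || pre_post_subject_correlation > 1)
    stop("pre_post_subject_correlation must lie in [0, 1]")
  props <- .cohort_properties(cfg)
  if (!is.null(confound_betas)) {
    if (!all(names(confound_betas) %in% names(props)))
      stop("confound_betas names must be among: ",
           paste(names(props), collapse = ", "))
    if (!all(vapply(confound_betas, length, 0L) == 3L))
      stop("each confound_betas entry must be c(age, gender, gmv)")
  }
  for (pe in planted_effects) {
    if (!inherits(pe, "planted_effect"))
      stop("planted_effects entries must be created by planted_effect()")
    tgt <- intersect(pe$property, names(props))
    if (length(tgt) != length(pe$property))
      stop("planted effect names a property absent from this cohort: ",
           paste(setdiff(pe$property, names(props)), collapse = ", "))
    for (p in tgt)
      if (any(pe$regions < 1L) || any(pe$regions > props[[p]]))
        stop("planted effect region index out of bounds for property ", p,
             " (", props[[p]], " regions)")
    if (!pe$group %in% c("HC", "ET_pre", "ET_post"))
      stop("planted effect group must be HC, ET_pre or ET_post")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Declare a planted covariance effect
#'
#' Multiplies the factor loadings of `regions` by `multiplier` in `group`
#' only, strengthening (multiplier > 1) or weakening (< 1) those regions'
#' covariance with the rest of the network for the given property. Passing
#' two property names targets the shared (cross-property) loading component
#' of both, planting a cross-property coupling effect instead.
#'
#' @param group `"HC"`, `"ET_pre"` or `"ET_post"`.
#' @param property One property name, or two for a cross-property effect.
#' @param regions 1-based region indices within the property's own columns.
#' @param multiplier Positive loading multiplier.
#' @export
planted_effect <- function(group, property, regions, multiplier) {
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier < 0)
    stop("multiplier must be a single nonnegative number")
  if (!length(regions)) stop("empty region set")
  structure(list(group = group, property = as.character(property),
                 regions = as.integer(regions), multiplier = multiplier),
            class = "planted_effect")
}

# property registry: name -> region count, plus display scale/offset so the
# written tables live on familiar units (correlations are scale-invariant)
.cohort_properties <- function(cfg) {
  props <- c(CT = cfg$n_cortical, SA = cfg$n_cortical, MC = cfg$n_cortical)
  if (cfg$n_noncortical > 0L) props <- c(props, VOL = cfg$n_noncortical)
  props
}

.property_units <- c(CT = 0.12, SA = 250, MC = 0.012, VOL = 500)
.property_means <- c(CT = 2.5, SA = 2500, MC = 0.13, VOL = 5000)

# overlapping community blocks: `size` regions per block, half-block stride,
# so each region belongs to two blocks (ends excepted)
.community_loadings <- function(P, size, b) {
  if (b == 0 || P < 2L) return(matrix(0, P, 0L))
  stride <- max(1L, size %/% 2L)
  nb <- as.integer(ceiling(P / stride))
  Lloc <- matrix(0, P, nb)
  for (q in seq_len(nb)) {
    lo <- (q - 1L) * stride + 1L
    hi <- min(lo + size - 1L, P)
    Lloc[lo:hi, q] <- b
  }
  Lloc
}

.cohort_stream_ids <- function(config) {
  props <- .cohort_properties(config)
  groups <- c("HC", "ET_pre", "ET_post")
  c(paste0("loadings.", names(props)),
    "confounds.HC", "confounds.ET",
    "factors.HC", "factors.ET",
    paste0("noise.", rep(groups, each = length(props)), ".",
           rep(names(props), length(groups))))
}

# per-property total loading matrix: K global positive-mean factors (drawn)
# followed by deterministic community-block factors
.draw_loadings <- function(config, streams) {
  props <- .cohort_properties(config)
  K <- config$n_factors
  loadings <- lapply(names(props), function(p) {
    P <- props[[p]]
    .with_seed(streams[[paste0("loadings.", p)]], {
      L <- matrix(stats::rnorm(P * K, mean = 0.5, sd = config$loading_sd),
                  P, K)
      cbind(L, .community_loadings(P, config$community_size,
                                   config$community_loading)) *
        config$loading_scale
    })
  })
  names(loadings) <- names(props)
  loadings
}

# split a property's loadings into cross-property-shared and specific parts
# and apply the planted multipliers for one group
.planted_loadings <- function(config, loadings, p, g) {
  cc <- config$cross_property_coupling
  Lsh <- sqrt(cc) * loadings[[p]]
  Lsp <- sqrt(1 - cc) * loadings[[p]]
  for (pe in config$planted_effects) {
    if (pe$group != g || !p %in% pe$property) next
    if (length(pe$property) == 1L) {              # same-property effect
      Lsh[pe$regions, ] <- Lsh[pe$regions, ] * pe$multiplier
      Lsp[pe$regions, ] <- Lsp[pe$regions, ] * pe$multiplier
    } else {                                      # cross-property coupling
      Lsh[pe$regions, ] <- Lsh[pe$regions, ] * pe$multiplier
    }
  }
  list(shared = Lsh, specific = Lsp)
}

#' Population correlation structure implied by a cohort configuration
#'
#' The analytic (infinite-sample) correlation matrices of the latent-factor
#' model, against which empirical correlations of generated data converge:
#' for each property the same-property correlation, and for each ordered
#' property pair the cross-property correlation (shared-factor covariance
#' only). Confound effects are excluded (they are removed by
#' residualization before any covariance is computed).
#'
#' @param config A [cohort_config()].
#' @param group Group whose planted effects apply.
#' @return List with `same` (per property) and `cross` (per `"p1_p2"` pair)
#'   correlation matrices.
#' @export
population_correlation <- function(config, group = "HC") {
  stopifnot(inherits(config, "cohort_config"))
  streams <- .substreams(config$seed, .cohort_stream_ids(config))
  loadings <- .draw_loadings(config, streams)
  props <- names(loadings)
  parts <- lapply(props, .planted_loadings, config = config,
                  loadings = loadings, g = group)
  names(parts) <- props
  s2 <- config$noise_sd^2
  same <- lapply(parts, function(pp) {
    S <- tcrossprod(pp$shared) + tcrossprod(pp$specific)
    diag(S) <- diag(S) + s2
    stats::cov2cor(S)
  })
  cross <- list()
  cprops <- setdiff(props, "VOL")
  if (length(cprops) >= 2L) {
    for (pair in utils::combn(cprops, 2L, simplify = FALSE)) {
      p1 <- parts[[pair[1L]]]; p2 <- parts[[pair[2L]]]
      k <- min(ncol(p1$shared), ncol(p2$shared))
      S12 <- tcrossprod(p1$shared[, seq_len(k), drop = FALSE],
                        p2$shared[, seq_len(k), drop = FALSE])
      v1 <- rowSums(p1$shared^2) + rowSums(p1$specific^2) + s2
      v2 <- rowSums(p2$shared^2) + rowSums(p2$specific^2) + s2
      cross[[paste(pair, collapse = "_")]] <-
        S12 / sqrt(outer(v1, v2))
    }
  }
  list(same = same, cross = cross)
}

# one global seed -> named substream seeds (independent R RNG streams)
.substreams <- function(seed, ids) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(ids))
  names(s) <- ids
  s
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# pre/post-correlated standard normal pair of S x K matrices
.paired_normals <- function(n, k, rho) {
  u <- matrix(stats::rnorm(n * k), n, k)
  a <- matrix(stats::rnorm(n * k), n, k)
  b <- matrix(stats::rnorm(n * k), n, k)
  list(pre = sqrt(rho) * u + sqrt(1 - rho) * a,
       post = sqrt(rho) * u + sqrt(1 - rho) * b)
}

#' Simulate a morphometric cohort
#'
#' Draws raw (non-residualized) subjects-by-regions tables for every group
#' and property under the latent-factor model described in [cohort_config()],
#' together with the subject covariate table and the region atlas. `ET_pre`
#' and `ET_post` rows describe the same subjects: their latent factors share
#' a per-pair component (correlation `pre_post_subject_correlation`) and
#' their covariates agree (age advanced by one year post-intervention).
#'
#' @param config A [cohort_config()].
#' @return An object of class `sca_cohort`: list with elements `data` (per
#'   group, per property numeric matrices with subject rownames and region
#'   colnames), `subjects` (data.frame: `subject_id`, `group`, `pair_id`,
#'   `age`, `gender`, `total_gmv`), `atlas` and `config`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_cortical = 10, n_noncortical = 0,
#'                                         seed = 7))
#' dim(cohort$data$HC$CT)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  props <- .cohort_properties(config)
  groups <- c("HC", "ET_pre", "ET_post")
  streams <- .substreams(config$seed, .cohort_stream_ids(config))
  loadings <- .draw_loadings(config, streams)
  # factor-score width per property (global + community factors); the
  # shared factor matrix spans the widest property and is subset per
  # property, aligning community factors across cortical properties
  Kp <- vapply(loadings, ncol, 0L)
  Kmax <- max(Kp)

  # covariates: HC drawn fresh; ET drawn once per subject, shared pre/post
  draw_cov <- function(n, cfg) {
    age <- stats::rnorm(n, 70, 8)
    while (any(bad <- age < 45 | age > 90))        # truncation by redraw
      age[bad] <- stats::rnorm(sum(bad), 70, 8)
    data.frame(age = age,
               gender = stats::rbinom(n, 1L, 0.5),
               total_gmv = stats::rnorm(n, cfg$gmv_mean, cfg$gmv_sd))
  }
  cov_hc <- .with_seed(streams[["confounds.HC"]], draw_cov(config$n_hc, config))
  cov_et <- .with_seed(streams[["confounds.ET"]], draw_cov(config$n_et, config))

  subjects <- rbind(
    data.frame(subject_id = sprintf("HC%03d", seq_len(config$n_hc)),
               group = "HC", pair_id = "", cov_hc),
    data.frame(subject_id = sprintf("ETpre%03d", seq_len(config$n_et)),
               group = "ET_pre", pair_id = sprintf("P%03d", seq_len(config$n_et)),
               cov_et),
    data.frame(subject_id = sprintf("ETpost%03d", seq_len(config$n_et)),
               group = "ET_post", pair_id = sprintf("P%03d", seq_len(config$n_et)),
               transform(cov_et, age = age + 1)))

  # factor scores: shared-across-properties component h plus per-property e;
  # ET pre/post tied through .paired_normals
  fac_hc <- .with_seed(streams[["factors.HC"]], {
    h <- matrix(stats::rnorm(config$n_hc * Kmax), config$n_hc, Kmax)
    e <- lapply(names(props), function(p)
      matrix(stats::rnorm(config$n_hc * Kp[[p]]), config$n_hc, Kp[[p]]))
    names(e) <- names(props)
    list(h = h, e = e)
  })
  fac_et <- .with_seed(streams[["factors.ET"]], {
    r <- config$pre_post_subject_correlation
    h <- .paired_normals(config$n_et, Kmax, r)
    e <- lapply(names(props), function(p)
      .paired_normals(config$n_et, Kp[[p]], r))
    names(e) <- names(props)
    list(h = h, e = e)
  })
  factors_for <- function(group, p) {
    k <- seq_len(Kp[[p]])
    if (group == "HC")
      list(h = fac_hc$h[, k, drop = FALSE], e = fac_hc$e[[p]])
    else if (group == "ET_pre")
      list(h = fac_et$h$pre[, k, drop = FALSE], e = fac_et$e[[p]]$pre)
    else
      list(h = fac_et$h$post[, k, drop = FALSE], e = fac_et$e[[p]]$post)
  }

  data <- lapply(groups, function(g) {
    n <- if (g == "HC") config$n_hc else config$n_et
    covs <- subjects[subjects$group == g, c("age", "gender", "total_gmv")]
    out <- lapply(names(props), function(p) {
      P <- props[[p]]
      f <- factors_for(g, p)
      Lp <- .planted_loadings(config, loadings, p, g)
      signal <- f$h %*% t(Lp$shared) + f$e %*% t(Lp$specific)
      noise <- .with_seed(streams[[paste0("noise.", g, ".", p)]],
                          matrix(stats::rnorm(n * P, sd = config$noise_sd), n, P))
      unit <- .property_units[[p]]
      vals <- .property_means[[p]] + unit * (signal + noise)
      if (!is.null(config$confound_betas[[p]])) {
        b <- config$confound_betas[[p]]
        vals <- vals +
          outer(covs$age - 70, rep(b[[1L]], P)) +
          outer(covs$gender - 0.5, rep(b[[2L]], P)) +
          outer(covs$total_gmv - config$gmv_mean, rep(b[[3L]], P))
      }
      rownames(vals) <- subjects$subject_id[subjects$group == g]
      vals
    })
    names(out) <- names(props)
    out
  })
  names(data) <- groups

  atlas <- region_atlas(config$n_cortical, config$n_noncortical)
  for (g in groups) for (p in names(props)) {
    colnames(data[[g]][[p]]) <-
      if (p == "VOL") atlas$name[!atlas$cortical] else atlas$name[atlas$cortical]
  }
  structure(list(data = data, subjects = subjects, atlas = atlas,
                 config = config),
            class = "sca_cohort")
}

#' @export
print.sca_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic morphometric cohort\n")
  cat(sprintf("  groups: HC (n=%d), ET_pre / ET_post (n=%d, paired)\n",
              cfg$n_hc, cfg$n_et))
  cat(sprintf("  regions: %d cortical + %d non-cortical\n",
              cfg$n_cortical, cfg$n_noncortical))
  cat(sprintf("  properties: %s\n",
              paste(names(x$data$HC), collapse = ", ")))
  if (length(cfg$planted_effects))
    cat(sprintf("  planted effects: %d\n", length(cfg$planted_effects)))
  invisible(x)
}

#' Summary moments of a clinical score, pre and post intervention
#'
#' @param score_name Label, e.g. `"ADL"` or `"TSTH"`.
#' @param mean_pre,sd_pre,n_pre Pre-intervention moments and sample size.
#' @param mean_post,sd_post,n_post Post-intervention moments and sample size.
#' @return A list of class `clinical_summary`.
#' @export
clinical_summary <- function(score_name, mean_pre, sd_pre, n_pre,
                             mean_post, sd_post, n_post = n_pre) {
  if (sd_pre <= 0 || sd_post <= 0) stop("standard deviations must be positive")
  if (n_pre < 2L || n_post < 2L) stop("sample sizes must be at least 2")
  structure(list(score_name = score_name,
                 mean_pre = mean_pre, sd_pre = sd_pre, n_pre = as.integer(n_pre),
                 mean_post = mean_post, sd_post = sd_post,
                 n_post = as.integer(n_post)),
            class = "clinical_summary")
}

#' Simulate per-subject pre/post clinical scores from summary moments
#'
#' Draws bivariate Gaussian (pre, post) scores with the requested marginal
#' moments and within-pair correlation. When the pre and post sample sizes
#' differ, the surplus rows of the larger arm are drawn independently and
#' the other arm is `NA` there.
#'
#' @param summary A [clinical_summary()].
#' @param pairing_correlation Within-subject pre/post correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @return data.frame: `subject`, `score_name`, `pre`, `post`.
#' @export
generate_clinical_scores <- function(summary, pairing_correlation = 0.5,
                                     seed = 1L) {
  stopifnot(inherits(summary, "clinical_summary"))
  rho <- pairing_correlation
  if (!is.numeric(rho) || rho < -1 || rho > 1)
    stop("pairing_correlation must lie in [-1, 1]")
  n <- max(summary$n_pre, summary$n_post)
  .with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    pre <- summary$mean_pre + summary$sd_pre * z1
    post <- summary$mean_post +
      summary$sd_post * (rho * z1 + sqrt(1 - rho^2) * z2)
    if (summary$n_pre < n) pre[(summary$n_pre + 1L):n] <- NA_real_
    if (summary$n_post < n) post[(summary$n_post + 1L):n] <- NA_real_
    data.frame(subject = sprintf("S%03d", seq_len(n)),
               score_name = summary$score_name, pre = pre, post = post)
  })
}
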