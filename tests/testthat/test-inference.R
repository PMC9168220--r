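# shared small residualized cohort: 10 cortical + 3 non-cortical regions
small_cohort <- residualize_cohort(simulate_cohort(
  cohort_config(n_hc = 14, n_et = 16, n_cortical = 10, n_noncortical = 3,
                seed = 101)))
small_grid <- density_grid(0.25, 0.55, 0.05)
deg_sub <- local({
  s <- sca_subcases("CT", pairs = list())
  s[s$metric == "degree", ]
})

test_that("the subcase enumeration spans 15 subcases over 87/68 regions", {
  sub <- sca_subcases()
  expect_equal(nrow(sub), 15L)
  expect_equal(sum(sub$type == "same"), 9L)
  expect_equal(sum(sub$type == "cross"), 6L)
  expect_setequal(unique(sub$metric[sub$type == "same"]),
                  c("degree", "clustering", "eigencentrality"))
  expect_setequal(unique(sub$metric[sub$type == "cross"]),
                  c("in_degree", "out_degree"))
  expect_setequal(unique(sub$case[sub$type == "cross"]),
                  c("CT_SA", "CT_MC", "SA_MC"))
})

test_that("contrasting a group with itself gives identically zero differences", {
  co <- small_cohort
  co$data$ET_mirror <- co$data$ET_pre
  sub_mirror <- co$subjects[co$subjects$group == "ET_pre", ]
  sub_mirror$group <- "ET_mirror"
  co$subjects <- rbind(co$subjects, sub_mirror)
  spec <- contrast_spec("self", group_a = "ET_pre", group_b = "ET_mirror")
  delta <- observed_contrast(co, spec, small_grid, check_connected = FALSE)
  expect_true(all(vapply(delta, function(d) max(abs(d)), 0) < 1e-10))
})

test_that("reversing a contrast negates deltas and preserves p-values", {
  f <- contrast_spec("HC_minus_ETpre", n_permutations = 30L)
  r <- contrast_spec("rev", group_a = "ET_pre", group_b = "HC",
                     n_permutations = 30L)
  df <- observed_contrast(small_cohort, f, small_grid, check_connected = FALSE)
  dr <- observed_contrast(small_cohort, r, small_grid, check_connected = FALSE)
  for (sc in names(df)) expect_equal(df[[sc]], -dr[[sc]], tolerance = 1e-12)
  nf <- permutation_null(small_cohort, f, small_grid, seed = 7)
  nr <- permutation_null(small_cohort, r, small_grid, seed = 7)
  for (sc in names(nf)) expect_equal(nf[[sc]], -nr[[sc]], tolerance = 1e-12)
  pf <- permutation_pvalues(df$CT.degree, nf$CT.degree)
  pr <- permutation_pvalues(dr$CT.degree, nr$CT.degree)
  expect_identical(pf, pr)
})

test_that("the identity assignment reproduces the observed delta as a null row", {
  spec <- contrast_spec("HC_minus_ETpre")
  delta <- observed_contrast(small_cohort, spec, small_grid,
                             subcases = deg_sub, check_connected = FALSE)
  # pooled rows are in alphabetical group order: ET_pre block, then HC
  n_hc <- sum(small_cohort$subjects$group == "HC")
  n_et <- sum(small_cohort$subjects$group == "ET_pre")
  null <- permutation_null(small_cohort, spec, small_grid, subcases = deg_sub,
                           assignments = list(n_et + seq_len(n_hc)))
  expect_equal(null$CT.degree[1, ], delta$CT.degree, tolerance = 1e-12)
})

test_that("permutation nulls are bit-reproducible under a fixed seed", {
  spec <- contrast_spec("HC_minus_ETpre", n_permutations = 15L)
  n1 <- permutation_null(small_cohort, spec, small_grid, seed = 42)
  n2 <- permutation_null(small_cohort, spec, small_grid, seed = 42)
  expect_identical(n1, n2)
  n3 <- permutation_null(small_cohort, spec, small_grid, seed = 43)
  expect_false(identical(n1$CT.degree, n3$CT.degree))
})

test_that("paired swapping permutes within pairs only", {
  spec <- contrast_spec("ETpost_minus_ETpre", n_permutations = 10L,
                        shuffle_scheme = "paired_swap")
  null <- permutation_null(small_cohort, spec, small_grid, subcases = deg_sub,
                           seed = 5)
  expect_equal(nrow(null$CT.degree), 10L)
  # mismatched pairing is rejected
  co <- small_cohort
  co$subjects$pair_id[co$subjects$group == "ET_post"] <-
    rev(co$subjects$pair_id[co$subjects$group == "ET_post"])
  expect_error(permutation_null(co, spec, small_grid, subcases = deg_sub,
                                seed = 5), "same row order")
})

test_that("add-one two-sided p-values follow the counting definition", {
  null <- matrix(c(-0.5, 0.2, 0.1, -0.3, 0.05, 0.15, -0.25), ncol = 1)
  # observed above all 7 null magnitudes
  expect_equal(unname(permutation_pvalues(0.6, null)), 1 / 8)
  # observed zero can never beat any magnitude
  expect_equal(unname(permutation_pvalues(0, null)), 1)
  # mid-ranked observation
  expect_equal(unname(permutation_pvalues(0.22, null)),
               (1 + 3) / 8)
  expect_error(permutation_pvalues(c(1, 2), null), "match")
})

test_that("Benjamini-Hochberg correction reproduces the hand-applied step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(fdr_correct(p), rep(0.04, 4))
  expect_equal(fdr_correct(rep(0.2, 5)), rep(0.2, 5))
  # q is monotone in p and never below p
  set.seed(8)
  p2 <- runif(50)
  q2 <- fdr_correct(p2)
  expect_true(all(q2 >= p2))
  o <- order(p2)
  expect_true(all(diff(q2[o]) >= -1e-12))
  # pooled scope adjusts jointly; per-subcase separately
  pl <- list(a = c(x = 0.001, y = 0.5), b = c(u = 0.04, v = 0.9))
  q_pool <- fdr_correct(pl, "pooled_across_subcases")
  expect_equal(unname(q_pool$a["x"]), 0.004)
  q_per <- fdr_correct(pl, "per_subcase")
  expect_equal(unname(q_per$a["x"]), 0.002)
  expect_named(q_pool$b, c("u", "v"))
})

test_that("a full small fit is reproducible and correctly assembled", {
  fit <- sca(small_cohort, grid = small_grid, n_permutations = 40L,
             seed = 9, check_connected = FALSE)
  fit2 <- sca(small_cohort, grid = small_grid, n_permutations = 40L,
              seed = 9, check_connected = FALSE)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$contrasts$HC_minus_ETpre$null,
                   fit2$contrasts$HC_minus_ETpre$null)
  expect_s3_class(fit, "sca")
  expect_equal(names(fit$contrasts),
               c("HC_minus_ETpre", "ETpost_minus_ETpre"))
  # p/q ranges and shapes
  for (cf in fit$contrasts) {
    expect_equal(nrow(cf$null[[1]]), 40L)
    p <- unlist(cf$p)
    q <- unlist(cf$q)
    expect_true(all(p > 0 & p <= 1))
    expect_true(all(q >= p - 1e-12 & q <= 1))
  }
  rep <- summary(fit)
  expect_s3_class(rep, "sca_report")
  # 15 subcases: 9 over 13 regions + 6 over 10 cortical, both contrasts
  expect_equal(nrow(rep), 2L * (9L * 13L + 6L * 10L))
  expect_true(all(rep$tier %in% c("ns", "alpha1", "alpha2")))
  expect_true(!is.unsorted(rep$q))
})

test_that("significance tiers follow the two alpha levels", {
  fit <- list(subcases = sca_subcases("CT", pairs = list())[1, ],
              alpha1 = 0.01, alpha2 = 0.001,
              contrasts = list(test = list(
                delta = list(CT.degree = c(r1 = 1, r2 = 2, r3 = 3)),
                p = list(CT.degree = c(r1 = 0.0001, r2 = 0.002, r3 = 0.2)),
                q = list(CT.degree = c(r1 = 0.0005, r2 = 0.005, r3 = 0.3)))))
  class(fit) <- "sca"
  rep <- significance_report(fit)
  expect_equal(rep$full$tier, c("alpha2", "alpha1", "ns"))
  expect_equal(nrow(rep$significant), 2L)
})

test_that("planted effects are recovered by the end-to-end chain", {
  regions <- c(2L, 7L)
  cfg <- cohort_config(n_hc = 34, n_et = 34, n_cortical = 12,
                       n_noncortical = 0,
                       planted_effects = list(
                         planted_effect("ET_pre", "CT", regions, 2.2)),
                       seed = 77)
  cohort <- residualize_cohort(simulate_cohort(cfg))
  sub <- sca_subcases("CT", pairs = list())
  sub <- sub[sub$metric == "degree", ]
  fit <- sca(cohort, contrasts = "HC_minus_ETpre", grid = small_grid,
             n_permutations = 200L, subcases = sub, seed = 78,
             check_connected = FALSE, fdr_scope = "per_subcase")
  cf <- fit$contrasts$HC_minus_ETpre
  # boosted covariance in ET_pre: HC minus ET_pre is negative there
  expect_true(all(cf$delta$CT.degree[regions] < 0))
  expect_true(all(rank(cf$p$CT.degree)[regions] <= 4))
})
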