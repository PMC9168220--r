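test_that("cohort generation is reproducible from its seed", {
  cfg <- tiny_config(seed = 7L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$data, c2$data)
  expect_identical(c1$subjects, c2$subjects)
  c3 <- simulate_cohort(tiny_config(seed = 8L))
  expect_false(identical(c1$data$HC$CT, c3$data$HC$CT))
})

test_that("group sizes, pairing and atlas dimensions match the configuration", {
  cohort <- simulate_cohort(cohort_config(n_cortical = 8, n_noncortical = 3,
                                          seed = 1))
  expect_equal(nrow(cohort$data$HC$CT), 29L)
  expect_equal(nrow(cohort$data$ET_pre$CT), 34L)
  expect_equal(dim(cohort$data$HC$VOL), c(29L, 3L))
  sub <- cohort$subjects
  expect_equal(sum(sub$group == "HC"), 29L)
  expect_identical(sub$pair_id[sub$group == "ET_pre"],
                   sub$pair_id[sub$group == "ET_post"])
  expect_true(all(sub$pair_id[sub$group == "HC"] == ""))
  expect_equal(sum(cohort$atlas$cortical), 8L)
  expect_equal(nrow(cohort$atlas), 11L)
})

test_that("zero loadings give independent regions", {
  cfg <- cohort_config(n_hc = 2000, n_et = 2, n_cortical = 6,
                       n_noncortical = 0, loading_scale = 0,
                       confound_betas = NULL, seed = 5)
  M <- simulate_cohort(cfg)$data$HC$CT
  R <- cor(M)
  expect_lt(max(abs(R[upper.tri(R)])), 0.1)
})

test_that("a single uniform factor with vanishing noise drives correlations to one", {
  cfg <- cohort_config(n_hc = 200, n_et = 2, n_cortical = 5,
                       n_noncortical = 0, n_factors = 1, loading_sd = 0,
                       community_loading = 0, noise_sd = 1e-6, seed = 5)
  M <- simulate_cohort(cfg)$data$HC$CT
  R <- cor(M)
  expect_gt(min(R), 1 - 1e-6)
})

test_that("empirical correlations converge to the population structure", {
  cfg <- cohort_config(n_hc = 5000, n_et = 2, n_cortical = 10,
                       n_noncortical = 0, seed = 9)
  pop <- population_correlation(cfg)$same$CT
  M <- simulate_cohort(cfg)$data$HC$CT
  expect_lt(max(abs(cor(M) - pop)), 0.05)
})

test_that("cross-property coupling shows up in cross-correlations at the configured level", {
  cfg <- cohort_config(n_hc = 5000, n_et = 2, n_cortical = 10,
                       n_noncortical = 0, cross_property_coupling = 0.75,
                       seed = 13)
  cohort <- simulate_cohort(cfg)
  pop <- population_correlation(cfg)$cross$CT_SA
  emp <- cor(cohort$data$HC$CT, cohort$data$HC$SA)
  expect_lt(max(abs(emp - pop)), 0.05)
  # decoupled configuration: cross-correlations collapse
  cfg0 <- cohort_config(n_hc = 5000, n_et = 2, n_cortical = 10,
                        n_noncortical = 0, cross_property_coupling = 0,
                        seed = 13)
  emp0 <- cor(simulate_cohort(cfg0)$data$HC$CT,
              simulate_cohort(cfg0)$data$HC$SA)
  expect_lt(max(abs(emp0)), 0.1)
})

test_that("pre/post subject factors correlate at the configured level", {
  cfg <- cohort_config(n_hc = 2, n_et = 3000, n_cortical = 6,
                       n_noncortical = 0,
                       pre_post_subject_correlation = 0.7, seed = 3)
  cohort <- simulate_cohort(cfg)
  # same region pre vs post across pairs: correlation approx r * signal share
  pre <- cohort$data$ET_pre$CT
  post <- cohort$data$ET_post$CT
  robs <- mean(sapply(seq_len(ncol(pre)), function(j) cor(pre[, j], post[, j])))
  # expected value is r times the signal share of variance (~0.8 here),
  # i.e. clearly between the uncorrelated and fully-shared extremes
  expect_gt(robs, 0.4)
  expect_lt(robs, 0.7)
})

test_that("planted loading boosts raise covariance-graph degree where planted", {
  # regions spread across community blocks; extra noise keeps correlations
  # away from saturation so the boost is visible in degree
  regions <- c(2L, 6L, 10L)
  cfg <- cohort_config(n_hc = 1000, n_et = 1000, n_cortical = 12,
                       n_noncortical = 0, noise_sd = 1.5,
                       planted_effects = list(
                         planted_effect("HC", "CT", regions, 2.5)),
                       seed = 21)
  cohort <- simulate_cohort(cfg)
  d_hc <- weighted_degree(structural_covariance(cohort$data$HC$CT)$weights)
  d_et <- weighted_degree(structural_covariance(cohort$data$ET_pre$CT)$weights)
  gain <- d_hc - d_et
  expect_true(all(gain[regions] > 0))
  expect_gt(mean(gain[regions]), mean(gain[-regions]))
})

test_that("planted-effect validation rejects bad configurations", {
  expect_error(cohort_config(n_cortical = 5, n_noncortical = 0,
                             planted_effects = list(
                               planted_effect("HC", "CT", 6L, 2))),
               "out of bounds")
  expect_error(cohort_config(planted_effects = list(
    planted_effect("HC", "XX", 1L, 2))), "absent")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(pre_post_subject_correlation = 1.5), "\\[0, 1\\]")
})

test_that("clinical score simulation honors requested moments and pairing", {
  sm <- clinical_summary("ADL", 29.59, 11.39, 10000, 6.03, 11.26, 10000)
  tab <- generate_clinical_scores(sm, pairing_correlation = 0.5, seed = 2)
  expect_lt(abs(mean(tab$pre) - 29.59), 0.5)
  expect_lt(abs(sd(tab$pre) - 11.39), 0.5)
  expect_lt(abs(mean(tab$post) - 6.03), 0.5)
  expect_lt(abs(sd(tab$post) - 11.26), 0.5)

  # degenerate copy: perfect pairing with equal moments
  sm2 <- clinical_summary("X", 5, 2, 50, 5, 2, 50)
  tab2 <- generate_clinical_scores(sm2, pairing_correlation = 1, seed = 3)
  expect_equal(tab2$post, tab2$pre)

  expect_identical(generate_clinical_scores(sm, 0.5, seed = 9),
                   generate_clinical_scores(sm, 0.5, seed = 9))
  expect_error(generate_clinical_scores(sm, 1.2), "pairing_correlation")
  expect_error(clinical_summary("X", 1, 0, 10, 1, 1, 10), "positive")
})

test_that("the full atlas carries the expected parcel numbering", {
  atlas <- region_atlas()
  expect_equal(nrow(atlas), 87L)
  expect_equal(sum(atlas$cortical), 68L)
  # 1-based positions of landmark regions in the conventional ordering
  expect_equal(atlas$name[15], "lh-parahippocampal")
  expect_equal(atlas$name[20], "lh-pericalcarine")
  expect_equal(atlas$name[38], "rh-cuneus")
  expect_equal(atlas$name[71], "Left-Thalamus-Proper")
  expect_false(anyDuplicated(atlas$name) > 0)
})
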