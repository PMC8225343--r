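# Gaussian-on-log generator configurations give exact model match for
# recovery checks; sizes are kept moderate so the suite stays fast
expr_cfg <- function(..., seed = 1)
  simulation_config(expr_noise = "gaussian_log", seed = seed, ...)

test_that("state shifts injected by the generator are recovered", {
  cfg <- expr_cfg(n_accessions = 200, n_genes = 500, seed = 42)
  tr <- simulate_state_matrix(cfg)
  ex <- simulate_expression(tr$states, cfg)
  res <- state_expression_contrasts(ex, tr$states)
  ctr <- res$contrasts
  gbm_um <- ctr[contrast == "gbM - UM"]
  expect_lt(abs(gbm_um$estimate - 0.0563), 2 * gbm_um$SE)
  # the full hierarchy gbM > UM > mCHG > mCHH has all-positive contrasts
  expect_true(all(ctr$estimate > 0))
  expect_lt(res$p_state, 1e-6)
})

test_that("a null generator yields null contrasts", {
  cfg <- expr_cfg(n_accessions = 120, n_genes = 300, seed = 7,
                  expr_state_shifts = c(mCHH = 0, mCHG = 0, UM = 0, gbM = 0))
  tr <- simulate_state_matrix(cfg)
  ex <- simulate_expression(tr$states, cfg)
  ctr <- state_expression_contrasts(ex, tr$states)$contrasts
  expect_true(all(abs(ctr$estimate) < 2 * ctr$SE + 1e-12))
})

test_that("permutation machinery is reproducible and degenerate-safe", {
  cfg <- expr_cfg(n_accessions = 40, n_genes = 80, seed = 3)
  tr <- simulate_state_matrix(cfg)
  ex <- simulate_expression(tr$states, cfg)
  p1 <- permutation_calibration(ex, tr$states, n_perm = 5, seed = 11)
  p2 <- permutation_calibration(ex, tr$states, n_perm = 5, seed = 11)
  expect_equal(p1$p_values, p2$p_values)
  p0 <- permutation_calibration(ex, tr$states, n_perm = 0)
  expect_equal(p0$n_perm, 0L)
  expect_length(p0$p_values, 0)
})

test_that("permutation p-values are uniform under the null", {
  # under a no-effect generator the LRT p-values across permutations should
  # look uniform; a Kolmogorov-Smirnov test guards against miscalibration
  cfg <- expr_cfg(n_accessions = 40, n_genes = 100, seed = 19,
                  expr_state_shifts = c(mCHH = 0, mCHG = 0, UM = 0, gbM = 0))
  tr <- simulate_state_matrix(cfg)
  ex <- simulate_expression(tr$states, cfg)
  pc <- permutation_calibration(ex, tr$states, n_perm = 200, seed = 5)
  ks <- suppressWarnings(stats::ks.test(pc$p_values, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the paired median sign test behaves and ignores monotone rescaling", {
  cfg <- expr_cfg(n_accessions = 150, n_genes = 400, seed = 13,
                  expr_state_shifts = c(mCHH = 0, mCHG = 0, UM = 0, gbM = 0))
  tr <- simulate_state_matrix(cfg)
  ex <- simulate_expression(tr$states, cfg)
  res <- paired_median_comparison(ex, tr$states)
  n_test <- res$n_genes - res$n_ties
  se3 <- 3 * sqrt(0.25 / n_test)
  expect_lt(abs(res$proportion - 0.5), se3)
  # with odd group sizes the median is an order statistic, so any strictly
  # monotone transform leaves the comparison unchanged
  set.seed(71)
  states3 <- toy_state_matrix(setNames(
    rep(list(c("gbM", "gbM", "gbM", "UM", "UM", "UM")), 200),
    sprintf("g%03d", 1:200)))
  expr3 <- matrix(rpois(1200, 30), 200, 6, dimnames = dimnames(states3))
  ra <- paired_median_comparison(expr3, states3)
  rb <- paired_median_comparison(expr3^2, states3)
  expect_equal(rb$n_gbM_higher, ra$n_gbM_higher)
  expect_equal(rb$p_value, ra$p_value)
  # degenerate all-higher case: two-sided p = 2 * 0.5^n
  states <- toy_state_matrix(setNames(
    rep(list(c("gbM", "gbM", "UM", "UM")), 10), sprintf("g%02d", 1:10)))
  expr <- matrix(rep(c(10, 10, 1, 1), each = 10), nrow = 10,
                 dimnames = dimnames(states))
  resd <- paired_median_comparison(expr, states)
  expect_equal(resd$proportion, 1)
  expect_equal(resd$p_value, 2 * 0.5^10)
})

test_that("reduced gbM variability is detected by the paired CV test", {
  cfg <- expr_cfg(n_accessions = 100, n_genes = 2000, seed = 23,
                  expr_gbM_sd_factor = 0.8,
                  expr_state_shifts = c(mCHH = 0, mCHG = 0, UM = 0, gbM = 0))
  tr <- simulate_state_matrix(cfg)
  ex <- simulate_expression(tr$states, cfg)
  res <- cv_comparison(ex, tr$states, seed = 2)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$n_UM_more_variable / res$n_genes, 0.5)
  # reproducible downsampling
  res2 <- cv_comparison(ex, tr$states, seed = 2)
  expect_equal(res$p_value, res2$p_value)
  # identical expression in both groups: degenerate, flagged, p = 1
  states <- toy_state_matrix(setNames(
    rep(list(c("gbM", "gbM", "UM", "UM")), 5), sprintf("g%d", 1:5)))
  expr <- matrix(rep(c(3, 7, 3, 7), each = 5), nrow = 5,
                 dimnames = dimnames(states))
  resd <- cv_comparison(expr, states)
  expect_true(resd$all_tied)
  expect_equal(resd$p_value, 1)
})

test_that("CG-count models separate sequence and epiallelic effects", {
  cfg <- expr_cfg(n_accessions = 150, n_genes = 400, seed = 31)
  tr <- simulate_state_matrix(cfg)
  cg <- simulate_cg_counts(tr$states, cfg)
  ex <- simulate_expression(tr$states, cfg, cg = cg)
  res <- cg_count_models(ex, tr$states, cg)
  # gbM epialleles carry the injected +1.338 CG-dinucleotide excess
  expect_lt(abs(res$cg_model$gbM_minus_UM - 1.338), 2 * res$cg_model$SE)
  expect_lt(res$cg_model$p_state, 1e-6)
  # the negative #CG slope and the positive state effect keep their signs
  expect_lt(res$expression_model$cg_slope, 0)
  gbm_um <- res$expression_model$contrasts[contrast == "gbM - UM"]
  expect_gt(gbm_um$estimate, 0)
})

test_that("degenerate expression inputs raise clear errors", {
  states <- toy_state_matrix(list(g1 = c("UM", "UM", "UM", "UM")))
  expr <- matrix(5, 1, 4, dimnames = dimnames(states))
  expect_error(state_expression_contrasts(expr, states))
  expect_error(paired_median_comparison(expr, states), "gbM")
  # constant #CG drops the covariate with a warning
  cfg <- expr_cfg(n_accessions = 60, n_genes = 100, seed = 37)
  tr <- simulate_state_matrix(cfg)
  ex <- simulate_expression(tr$states, cfg)
  cg_const <- matrix(50, nrow(ex), ncol(ex), dimnames = dimnames(ex))
  expect_warning(cg_count_models(ex, tr$states, cg_const), "constant")
})
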