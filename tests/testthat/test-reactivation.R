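test_that("relative_log_expression anchors the pre point at zero", {
  expect_equal(relative_log_expression(c(100, 50, 25, 12.5)), c(0, -1, -2, -3))
  expect_equal(relative_log_expression(c(7, 7, 7, 7)), rep(0, 4))
  expect_equal(relative_log_expression(c(100, 100, 50, 50)), c(0, 0, -1, -1))
  expect_error(relative_log_expression(c(1, 2, 3)), "4 time points")
  expect_error(relative_log_expression(c(1, 0, 2, 3)), "positive")
})

test_that("control-drift and leaky-rescue filters use symmetric ratio rules", {
  expect_true(control_drift_filter(c(100, 90, 95, 119)))   # 19% < 20%
  expect_false(control_drift_filter(c(100, 90, 95, 125)))  # 25% > 20%
  expect_false(control_drift_filter(c(100, 90, 95, 80)))   # ratio 1.25

  expect_true(leaky_rescue_filter(100, 100))
  expect_false(leaky_rescue_filter(160, 100))  # 60% > 50%
  expect_false(leaky_rescue_filter(100, 160))  # symmetric
  expect_true(leaky_rescue_filter(149, 100))
})

test_that("annotation_filter drops low-confidence and missing genes", {
  ann <- data.frame(gene_id = c("a", "b"), high_confidence = c(TRUE, FALSE))
  expect_equal(annotation_filter(c("a", "b"), ann), c(TRUE, FALSE))
  expect_warning(keep <- annotation_filter(c("a", "zz"), ann), "absent")
  expect_equal(keep, c(TRUE, FALSE))
})

test_that("fit_slope matches closed-form least squares", {
  expect_equal(fit_slope(c(0, -1, -2, -3)), -1)
  expect_equal(fit_slope(c(0, 0, 0, 0)), 0)
  expect_equal(fit_slope(c(0, -1, -1, -2)), -0.6) # Sxy = -3, Sxx = 5
  # invariant to adding a constant
  set.seed(10)
  for (i in 1:25) {
    y <- rnorm(4)
    expect_equal(fit_slope(y + runif(1, -50, 50)), fit_slope(y),
                 tolerance = 1e-9)
  }
})

test_that("relative_slope subtracts control from experimental", {
  expect_equal(relative_slope(-1.0, -0.2), -0.8)
  expect_equal(relative_slope(-0.6, 0.1), -0.7)
  s <- fit_slope(c(0, -0.4, -0.9, -1.1))
  expect_equal(relative_slope(s, s), 0)
})

test_that("relative slope is invariant to per-condition rescaling", {
  set.seed(11)
  for (i in 1:25) {
    ex <- 2^rnorm(4, 8, 1); ct <- 2^rnorm(4, 8, 1)
    base <- relative_slope(fit_slope(relative_log_expression(ex)),
                           fit_slope(relative_log_expression(ct)))
    ex2 <- ex * runif(1, 0.1, 10); ct2 <- ct * runif(1, 0.1, 10)
    resc <- relative_slope(fit_slope(relative_log_expression(ex2)),
                           fit_slope(relative_log_expression(ct2)))
    expect_equal(resc, base, tolerance = 1e-9)
  }
})

test_that("pearson_time_correlation matches hand computations", {
  expect_equal(pearson_time_correlation(c(0, -1, -2, -3)), -1)
  # Sxy = -1.5, Sxx = 5, Syy = 6.75
  expect_equal(pearson_time_correlation(c(3, 1, 4, 1)), -1.5 / sqrt(33.75))
  expect_equal(pearson_time_correlation(c(0, -1, -1, -2)), -3 / sqrt(10))
  expect_true(is.na(pearson_time_correlation(c(2, 2, 2, 2))))
})

test_that("the exhaustive permutation test enumerates all 24 orderings", {
  # strictly decreasing distinct values uniquely minimize r -> p = 1/24
  expect_equal(permutation_test(c(0, -1, -2, -3)), 1 / 24)
  # constant series -> p = 1 by convention
  expect_equal(permutation_test(c(0.3, 0.3, 0.3, 0.3)), 1)
  # second-most-extreme arrangement -> p = 2/24 (verified by enumeration)
  expect_equal(permutation_test(c(0, -1.5, -1, -3)), 2 / 24)
  # tied values are counted in the tail: [0, 0, s, 2s] has a 2-permutation tie
  expect_equal(permutation_test(c(0, 0, -1, -2)), 2 / 24)
})

test_that("exhaustive p equals brute force and lies on the k/24 lattice", {
  set.seed(12)
  for (i in 1:100) {
    d <- rnorm(4)
    p <- permutation_test(d)
    expect_equal(p, perm_p_bruteforce(d))
    expect_equal(p * 24, round(p * 24), tolerance = 1e-9)
  }
})

test_that("the Monte-Carlo path converges to the exhaustive p", {
  set.seed(13)
  for (i in 1:5) {
    d <- rnorm(4)
    p_ex <- permutation_test(d)
    p_mc <- permutation_test(d, exhaustive = FALSE, seed = 99,
                             n_draws = 100000L)
    expect_lt(abs(p_mc - p_ex), 0.01)
  }
})

test_that("fold_decay_4h is the pre/4h expression ratio", {
  expect_equal(fold_decay_4h(c(100, 70, 30, 12.5)), 8)
  expect_equal(fold_decay_4h(c(55, 55, 55, 55)), 1)
  expect_equal(fold_decay_4h(c(100, 120, 150, 200)), 0.5)
})

test_that("call_reactivation_targets applies all criteria conjunctively", {
  row <- function(fold, slope, p, drift = FALSE, leaky = FALSE, ann = FALSE) {
    data.frame(gene_id = "g", fold_decay_4h = fold, relative_slope = slope,
               perm_p = p, flag_control_drift = drift,
               flag_leaky_rescue = leaky, flag_low_annotation = ann)
  }
  expect_true(call_reactivation_targets(row(2.0, -0.3, 1 / 24)))
  expect_false(call_reactivation_targets(row(1.7, -0.5, 1 / 24)))  # fold
  expect_false(call_reactivation_targets(row(2.0, 0.0, 1 / 24)))   # slope
  expect_false(call_reactivation_targets(row(2.0, -0.3, 0.1)))     # strict p
  expect_false(call_reactivation_targets(row(2.0, -0.3, 1 / 24, drift = TRUE)))
  expect_false(call_reactivation_targets(row(2.0, -0.3, 1 / 24, leaky = TRUE)))
  expect_false(call_reactivation_targets(row(2.0, -0.3, 1 / 24, ann = TRUE)))
})

test_that("flat series are never targets regardless of thresholds", {
  tc <- expand.grid(gene_id = "flat", condition = c("experimental", "control"),
                    timepoint = 1:4, replicate = 1L,
                    stringsAsFactors = FALSE)
  tc$expression <- 500
  for (fold_min in c(0.5, 1.8)) {
    for (p_max in c(0.5, 0.99)) {
      res <- reactivation_analysis(
        tc, config = pipeline_config(fold_decay_min = fold_min,
                                     perm_alpha = p_max))
      expect_false(res$is_target)
    }
  }
})

test_that("replicates are averaged on the log2 scale before fitting", {
  # two replicates whose log2 mean is an exact halving series
  tc <- expand.grid(gene_id = "g", condition = c("experimental", "control"),
                    timepoint = 1:4, replicate = 1:2,
                    stringsAsFactors = FALSE)
  exp_vals <- c(100, 50, 25, 12.5)
  tc$expression <- ifelse(tc$condition == "experimental",
                          exp_vals[tc$timepoint] * ifelse(tc$replicate == 1, 2, 0.5),
                          100)
  res <- reactivation_analysis(tc, config = pipeline_config())
  expect_equal(res$slope_exp, -1, tolerance = 1e-9)
  expect_equal(res$slope_ctrl, 0, tolerance = 1e-9)
  expect_equal(res$fold_decay_4h, 8, tolerance = 1e-9)
})

test_that("noise-free synthetic recovery is exact", {
  cfg <- generator_config(n_genes = 400, p_direct = 0.05, p_indirect_up = 0.05,
                          p_heatshock = 0, p_leaky = 0, p_lowexpr = 0,
                          noise_sd = 0, prev_high_confidence = 1)
  ds <- generate_dataset(cfg, 23)
  res <- reactivation_analysis(ds$timecourse, ds$annotation,
                               pipeline_config())
  expect_setequal(res$gene_id[res$is_target],
                  ds$truth$gene_id[ds$truth$class == "direct_target"])
})

test_that("artifact classes are screened out by their dedicated filters", {
  cfg <- generator_config(n_genes = 500, p_direct = 0.1, p_indirect_up = 0,
                          p_heatshock = 0.2, p_leaky = 0.2, p_lowexpr = 0,
                          noise_sd = 0, prev_high_confidence = 1)
  ds <- generate_dataset(cfg, 24)
  res <- reactivation_analysis(ds$timecourse, ds$annotation,
                               pipeline_config())
  cls <- ds$truth$class[match(res$gene_id, ds$truth$gene_id)]
  expect_setequal(res$gene_id[res$is_target],
                  ds$truth$gene_id[ds$truth$class == "direct_target"])
  # every leaky-rescue gene trips the leaky filter (offset drawn above 1.5)
  expect_true(all(res$flag_leaky_rescue[cls == "leaky_rescue"]))
  expect_false(any(res$is_target[cls == "heatshock_artifact"]))
})
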