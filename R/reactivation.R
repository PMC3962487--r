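#' Reactivation time-course target calling
#'
#' The core caller. For each gene with a paired experimental (rescue cDNA) and
#' control (no cDNA) 4-point series, expression is expressed on a log2 scale
#' relative to the pre-heat-shock point within each condition, least-squares
#' decay slopes are fit against ordinal time 1–4, and a gene is called a
#' direct-target candidate when it survives the control-drift, leaky-rescue
#' and annotation filters, decays at least `fold_decay_min`-fold by 4 h in the
#' rescue condition, has a negative relative slope (experimental minus
#' control), and its experimental-minus-control series is significantly
#' associated with time by an exhaustive 24-permutation test.
#'
#' @name reactivation
NULL

#' Log2 expression relative to the pre-heat-shock point
#'
#' @param series Positive expression values over the 4 ordered time points.
#' @return Length-4 numeric: `log2(series / series[1])`; the pre value is 0.
#' @export
relative_log_expression <- function(series) {
  if (length(series) != 4) stop("series must have 4 time points", call. = FALSE)
  if (any(!is.finite(series)) || any(series <= 0)) {
    stop("expression values must be positive", call. = FALSE)
  }
  log2(series / series[1])
}

#' Control-drift filter
#'
#' Drops genes whose control series changed by more than `drift_max`
#' (fraction, default 20%) between the pre and 4 h points, in either
#' direction: drop iff `max(pre/4h, 4h/pre) > 1 + drift_max`.
#'
#' @param control_series Control-condition expression over the 4 points.
#' @param drift_max Maximum tolerated fractional change.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
control_drift_filter <- function(control_series, drift_max = 0.20) {
  x <- control_series
  r <- max(x[1] / x[4], x[4] / x[1])
  r <= 1 + drift_max
}

#' Leaky-rescue filter
#'
#' Drops genes whose expression differs by more than `diff_max` (fraction,
#' default 50%) between the two conditions already at the pre-heat-shock
#' point, in either direction.
#'
#' @param pre_exp,pre_ctrl Pre-point expression in the experimental and
#'   control conditions (both positive).
#' @param diff_max Maximum tolerated fractional difference.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
leaky_rescue_filter <- function(pre_exp, pre_ctrl, diff_max = 0.50) {
  stopifnot(pre_exp > 0, pre_ctrl > 0)
  max(pre_exp / pre_ctrl, pre_ctrl / pre_exp) <= 1 + diff_max
}

#' Annotation-confidence filter
#'
#' Keeps only genes flagged as high-confidence in the annotation table; genes
#' absent from the table are dropped with a warning.
#'
#' @param gene_ids Character vector of gene ids to check.
#' @param annotation Annotation table with `gene_id` and `high_confidence`.
#' @return Logical keep vector aligned with `gene_ids`.
#' @export
annotation_filter <- function(gene_ids, annotation) {
  idx <- match(gene_ids, annotation$gene_id)
  keep <- !is.na(idx) & annotation$high_confidence[replace(idx, is.na(idx), 1L)]
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " gene(s) absent from annotation; dropped")
    keep[is.na(idx)] <- FALSE
  }
  keep
}

#' Ordinary least-squares slope against ordinal time
#'
#' @param log_rel Four log2 values (typically from
#'   [relative_log_expression()]).
#' @param ordinal Abscissae; always the ordinal time values 1–4.
#' @return Slope in log2 units per ordinal unit.
#' @export
fit_slope <- function(log_rel, ordinal = 1:4) {
  stopifnot(length(log_rel) == length(ordinal))
  xc <- ordinal - mean(ordinal)
  sum(xc * (log_rel - mean(log_rel))) / sum(xc^2)
}

#' Relative decay slope
#'
#' Slope of the experimental (rescue) condition minus the slope of the
#' control condition, both in log2 units per ordinal unit.
#'
#' @param slope_exp,slope_ctrl Per-condition slopes from [fit_slope()].
#' @return The difference `slope_exp - slope_ctrl`.
#' @export
relative_slope <- function(slope_exp, slope_ctrl) slope_exp - slope_ctrl

#' Pearson correlation with ordinal time
#'
#' @param values Four reals.
#' @param ordinal Ordinal time values 1–4.
#' @return Pearson r in `[-1,1]`, or `NA` when `values` has zero variance
#'   (callers treat that as no association).
#' @export
pearson_time_correlation <- function(values, ordinal = 1:4) {
  if (stats::sd(values) == 0) return(NA_real_)
  stats::cor(values, ordinal)
}

.perm_orders <- local({
  # all 24 orderings of the 4 ordinal labels, identity first
  p <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  p <- p[apply(p, 1L, function(r) length(unique(r)) == 4L), , drop = FALSE]
  p <- p[order(p[, 1], p[, 2], p[, 3], p[, 4]), , drop = FALSE]
  dimnames(p) <- NULL
  p
})
# centered permutation matrix; every row has sum of squares 5
.perm_centered <- .perm_orders - 2.5

#' Permutation test for association between decay and time
#'
#' The statistic is the Pearson correlation of the experimental-minus-control
#' log2-relative series with ordinal time. The exhaustive test enumerates all
#' 24 permutations of the four ordinal labels; the one-sided p-value is the
#' fraction of permutations (identity included, ties counted) whose
#' correlation is at most the observed one, so attainable p-values lie on the
#' lattice k/24. A zero-variance series returns p = 1.
#'
#' @param diff_series Four experimental-minus-control log2-relative values.
#' @param exhaustive If `FALSE`, a Monte-Carlo approximation with `n_draws`
#'   random permutations (identity always included) is used instead.
#' @param seed Seed for the Monte-Carlo path.
#' @param n_draws Number of Monte-Carlo draws.
#' @return One-sided p-value.
#' @export
permutation_test <- function(diff_series, exhaustive = TRUE, seed = 1L,
                             n_draws = 10000L) {
  stopifnot(length(diff_series) == 4)
  if (stats::sd(diff_series) == 0) return(1)
  r_obs <- stats::cor(diff_series, 1:4)
  if (exhaustive) {
    dc <- diff_series - mean(diff_series)
    rs <- as.numeric(.perm_centered %*% dc) / sqrt(5 * sum(dc^2))
    return(sum(rs <= r_obs + 1e-12) / nrow(.perm_orders))
  }
  set.seed(seed)
  # drawing a uniform random permutation = drawing a row of the 24-row table
  dc <- diff_series - mean(diff_series)
  rs <- as.numeric(.perm_centered %*% dc) / sqrt(5 * sum(dc^2))
  idx <- sample.int(nrow(.perm_orders), n_draws, replace = TRUE)
  (1L + sum(rs[idx] <= r_obs + 1e-12)) / (n_draws + 1L)
}

#' Fold decay over the 4-hour window
#'
#' Ratio of pre-heat-shock to 4 h expression in the rescue (experimental)
#' condition; values below 1 indicate an increase.
#'
#' @param exp_series Experimental-condition expression over the 4 points.
#' @return `x_pre / x_4h`.
#' @export
fold_decay_4h <- function(exp_series) {
  stopifnot(all(exp_series > 0))
  exp_series[1] / exp_series[4]
}

.tc_series <- function(timecourse) {
  # average replicates on the log2 scale within condition x time point,
  # return per-gene 4-vectors for both conditions
  key <- paste(timecourse$gene_id, timecourse$condition, timecourse$timepoint,
               sep = "\r")
  l2 <- tapply(log2(timecourse$expression), key, mean)
  parts <- do.call(rbind, strsplit(names(l2), "\r", fixed = TRUE))
  df <- data.frame(gene_id = parts[, 1], condition = parts[, 2],
                   timepoint = as.integer(parts[, 3]),
                   l2 = as.numeric(l2), stringsAsFactors = FALSE)
  split(df, df$gene_id)
}

#' Compute per-gene reactivation statistics
#'
#' Averages replicates on the log2 scale within condition and time point,
#' computes log2-relative series, per-condition slopes, the relative slope,
#' the Pearson correlation of the difference series with ordinal time, the
#' exhaustive permutation p, the 4 h fold decay, and the three filter flags.
#'
#' @param timecourse Long-format time course (gene_id, condition, timepoint,
#'   replicate, expression) with conditions `experimental` and `control` and
#'   time points 1–4.
#' @param annotation Optional annotation table for the confidence filter; when
#'   `NULL` no gene is flagged for annotation.
#' @param config A [pipeline_config()] holding the thresholds.
#' @return A `reactivation_result` data.frame, one row per gene, including
#'   `is_target`.
#' @export
reactivation_analysis <- function(timecourse, annotation = NULL,
                                  config = pipeline_config()) {
  validate_pipeline_config(config)
  need <- c("gene_id", "condition", "timepoint", "expression")
  if (!all(need %in% names(timecourse))) {
    stop("timecourse lacks required columns", call. = FALSE)
  }
  if (any(timecourse$expression <= 0)) {
    stop("expression values must be positive", call. = FALSE)
  }
  genes <- unique(timecourse$gene_id)
  per <- .tc_series(timecourse)

  stats_mat <- vapply(genes, function(g) {
    d <- per[[g]]
    ie <- d$condition == "experimental"
    ex <- 2^d$l2[ie][order(d$timepoint[ie])]
    ct <- 2^d$l2[!ie][order(d$timepoint[!ie])]
    if (length(ex) != 4 || length(ct) != 4) {
      stop("gene ", g, ": need all four time points in both conditions",
           call. = FALSE)
    }
    rel_e <- relative_log_expression(ex)
    rel_c <- relative_log_expression(ct)
    se <- fit_slope(rel_e)
    sc <- fit_slope(rel_c)
    diff <- rel_e - rel_c
    r <- pearson_time_correlation(diff)
    c(se, sc, se - sc, ifelse(is.na(r), 0, r), permutation_test(diff),
      fold_decay_4h(ex),
      !control_drift_filter(ct, config$control_drift_max),
      !leaky_rescue_filter(ex[1], ct[1], config$leaky_diff_max))
  }, numeric(8))
  out <- data.frame(
    gene_id = genes,
    slope_exp = stats_mat[1, ], slope_ctrl = stats_mat[2, ],
    relative_slope = stats_mat[3, ], pearson_r = stats_mat[4, ],
    perm_p = stats_mat[5, ], fold_decay_4h = stats_mat[6, ],
    flag_control_drift = as.logical(stats_mat[7, ]),
    flag_leaky_rescue = as.logical(stats_mat[8, ]),
    stringsAsFactors = FALSE
  )
  if (is.null(annotation)) {
    out$flag_low_annotation <- FALSE
  } else {
    out$flag_low_annotation <- !annotation_filter(out$gene_id, annotation)
  }
  out$is_target <- call_reactivation_targets(out, config$fold_decay_min,
                                             config$perm_alpha)
  rownames(out) <- NULL
  out
}

#' Apply the direct-target calling criteria
#'
#' A gene is a target iff no filter flag is set, its 4 h fold decay is at
#' least `fold_min`, its (unrounded) relative slope is negative, and its
#' permutation p is strictly below `p_max`. All analyzed non-targets form the
#' non-direct control set.
#'
#' @param results A `reactivation_result` table (filter flags and statistics
#'   computed).
#' @param fold_min Minimum 4 h fold decay (default 1.8).
#' @param p_max Permutation-p threshold (default 0.1), strict.
#' @return Logical target-call vector aligned with `results`.
#' @export
call_reactivation_targets <- function(results, fold_min = 1.8, p_max = 0.1) {
  !results$flag_control_drift &
    !results$flag_leaky_rescue &
    !results$flag_low_annotation &
    results$fold_decay_4h >= fold_min &
    results$relative_slope < 0 &
    results$perm_p < p_max
}
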