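#' Steady-state differential expression in the NMD mutant
#'
#' A simplified negative-binomial exact test in the DESeq style: per-sample
#' size factors by median-of-ratios, per-gene method-of-moments dispersion
#' pooled across conditions, and a conditional exact test on the split of the
#' two-condition total. Raw p-values are thresholded (no FDR adjustment).
#'
#' @name steady_state_de
NULL

.counts_matrix <- function(counts) {
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$gene_id
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  m
}

.split_conditions <- function(counts, sample_info) {
  m <- .counts_matrix(counts)
  if (is.null(sample_info)) {
    cond <- ifelse(grepl("^(ctrl|control)", colnames(m)), "control", "mutant")
  } else {
    cond <- sample_info$condition[match(colnames(m), sample_info$sample)]
  }
  if (!all(c("control", "mutant") %in% cond)) {
    stop("need at least one sample per condition", call. = FALSE)
  }
  list(m = m, cond = cond)
}

#' Filter to genes detected in every sample
#'
#' @param counts Count table (gene_id + one integer column per sample).
#' @return The table restricted to genes with a positive count in all samples.
#' @export
detection_filter <- function(counts) {
  m <- .counts_matrix(counts)
  keep <- apply(m > 0, 1L, all)
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-positive genes of the ratio of its
#' count to the gene's geometric mean across samples.
#'
#' @param counts Count table.
#' @return Named numeric vector of positive per-sample factors.
#' @export
estimate_size_factors <- function(counts) {
  m <- .counts_matrix(counts)
  allpos <- apply(m > 0, 1L, all)
  if (!any(allpos)) {
    stop("no gene has positive counts in every sample; cannot normalize",
         call. = FALSE)
  }
  lg <- log(m[allpos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2L, stats::median)
}

#' Method-of-moments NB dispersion
#'
#' On size-factor-normalized counts, within-condition sample variances are
#' pooled and the dispersion solved from `var = mean + alpha * mean^2`,
#' truncated at zero: `alpha = max(0, (s2 - m) / m^2)`.
#'
#' @param counts Count table.
#' @param factors Size factors from [estimate_size_factors()].
#' @param sample_info Optional sample metadata (`sample`, `condition`);
#'   defaults to inferring condition from `ctrl*`/`mut*` column names.
#' @return Per-gene non-negative dispersion vector.
#' @export
estimate_dispersion <- function(counts, factors, sample_info = NULL) {
  sp <- .split_conditions(counts, sample_info)
  k <- sweep(sp$m, 2L, factors, "/")
  conds <- unique(sp$cond)
  ss <- 0; df <- 0
  for (cc in conds) {
    kc <- k[, sp$cond == cc, drop = FALSE]
    if (ncol(kc) >= 2) {
      ss <- ss + apply(kc, 1L, stats::var) * (ncol(kc) - 1)
      df <- df + ncol(kc) - 1
    }
  }
  mbar <- rowMeans(k)
  if (df == 0) return(stats::setNames(rep(0, nrow(k)), rownames(k)))
  s2 <- ss / df
  disp <- pmax(0, (s2 - mbar) / mbar^2)
  disp[!is.finite(disp)] <- 0
  stats::setNames(disp, rownames(k))
}

#' Conditional NB exact test for one gene
#'
#' Given the total count across both conditions, sums the probabilities of all
#' splits as or less likely than the observed split under the null model in
#' which both condition totals are NB with means proportional to their summed
#' size factors and common dispersion. With dispersion 0 the NB reduces to
#' Poisson and the conditional law of the split is binomial.
#'
#' @param k_a,k_b Summed counts in conditions A and B.
#' @param s_a,s_b Summed size factors for the two conditions.
#' @param dispersion Common NB dispersion (>= 0).
#' @return Two-sided exact p-value in `[0,1]`; total 0 gives 1 by convention.
#' @export
nb_exact_test <- function(k_a, k_b, s_a, s_b, dispersion = 0) {
  stopifnot(dispersion >= 0, s_a > 0, s_b > 0)
  k <- k_a + k_b
  if (k == 0) return(1)
  q0 <- k / (s_a + s_b)
  mu_a <- s_a * q0
  mu_b <- s_b * q0
  a <- 0:k
  if (dispersion == 0) {
    lp <- stats::dpois(a, mu_a, log = TRUE) +
      stats::dpois(k - a, mu_b, log = TRUE)
  } else {
    sz <- 1 / dispersion
    lp <- stats::dnbinom(a, mu = mu_a, size = sz, log = TRUE) +
      stats::dnbinom(k - a, mu = mu_b, size = sz, log = TRUE)
  }
  lobs <- lp[k_a + 1]
  tot <- sum(exp(lp - max(lp)))
  # tolerance guards against ties lost to floating point
  p <- sum(exp(lp[lp <= lobs + 1e-10] - max(lp))) / tot
  min(1, p)
}

#' Run the NB exact test over a count table
#'
#' @param counts Count table (post [detection_filter()] or not).
#' @param sample_info Optional sample metadata; see [estimate_dispersion()].
#' @return A `de_result` data.frame: gene_id, mean_control, mean_mutant,
#'   fold_change (mutant/control; `Inf` when the control mean is zero and the
#'   mutant mean is not), p_value, direction.
#' @export
de_test <- function(counts, sample_info = NULL) {
  sp <- .split_conditions(counts, sample_info)
  factors <- estimate_size_factors(counts)
  disp <- estimate_dispersion(counts, factors, sample_info)
  m <- sp$m
  isc <- sp$cond == "control"
  s_c <- sum(factors[isc]); s_m <- sum(factors[!isc])
  k_c <- rowSums(m[, isc, drop = FALSE])
  k_m <- rowSums(m[, !isc, drop = FALSE])
  norm <- sweep(m, 2L, factors, "/")
  mean_c <- rowMeans(norm[, isc, drop = FALSE])
  mean_m <- rowMeans(norm[, !isc, drop = FALSE])
  fc <- ifelse(mean_c > 0, mean_m / mean_c,
               ifelse(mean_m > 0, Inf, 1))
  p <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_test(k_m[i], k_c[i], s_m, s_c, disp[i])
  }, 0)
  direction <- ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none"))
  data.frame(gene_id = rownames(m), mean_control = mean_c,
             mean_mutant = mean_m, fold_change = fc, p_value = p,
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Call up- and down-regulated genes
#'
#' @param results A `de_result` table from [de_test()].
#' @param alpha Raw p-value threshold in (0,1); strict inequality.
#' @return List with character vectors `up` (p < alpha and fold change > 1)
#'   and `down` (p < alpha and fold change < 1).
#' @export
call_de <- function(results, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  list(
    up = results$gene_id[results$p_value < alpha & results$fold_change > 1],
    down = results$gene_id[results$p_value < alpha & results$fold_change < 1]
  )
}
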