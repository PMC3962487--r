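#' Four-way classification and enrichment
#'
#' Combines steady-state up-regulation calls with reactivation-target calls on
#' a common, well-annotated gene universe, forming the four classes
#' up-and-target, up-not-target, target-not-up, and neither, with a Fisher
#' exact test for enrichment of targets among up-regulated genes.
#'
#' @name classification
NULL

#' Intersect the analyzed gene universes
#'
#' The analyzed universe is the set of genes present in both the DE and the
#' reactivation analyses that pass the annotation-confidence filter.
#'
#' @param de_genes,reactivation_genes Character vectors of gene ids.
#' @param annotation Optional annotation table; when supplied only
#'   high-confidence genes are retained.
#' @return Character vector of analyzed gene ids.
#' @export
intersect_universe <- function(de_genes, reactivation_genes,
                               annotation = NULL) {
  u <- intersect(de_genes, reactivation_genes)
  if (!is.null(annotation)) {
    u <- u[annotation_filter(u, annotation)]
  }
  if (length(u) == 0) stop("empty analyzed gene universe", call. = FALSE)
  u
}

#' Assign the four gene classes
#'
#' @param universe Analyzed gene ids.
#' @param up_set Up-regulated gene ids (subset of `universe`).
#' @param target_set Reactivation-target gene ids (subset of `universe`).
#' @return List with `classes` (data.frame gene_id, class) and `table`, a
#'   named integer vector of the 2x2 contingency cells
#'   `a` = |up & target|, `b` = |up only|, `c` = |target only|, `d` = rest.
#' @export
assign_classes <- function(universe, up_set, target_set) {
  if (!all(up_set %in% universe) || !all(target_set %in% universe)) {
    stop("up and target sets must be subsets of the universe", call. = FALSE)
  }
  up <- universe %in% up_set
  tg <- universe %in% target_set
  cls <- ifelse(up & tg, "up_and_target",
         ifelse(up, "up_not_target",
         ifelse(tg, "target_not_up", "neither")))
  tab <- c(a = sum(up & tg), b = sum(up & !tg),
           c = sum(!up & tg), d = sum(!up & !tg))
  list(
    classes = data.frame(gene_id = universe, class = cls,
                         stringsAsFactors = FALSE),
    table = tab
  )
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test with both margins fixed; the two-sided p-value
#' sums the probabilities of all tables whose probability does not exceed the
#' observed table's (minimum-likelihood rule, the common default).
#'
#' @param a,b,c,d Cell counts (row 1: a, b; row 2: c, d), all non-negative.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b          # row-1 margin
  n1 <- a + c         # column-1 margin
  N <- a + b + c + d
  if (N == 0) return(1)
  lo <- max(0, n1 - (N - m))
  hi <- min(n1, m)
  x <- lo:hi
  lp <- stats::dhyper(x, m, N - m, n1, log = TRUE)
  lobs <- stats::dhyper(a, m, N - m, n1, log = TRUE)
  min(1, sum(exp(lp[lp <= lobs + 1e-7])))
}

#' Histogram of relative slopes
#'
#' Bins the relative slopes of a gene subset with fixed-width bins covering
#' the observed range; bin edges are aligned to multiples of the bin width so
#' histograms of different subsets are comparable.
#'
#' @param results A `reactivation_result` table.
#' @param subset Gene ids to include; defaults to all genes in `results`.
#' @param bin_width Bin width in slope units (default 0.1).
#' @return A data.frame with `bin_left`, `bin_right`, `count`; counts sum to
#'   the subset size. Zero rows for an empty subset.
#' @export
slope_distribution <- function(results, subset = results$gene_id,
                               bin_width = 0.1) {
  stopifnot(bin_width > 0)
  s <- results$relative_slope[results$gene_id %in% subset]
  if (length(s) == 0) {
    return(data.frame(bin_left = numeric(0), bin_right = numeric(0),
                      count = integer(0)))
  }
  lo <- floor(min(s) / bin_width)
  hi <- ceiling(max(s) / bin_width)
  if (hi == lo) hi <- lo + 1
  breaks <- (lo:hi) * bin_width
  nb <- length(breaks) - 1L
  idx <- findInterval(s, breaks) # bins are [left, right)
  idx[idx > nb] <- nb            # top edge closed
  data.frame(bin_left = breaks[-length(breaks)],
             bin_right = breaks[-1],
             count = as.integer(tabulate(idx, nbins = nb)))
}

#' Enrichment summary record
#'
#' Reports the fraction of up-regulated genes that are reactivation targets
#' (`a/(a+b)`) and the target rate over the whole universe (`(a+c)/N`), both
#' as percentages, together with the Fisher p-value.
#'
#' @param tab Named cell vector from [assign_classes()].
#' @param p Fisher p-value (computed from `tab` when omitted).
#' @return A one-row data.frame: `pct_up_that_are_targets`,
#'   `pct_universe_targets`, `fisher_p`, plus the cells.
#' @export
enrichment_summary <- function(tab, p = NULL) {
  a <- tab[["a"]]; b <- tab[["b"]]; c <- tab[["c"]]; d <- tab[["d"]]
  if (is.null(p)) p <- fisher_exact(a, b, c, d)
  N <- a + b + c + d
  data.frame(
    a = a, b = b, c = c, d = d,
    pct_up_that_are_targets = if (a + b > 0) 100 * a / (a + b) else 0,
    pct_universe_targets = if (N > 0) 100 * (a + c) / N else 0,
    fisher_p = p
  )
}
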