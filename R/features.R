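#' Transcript structural-feature analysis
#'
#' Univariate logistic regressions asking which structural features of a
#' transcript (3' UTR length, per-base folding free energy, CDS/3' UTR length
#' ratio, stop-codon density, and binary flags such as 3' UTR introns or
#' bi-/polycistronic structure) predict direct-target status, plus the
#' feature summary table and 3' UTR length CDFs.
#'
#' @name features
NULL

#' Stop-codon density of a 3' UTR sequence
#'
#' Counts every position i (overlapping scan across all three frames on the
#' given strand) where the trinucleotide starting at i is TAA, TAG or TGA, and
#' divides by the sequence length.
#'
#' @param utr3_sequence Nucleotide string over A, C, G, T.
#' @return Stops per base in `[0,1]`. Sequences shorter than 3 bases return 0
#'   with a warning; invalid characters are an error.
#' @export
stop_codon_density <- function(utr3_sequence) {
  s <- toupper(utr3_sequence)
  if (grepl("[^ACGT]", s)) stop("invalid characters in sequence", call. = FALSE)
  L <- nchar(s)
  if (L < 3) {
    warning("sequence shorter than 3 bases; density 0")
    return(0)
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  tri <- paste0(ch[1:(L - 2)], ch[2:(L - 1)], ch[3:L])
  sum(tri %in% c("TAA", "TAG", "TGA")) / L
}

#' Univariate logistic regression of target status on one feature
#'
#' Fits `target ~ feature` by maximum likelihood (IRLS via [stats::glm()])
#' with an intercept; boolean features are coded 0/1. Reports the slope
#' coefficient (log-odds per unit) and its Wald p-value. Complete separation
#' or non-convergence is flagged and no coefficient is reported.
#'
#' @param feature Numeric or logical vector.
#' @param labels Logical vector (TRUE = target); both classes must be present.
#' @return A one-row data.frame: `coefficient`, `std_error`, `p_value`,
#'   `converged`.
#' @export
logistic_fit <- function(feature, labels) {
  stopifnot(length(feature) == length(labels))
  y <- as.logical(labels)
  if (!any(y) || all(y)) stop("both label classes must be present",
                              call. = FALSE)
  x <- as.numeric(feature)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  # perfect separation: the deviance collapses and the slope diverges (on the
  # sd scale); report no coefficient rather than a spurious one
  slope_sd_units <- if ("x" %in% rownames(co)) {
    abs(co["x", "Estimate"]) * max(stats::sd(x), .Machine$double.eps)
  } else 0
  separated <- !fit$converged ||
    (fit$deviance < 1e-6 && slope_sd_units > 10)
  if (!"x" %in% rownames(co) || separated) {
    return(data.frame(coefficient = NA_real_, std_error = NA_real_,
                      p_value = NA_real_, converged = FALSE))
  }
  data.frame(coefficient = co["x", "Estimate"],
             std_error = co["x", "Std. Error"],
             p_value = co["x", "Pr(>|z|)"],
             converged = TRUE)
}

.feature_cols <- c(
  utr3_length = "quantitative",
  utr3_free_energy = "quantitative",
  cds_utr3_ratio = "quantitative",
  readthrough_candidate = "boolean",
  bicistronic = "boolean",
  utr3_intron = "boolean",
  utr3_stop_density = "quantitative",
  polycistronic = "boolean"
)

#' Feature summary across the four gene classes
#'
#' For each structural feature, the mean (quantitative) or count (boolean)
#' within the nonresponding set and within each compared set (up-regulated,
#' reactivation targets, up-regulated reactivation targets), plus the
#' univariate logistic p-value of each compared set against the nonresponding
#' set. The regression universe for each p is the union of the nonresponding
#' set and the compared set.
#'
#' @param annotation Annotation table.
#' @param classes Class assignment data.frame from [assign_classes()].
#' @return A data.frame with one row per feature and summary/p columns per
#'   set; sets with no genes get `NA` summaries and no p.
#' @export
feature_table <- function(annotation, classes) {
  ann <- annotation[match(classes$gene_id, annotation$gene_id), , drop = FALSE]
  nonresp <- classes$class == "neither"
  sets <- list(
    nonresponding = nonresp,
    up_regulated = classes$class %in% c("up_and_target", "up_not_target"),
    reactivation_targets = classes$class %in% c("up_and_target",
                                                "target_not_up"),
    up_regulated_targets = classes$class == "up_and_target"
  )
  summarize <- function(vals, kind, members) {
    if (!any(members)) return(NA_real_)
    if (kind == "boolean") sum(vals[members]) else mean(vals[members])
  }
  rows <- lapply(names(.feature_cols), function(fname) {
    kind <- .feature_cols[[fname]]
    vals <- ann[[fname]]
    out <- list(feature = fname, kind = kind)
    for (sname in names(sets)) {
      out[[paste0(sname, "_value")]] <- summarize(vals, kind, sets[[sname]])
      if (sname != "nonresponding") {
        members <- sets[[sname]]
        if (any(members) && any(nonresp)) {
          uni <- nonresp | members
          lf <- logistic_fit(vals[uni], members[uni])
          out[[paste0(sname, "_p")]] <- lf$p_value
        } else {
          out[[paste0(sname, "_p")]] <- NA_real_
        }
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  sizes <- vapply(sets, sum, 0L)
  attr(res, "set_sizes") <- sizes
  res
}

#' Cumulative 3' UTR length distributions
#'
#' @param annotation Annotation table with `utr3_length`.
#' @param gene_sets Named list of gene-id vectors.
#' @return Named list; per set a list with `lengths` (sorted),
#'   `cum_pct` (cumulative percentage reaching 100 at the maximum) and
#'   `median`.
#' @export
utr_length_cdf <- function(annotation, gene_sets) {
  stopifnot(is.list(gene_sets))
  lapply(gene_sets, function(g) {
    idx <- match(g, annotation$gene_id)
    if (anyNA(idx)) stop("gene set member absent from annotation",
                         call. = FALSE)
    len <- sort(annotation$utr3_length[idx])
    if (length(len) == 0) {
      return(list(lengths = numeric(0), cum_pct = numeric(0),
                  median = NA_real_))
    }
    list(lengths = len,
         cum_pct = 100 * seq_along(len) / length(len),
         median = stats::median(len))
  })
}
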