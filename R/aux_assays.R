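#' Auxiliary quantifications
#'
#' Small helpers for secondary analyses: the fraction of mappable reads
#' assigned to a feature (e.g. a transposon family or premature-stop-bearing
#' reads), fold changes of such fractions between genotypes, and
#' reference-gene relative qPCR quantification by the 2^-ddCt convention
#' (amplification efficiency fixed at perfect doubling).
#'
#' @name aux_assays
NULL

#' Percentage of reads assigned to a feature
#'
#' @param feature_reads Reads assigned to the feature (>= 0).
#' @param total_reads Total mappable reads (> 0, at least `feature_reads`).
#' @return `100 * feature_reads / total_reads`.
#' @export
read_fraction <- function(feature_reads, total_reads) {
  stopifnot(total_reads > 0, feature_reads >= 0,
            feature_reads <= total_reads)
  100 * feature_reads / total_reads
}

#' Fold change of a read fraction between genotypes
#'
#' @param fraction_mutant,fraction_control Read fractions (percent or
#'   proportion, same units); the control fraction must be positive.
#' @return `fraction_mutant / fraction_control`.
#' @export
fraction_fold_change <- function(fraction_mutant, fraction_control) {
  stopifnot(fraction_control > 0)
  fraction_mutant / fraction_control
}

#' Relative expression by the 2^-ddCt method
#'
#' Target expression in a sample relative to a calibrator sample, each
#' normalized to a reference gene measured in the same sample:
#' `2^-((Ct_target,s - Ct_ref,s) - (Ct_target,c - Ct_ref,c))`.
#'
#' @param sample_ct,calibrator_ct Length-2 numeric vectors
#'   `c(target_ct, reference_ct)` with finite positive cycle values.
#' @return Fold expression of the sample relative to the calibrator.
#' @export
ddct_relative_expression <- function(sample_ct, calibrator_ct) {
  stopifnot(length(sample_ct) == 2, length(calibrator_ct) == 2,
            all(is.finite(c(sample_ct, calibrator_ct))),
            all(c(sample_ct, calibrator_ct) > 0))
  ddct <- (sample_ct[1] - sample_ct[2]) - (calibrator_ct[1] - calibrator_ct[2])
  2^(-ddct)
}
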