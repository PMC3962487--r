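#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure of an in vivo NMD
#' reactivation study: a steady-state RNA-seq contrast between an NMD-pathway
#' hypomorph and a wild-type control (negative-binomial counts, ~4% of genes
#' up-regulated between 1.8- and 330-fold), a 4-point rescue time course in
#' which direct decay targets lose transcript exponentially only after pathway
#' reactivation, and per-gene structural annotations in which direct targets
#' carry longer 3' UTRs (median 423 vs 218 bases).
#'
#' Class proportions: `p_direct` defaults to 0.023 (2.3% of the analyzed
#' universe are direct reactivation targets); `p_indirect_up` genes hold an
#' elevated steady-state level but do not decay within the 4 h window;
#' `p_heatshock` genes carry a transient shared by both conditions;
#' `p_leaky` genes differ between conditions already before heat shock;
#' `p_lowexpr` genes are noisy low-expressed genes. Whatever remains is
#' unaffected. A fraction `p_up_given_direct` of direct targets is also
#' up-regulated at steady state (most direct targets are buffered and show no
#' steady-state change).
#'
#' @param n_genes Number of genes.
#' @param p_direct,p_indirect_up,p_heatshock,p_leaky,p_lowexpr Class
#'   proportions in `[0,1]`; their sum must be at most 1.
#' @param p_up_given_direct Probability that a direct target is also
#'   steady-state up-regulated.
#' @param fold_change_range Steady-state mutant/control fold-change range for
#'   up-regulated genes (log-uniform draw).
#' @param fold_decay_range 4 h fold-decay range for direct targets
#'   (uniform draw); the implied per-ordinal-unit log2 decay slope is
#'   `-log2(F)/3` since log2 expression is linear over ordinal times 1–4.
#' @param noise_sd Gaussian log2 noise sd added to every time-course
#'   observation.
#' @param nb_dispersion Negative-binomial dispersion for counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param mean_depth Expected total counts per sample.
#' @param size_factors Relative library sizes of the four samples
#'   (control x2, mutant x2).
#' @param replicates Arrays per condition x time point (default 1).
#' @param utr3_median_target,utr3_median_other Median 3' UTR lengths (bases)
#'   for direct targets and all other genes; lengths are log-normal with
#'   `utr3_sdlog`.
#' @param utr3_sdlog Log-sd of the 3' UTR length distribution.
#' @param cds_meanlog,cds_sdlog Log-normal parameters for CDS length.
#' @param fe_mean,fe_sd Per-base 3' UTR folding free energy (kcal/mol/base),
#'   Gaussian.
#' @param prev_readthrough,prev_bicistronic,prev_polycistronic,prev_utr3_intron
#'   Bernoulli prevalences of the binary structural flags.
#' @param prev_high_confidence Prevalence of the high-confidence annotation
#'   flag (genes failing it are dropped by the annotation filter).
#' @param stop_density_mean,stop_density_sd Gaussian parameters for the 3' UTR
#'   stop-codon density when sequences are not generated.
#' @param generate_sequences If `TRUE`, random uniform ACGT 3' UTR sequences of
#'   the drawn lengths are generated and stop densities computed from them.
#' @param heatshock_bump Transient (log2 units) added to both conditions of
#'   heat-shock-artifact genes at the 0 h point (half that at 2 h).
#' @param leaky_offset_range Multiplicative rescue/control offset range for
#'   leaky-rescue genes (log-uniform; minimum must exceed 1.5 so the leaky
#'   filter is actually challenged).
#' @param lowexpr_noise_mult Noise-sd multiplier for the low-expression class.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_genes = 5000,
                             p_direct = 0.023,
                             p_indirect_up = 0.036,
                             p_heatshock = 0.02,
                             p_leaky = 0.01,
                             p_lowexpr = 0.02,
                             p_up_given_direct = 0.192,
                             fold_change_range = c(1.8, 330),
                             fold_decay_range = c(1.80, 7.18),
                             noise_sd = 0.15,
                             nb_dispersion = 0.01,
                             mean_depth = 2e6,
                             size_factors = c(1, 1, 1, 1),
                             replicates = 1L,
                             utr3_median_target = 423,
                             utr3_median_other = 218,
                             utr3_sdlog = 1.0,
                             cds_meanlog = log(1500),
                             cds_sdlog = 0.6,
                             fe_mean = -0.024,
                             fe_sd = 0.008,
                             prev_readthrough = 0.021,
                             prev_bicistronic = 0.0044,
                             prev_polycistronic = 0.0059,
                             prev_utr3_intron = 0.048,
                             prev_high_confidence = 0.95,
                             stop_density_mean = 0.067,
                             stop_density_sd = 0.012,
                             generate_sequences = FALSE,
                             heatshock_bump = 1.5,
                             leaky_offset_range = c(1.6, 2.5),
                             lowexpr_noise_mult = 6) {
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  p <- c(cfg$p_direct, cfg$p_indirect_up, cfg$p_heatshock, cfg$p_leaky,
         cfg$p_lowexpr)
  if (any(p < 0 | p > 1) || sum(p) > 1) {
    stop("class proportions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  if (cfg$n_genes < 1) stop("n_genes must be positive", call. = FALSE)
  for (rg in list(cfg$fold_change_range, cfg$fold_decay_range,
                  cfg$leaky_offset_range)) {
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[1] > rg[2] || rg[1] <= 0) {
      stop("ranges must be finite, positive and non-degenerate", call. = FALSE)
    }
  }
  if (any(cfg$size_factors <= 0)) stop("library sizes must be positive",
                                       call. = FALSE)
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  invisible(cfg)
}

.class_levels <- c("direct_target", "indirect_up", "unaffected",
                   "heatshock_artifact", "leaky_rescue", "low_expression")

#' Generate the per-gene ground truth
#'
#' Assigns every gene a class, a steady-state fold change, a decay rate
#' (per-ordinal-unit log2 slope, 0 for non-decaying classes) and an
#' up-regulation flag. Deterministic given `cfg` and `seed`; the other
#' generators call this internally so that counts, time course and
#' annotations share one truth.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `gene_id`, `class`, `fold_change`,
#'   `decay_rate`, `is_up_regulated`.
#' @export
generate_truth <- function(cfg, seed) {
  validate_generator_config(cfg)
  set.seed(seed)
  n <- cfg$n_genes
  probs <- c(cfg$p_direct, cfg$p_indirect_up,
             1 - cfg$p_direct - cfg$p_indirect_up - cfg$p_heatshock -
               cfg$p_leaky - cfg$p_lowexpr,
             cfg$p_heatshock, cfg$p_leaky, cfg$p_lowexpr)
  cls <- sample(.class_levels, n, replace = TRUE, prob = probs)
  is_up <- (cls == "indirect_up") |
    (cls == "direct_target" & stats::runif(n) < cfg$p_up_given_direct)
  fcr <- log(cfg$fold_change_range)
  fc <- ifelse(is_up, exp(stats::runif(n, fcr[1], fcr[2])), 1)
  fdr <- cfg$fold_decay_range
  fd <- stats::runif(n, fdr[1], fdr[2])
  # log2 expression is linear in ordinal time, so the pre -> 4 h drop spans
  # the 3 ordinal steps between time points 1 and 4
  decay <- ifelse(cls == "direct_target", -log2(fd) / 3, 0)
  data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    class = cls,
    fold_change = fc,
    decay_rate = decay,
    is_up_regulated = is_up,
    stringsAsFactors = FALSE
  )
}

#' Generate a steady-state RNA-seq count matrix
#'
#' Two control and two mutant samples. Per-gene base means are log-normal and
#' rescaled so each unit-size-factor sample has expected depth
#' `cfg$mean_depth`; mutant means are multiplied by the truth fold change;
#' counts are negative-binomial with dispersion `cfg$nb_dispersion`
#' (Poisson when 0) and per-sample library-size factors.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @param truth Optional truth table from [generate_truth()]; generated from
#'   the same seed when omitted.
#' @return A list with elements `counts` (data.frame: gene_id, ctrl_1, ctrl_2,
#'   mut_1, mut_2), `truth`, and `sample_info`.
#' @export
generate_counts <- function(cfg, seed, truth = NULL) {
  validate_generator_config(cfg)
  if (is.null(truth)) truth <- generate_truth(cfg, seed)
  set.seed(seed + 1L)
  n <- nrow(truth)
  base <- stats::rlnorm(n, meanlog = log(100), sdlog = 1.5)
  base <- base * cfg$mean_depth / sum(base)
  sf <- cfg$size_factors
  cond <- c("control", "control", "mutant", "mutant")
  mu <- outer(base, sf) # genes x samples
  mu[, cond == "mutant"] <- mu[, cond == "mutant"] * truth$fold_change
  draw <- function(m) {
    if (cfg$nb_dispersion == 0) stats::rpois(length(m), m)
    else stats::rnbinom(length(m), mu = m, size = 1 / cfg$nb_dispersion)
  }
  cnt <- matrix(draw(mu), nrow = n)
  counts <- data.frame(gene_id = truth$gene_id,
                       ctrl_1 = cnt[, 1], ctrl_2 = cnt[, 2],
                       mut_1 = cnt[, 3], mut_2 = cnt[, 4],
                       stringsAsFactors = FALSE)
  sample_info <- data.frame(
    sample = c("ctrl_1", "ctrl_2", "mut_1", "mut_2"),
    condition = cond, replicate = c(1L, 2L, 1L, 2L),
    stringsAsFactors = FALSE
  )
  list(counts = counts, truth = truth, sample_info = sample_info)
}

#' Generate a rescue-reactivation time course
#'
#' Per gene and condition (`experimental` carries the rescue cDNA, `control`
#' does not) an expression series over the four ordinal time points 1–4
#' (pre-heat-shock, 0 h, 2 h, 4 h). Direct targets decay exponentially in the
#' experimental condition only — log2 expression linear in ordinal time with
#' the truth decay slope, the pre point staying at baseline;
#' heat-shock-artifact genes receive an identical transient in both
#' conditions; leaky-rescue genes carry a constant multiplicative offset
#' between conditions; the low-expression class gets inflated noise. Gaussian
#' log2 noise of sd `cfg$noise_sd` is added to every observation.
#'
#' @inheritParams generate_counts
#' @return A list with elements `timecourse` (long data.frame: gene_id,
#'   condition, timepoint, replicate, expression) and `truth`.
#' @export
generate_timecourse <- function(cfg, seed, truth = NULL) {
  validate_generator_config(cfg)
  if (is.null(truth)) truth <- generate_truth(cfg, seed)
  set.seed(seed + 2L)
  n <- nrow(truth)
  r <- as.integer(cfg$replicates)
  base_l2 <- log2(stats::rlnorm(n, meanlog = log(1000), sdlog = 1)) +
    log2(truth$fold_change) # background is the mutant steady state
  bump <- c(0, cfg$heatshock_bump, cfg$heatshock_bump / 2, 0)
  lor <- log(cfg$leaky_offset_range)
  leaky_l2 <- ifelse(truth$class == "leaky_rescue",
                     log2(exp(stats::runif(n, lor[1], lor[2]))), 0)
  noise_sd <- cfg$noise_sd *
    ifelse(truth$class == "low_expression", cfg$lowexpr_noise_mult, 1)

  grid <- expand.grid(gene = seq_len(n), condition = c("experimental", "control"),
                      timepoint = 1:4, replicate = seq_len(r),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- grid$gene; t <- grid$timepoint
  l2 <- base_l2[g]
  hs <- truth$class[g] == "heatshock_artifact"
  l2[hs] <- l2[hs] + bump[t[hs]]
  isexp <- grid$condition == "experimental"
  # experimental condition only: log2 expression linear in ordinal time with
  # the truth decay slope; the pre point (t = 1) stays at baseline
  l2[isexp] <- l2[isexp] +
    truth$decay_rate[g[isexp]] * (t[isexp] - 1) +
    leaky_l2[g[isexp]]
  l2 <- l2 + stats::rnorm(nrow(grid), sd = noise_sd[g])
  tc <- data.frame(gene_id = truth$gene_id[g],
                   condition = grid$condition,
                   timepoint = as.integer(t),
                   replicate = as.integer(grid$replicate),
                   expression = 2^l2,
                   stringsAsFactors = FALSE)
  ord <- order(match(tc$gene_id, truth$gene_id), tc$condition,
               tc$timepoint, tc$replicate)
  tc <- tc[ord, , drop = FALSE]
  rownames(tc) <- NULL
  list(timecourse = tc, truth = truth)
}

.random_dna <- function(len) {
  vapply(len, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
}

#' Generate per-gene structural annotations
#'
#' 3' UTR lengths are log-normal with class-specific medians (direct targets
#' vs all other genes); CDS lengths are independent log-normal; binary flags
#' are Bernoulli at configured prevalences; per-base folding free energies are
#' Gaussian. When `cfg$generate_sequences` is `TRUE`, random uniform ACGT
#' 3' UTR sequences of the drawn lengths are attached (attribute
#' `"utr3_sequences"`) and stop-codon densities are computed from them with
#' [stop_codon_density()].
#'
#' @inheritParams generate_counts
#' @return A `data.frame` in the `annotation` schema (see [read_table()]);
#'   truth attached as attribute `"truth"`.
#' @export
generate_annotations <- function(cfg, seed, truth = NULL) {
  validate_generator_config(cfg)
  if (is.null(truth)) truth <- generate_truth(cfg, seed)
  set.seed(seed + 3L)
  n <- nrow(truth)
  is_target <- truth$class == "direct_target"
  med <- ifelse(is_target, cfg$utr3_median_target, cfg$utr3_median_other)
  utr3 <- round(stats::rlnorm(n, meanlog = log(med), sdlog = cfg$utr3_sdlog))
  utr3 <- pmax(utr3, 3)
  cds <- round(stats::rlnorm(n, meanlog = cfg$cds_meanlog,
                             sdlog = cfg$cds_sdlog))
  cds <- pmax(cds, 3)
  fe <- stats::rnorm(n, cfg$fe_mean, cfg$fe_sd)
  ann <- data.frame(
    gene_id = truth$gene_id,
    high_confidence = stats::runif(n) < cfg$prev_high_confidence,
    utr3_length = utr3,
    cds_length = cds,
    utr3_free_energy = fe,
    cds_utr3_ratio = cds / utr3,
    readthrough_candidate = stats::runif(n) < cfg$prev_readthrough,
    bicistronic = stats::runif(n) < cfg$prev_bicistronic,
    polycistronic = stats::runif(n) < cfg$prev_polycistronic,
    utr3_intron = stats::runif(n) < cfg$prev_utr3_intron,
    stringsAsFactors = FALSE
  )
  if (isTRUE(cfg$generate_sequences)) {
    seqs <- .random_dna(utr3)
    ann$utr3_stop_density <- vapply(seqs, stop_codon_density, 0,
                                    USE.NAMES = FALSE)
    attr(ann, "utr3_sequences") <- stats::setNames(seqs, truth$gene_id)
  } else {
    dens <- stats::rnorm(n, cfg$stop_density_mean, cfg$stop_density_sd)
    ann$utr3_stop_density <- pmin(pmax(dens, 0), 1)
  }
  attr(ann, "truth") <- truth
  ann
}

#' Generate a complete synthetic data set
#'
#' Convenience wrapper producing counts, time course and annotations from one
#' shared truth table, guaranteeing every gene appears exactly once in each.
#'
#' @inheritParams generate_counts
#' @return A list with `truth`, `counts`, `sample_info`, `timecourse`,
#'   `annotation`.
#' @export
generate_dataset <- function(cfg, seed) {
  truth <- generate_truth(cfg, seed)
  cn <- generate_counts(cfg, seed, truth)
  tc <- generate_timecourse(cfg, seed, truth)
  ann <- generate_annotations(cfg, seed, truth)
  list(truth = truth, counts = cn$counts, sample_info = cn$sample_info,
       timecourse = tc$timecourse, annotation = ann)
}

#' Write the 3' UTR sequences attached to an annotation table as FASTA
#'
#' @param annotation Annotation table from [generate_annotations()] with the
#'   `utr3_sequences` attribute.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(annotation, path) {
  seqs <- attr(annotation, "utr3_sequences")
  if (is.null(seqs)) stop("annotation carries no utr3_sequences attribute",
                          call. = FALSE)
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}
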