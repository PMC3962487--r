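quiet_classes <- function(...) {
  generator_config(p_direct = 0, p_indirect_up = 0, p_heatshock = 0,
                   p_leaky = 0, p_lowexpr = 0, ...)
}

test_that("generator config validates proportions and ranges", {
  expect_error(generator_config(p_direct = 0.7, p_indirect_up = 0.5),
               "sum to at most 1")
  expect_error(generator_config(fold_decay_range = c(3, 2)), "non-degenerate")
  expect_error(generator_config(size_factors = c(1, -1, 1, 1)), "positive")
  expect_error(generator_config(nb_dispersion = -0.1), ">= 0")
})

test_that("truth respects its class invariants", {
  cfg <- generator_config(n_genes = 3000)
  tr <- generate_truth(cfg, 4)
  expect_equal(nrow(tr), 3000)
  expect_false(anyDuplicated(tr$gene_id) > 0)
  direct <- tr$class == "direct_target"
  expect_true(all(tr$decay_rate[direct] < 0))
  # implied 4 h fold decay within the configured range
  fd <- 2^(-3 * tr$decay_rate[direct])
  expect_true(all(fd >= cfg$fold_decay_range[1] - 1e-9))
  expect_true(all(fd <= cfg$fold_decay_range[2] + 1e-9))
  unaff <- tr$class == "unaffected"
  expect_true(all(tr$fold_change[unaff] == 1))
  expect_true(all(tr$decay_rate[unaff] == 0))
  expect_true(all(tr$fold_change[tr$is_up_regulated] >= 1.8))
})

test_that("class proportions come out binomially at n = 5000", {
  cfg <- generator_config(n_genes = 5000, p_direct = 0.023)
  tr <- generate_truth(cfg, 8)
  n_direct <- sum(tr$class == "direct_target")
  sdev <- sqrt(5000 * 0.023 * 0.977)
  expect_gt(n_direct, 115 - 4 * sdev)
  expect_lt(n_direct, 115 + 4 * sdev)
})

test_that("counts reproduce the configured fold change at high depth", {
  # law of large numbers: dispersion ~ 0, deep library, single up gene at 4x
  cfg <- generator_config(n_genes = 200, p_indirect_up = 0.5, p_direct = 0,
                          p_heatshock = 0, p_leaky = 0, p_lowexpr = 0,
                          fold_change_range = c(4, 4),
                          nb_dispersion = 0, mean_depth = 1e7)
  cn <- generate_counts(cfg, 2)
  m <- as.matrix(cn$counts[, -1])
  ratio <- rowMeans(m[, 3:4]) / rowMeans(m[, 1:2])
  up <- cn$truth$is_up_regulated
  deep <- rowMeans(m[, 1:2]) > 2000 # only well-measured genes
  expect_true(all(abs(ratio[up & deep] / 4 - 1) < 0.05))
  expect_true(all(abs(ratio[!up & deep] - 1) < 0.05))
})

test_that("generators are seed-deterministic and share one gene universe", {
  cfg <- generator_config(n_genes = 100)
  d1 <- generate_dataset(cfg, 21)
  d2 <- generate_dataset(cfg, 21)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$timecourse, d2$timecourse)
  expect_identical(d1$annotation, d2$annotation, ignore_attr = TRUE)
  ids <- d1$truth$gene_id
  expect_setequal(unique(d1$timecourse$gene_id), ids)
  expect_setequal(d1$counts$gene_id, ids)
  expect_setequal(d1$annotation$gene_id, ids)
  expect_equal(nrow(d1$timecourse), 100 * 2 * 4 * cfg$replicates)
})

test_that("all-unaffected config yields no fold changes and no decay", {
  cfg <- quiet_classes(n_genes = 50)
  tr <- generate_truth(cfg, 9)
  expect_true(all(tr$fold_change == 1))
  expect_true(all(tr$decay_rate == 0))
})

test_that("noise-free time-course construction is exact", {
  cfg <- generator_config(n_genes = 400, p_direct = 0.3, p_heatshock = 0.2,
                          p_indirect_up = 0, p_leaky = 0, p_lowexpr = 0,
                          noise_sd = 0)
  ds <- generate_timecourse(cfg, 13)
  tc <- ds$timecourse
  wide <- function(g, cond) {
    x <- tc[tc$gene_id == g & tc$condition == cond, ]
    x$expression[order(x$timepoint)]
  }
  direct <- ds$truth[ds$truth$class == "direct_target", ][1, ]
  rel <- relative_log_expression(wide(direct$gene_id, "experimental"))
  expect_equal(rel, direct$decay_rate * (0:3), tolerance = 1e-12)
  expect_equal(relative_log_expression(wide(direct$gene_id, "control")),
               rep(0, 4), tolerance = 1e-12)
  # heat-shock transient cancels between conditions
  hs <- ds$truth$gene_id[ds$truth$class == "heatshock_artifact"][1]
  diff <- log2(wide(hs, "experimental")) - log2(wide(hs, "control"))
  expect_equal(diff, rep(0, 4), tolerance = 1e-12)
  # but is visible within each condition
  expect_gt(max(abs(relative_log_expression(wide(hs, "control")))), 0.5)
})

test_that("leaky-rescue genes differ >50% between conditions pre heat shock", {
  cfg <- generator_config(n_genes = 300, p_leaky = 0.5, p_direct = 0,
                          p_indirect_up = 0, p_heatshock = 0, p_lowexpr = 0,
                          noise_sd = 0)
  ds <- generate_timecourse(cfg, 14)
  tc <- ds$timecourse
  pre <- tc[tc$timepoint == 1, ]
  for (g in head(ds$truth$gene_id[ds$truth$class == "leaky_rescue"], 20)) {
    e <- pre$expression[pre$gene_id == g & pre$condition == "experimental"]
    c0 <- pre$expression[pre$gene_id == g & pre$condition == "control"]
    expect_gt(max(e / c0, c0 / e), 1.5)
  }
})

test_that("annotation medians track the configured class medians", {
  cfg <- generator_config(n_genes = 5000, p_direct = 0.3)
  ann <- generate_annotations(cfg, 15)
  tr <- attr(ann, "truth")
  tgt <- tr$class == "direct_target"
  expect_lt(abs(median(ann$utr3_length[tgt]) / 423 - 1), 0.10)
  expect_lt(abs(median(ann$utr3_length[!tgt]) / 218 - 1), 0.10)
  expect_equal(ann$cds_utr3_ratio, ann$cds_length / ann$utr3_length)
})

test_that("equal class medians give a null 3' UTR length coefficient", {
  cfg <- generator_config(n_genes = 4000, p_direct = 0.3,
                          utr3_median_target = 300, utr3_median_other = 300)
  ann <- generate_annotations(cfg, 16)
  tr <- attr(ann, "truth")
  fit <- logistic_fit(ann$utr3_length, tr$class == "direct_target")
  # coefficient indistinguishable from 0 at the Wald level
  expect_gt(fit$p_value, 0.01)
})

test_that("generated sequences drive the stop-codon density column", {
  cfg <- generator_config(n_genes = 40, generate_sequences = TRUE)
  ann <- generate_annotations(cfg, 17)
  seqs <- attr(ann, "utr3_sequences")
  expect_length(seqs, 40)
  expect_equal(nchar(seqs[[5]]), ann$utr3_length[5])
  expect_equal(ann$utr3_stop_density[5], stop_codon_density(seqs[[5]]))
  # FASTA export round-trips the sequences
  tf <- withr::local_tempfile(fileext = ".fa")
  write_utr_fasta(ann, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], paste0(">", ann$gene_id[1]))
  expect_equal(lines[2], unname(seqs[1]))
})
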