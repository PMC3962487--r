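# nmdreact

Distinguishing **direct** from **indirect** targets of nonsense-mediated mRNA
decay (NMD) in vivo.

Knocking out the NMD pathway changes the expression of hundreds of genes, but
most of those changes are downstream ripples, not decay substrates. The
decisive experiment is a *reactivation assay*: in an NMD-deficient animal
(a *Upf2* hypomorph), a rescue cDNA is switched on acutely and transcript
levels are tracked at four time points (pre-heat-shock, 0 h, 2 h, 4 h). A
direct target is re-exposed to the decay machinery and falls roughly
exponentially; an indirect target lags. `nmdreact` is a tested, reusable
implementation of that analysis for transcriptomicists who want to run it on
their own tables or to study its operating characteristics on simulated data.

## What it computes

For each gene with paired rescue (`experimental`) and no-rescue (`control`)
series over ordinal times $t = 1\ldots4$:

- log2 expression relative to the pre point, $y_t = \log_2(x_t/x_1)$,
  replicates averaged on the log2 scale;
- per-condition least-squares decay slopes and the **relative slope**
  $\hat\beta_{\mathrm{exp}} - \hat\beta_{\mathrm{ctrl}}$ (log2 per ordinal
  unit);
- an exhaustive 24-permutation test of the Pearson correlation between the
  experimental-minus-control series and ordinal time (p-values on the
  $k/24$ lattice);
- the 4 h fold decay $x_{\text{pre}}/x_{4h}$ in the rescue arm;
- filter flags (control drift > 20%, pre-point condition difference > 50%,
  low-confidence annotation).

A gene is called a direct-target candidate iff it passes all filters, fold
decay ≥ 1.8, relative slope < 0, and permutation p < 0.1. Around this core
the package provides a simplified negative-binomial exact test for the
mutant-vs-control steady-state contrast (median-of-ratios size factors,
method-of-moments dispersion), four-way classification with a two-sided
Fisher exact enrichment test, univariate logistic regressions of target
status on transcript structural features (3′ UTR length and friends), small
read-fraction / 2^−ΔΔCt helpers, and a seeded synthetic-data generator with
per-gene ground truth.

## A worked example

```r
library(nmdreact)
cfg <- pipeline_config(rng_seed = 7, out_dir = "run7")  # published thresholds
res <- run_pipeline(cfg)   # simulate -> de -> reactivate -> classify -> features
res$enrichment
```

```
  a   b  c    d pct_up_that_are_targets pct_universe_targets     fisher_p
 18 256 70 4429                6.569343             1.843704 1.651168e-06
```

Reading this: of 5000 simulated genes, 4773 passed the detection and
annotation filters to form the analyzed universe. 274 were called
up-regulated in the mutant at raw p < 0.01 (`a + b`), 88 were called
reactivation targets (`a + c`), and 18 were both. 6.6% of up-regulated genes
are targets versus a 1.8% baseline rate — direct targets are enriched among
up-regulated genes (Fisher p ≈ 1.7 × 10⁻⁶), yet most up-regulated genes are
*not* direct targets and most direct targets are not up-regulated at steady
state, which is precisely the point of the assay. Per-stage TSVs
(`de_results.tsv`, `reactivation_results.tsv`, `classes.tsv`,
`feature_table.tsv`, `summary.txt`, …) land in `run7/`.

The same pipeline runs from the shell:

```sh
inst/cli/nmdreact all --seed 7 --fold-decay-min 1.8 --perm-alpha 0.1 --out-dir run7
inst/cli/nmdreact simulate --seed 3 --n-genes 500 --out-dir sim3   # tables only
```

Real data come in through the same TSV schemas (`read_table(path, "counts")`,
`"timecourse"`, `"annotation"`) with `counts_path=`/`timecourse_path=`/
`annotation_path=` set in the config.

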