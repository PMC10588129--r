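# deconvbench

Benchmarking framework for bulk-tumor cell-type deconvolution under
experimental-protocol variation.

Bulk RNA-seq deconvolution estimates the fraction of transcripts each
cell type contributes to a tissue sample, using a single-cell reference.
Both inputs depend on upstream experimental choices: dissociating the
tissue destroys fragile cell types (erythrocytes, adipocytes) and
induces stress genes; poly-A capture loses non-polyadenylated canonical
histone transcripts while rRNA depletion co-depletes mitochondrial RNA;
and the reference profile changes with demultiplexing stringency and
sequencing scale. `deconvbench` simulates a virtual high-grade serous
ovarian carcinoma (HGSOC) cohort in which all of these effects are
explicit, calibrated parameters, and scores deconvolution methods
jointly on

* **accuracy** — RMSE and signed differences between estimated and true
  RNA fractions on pseudo-bulk data with exact ground truth, and
* **robustness** — variance of a method's estimates for the same tumor
  across bulk protocols and across reference profiles.

## The core model

A bulk sample is treated as a linear mixture: for gene expression
profile `b` and cell-type signature matrix `S` (genes x types, mean CPM
per type), the built-in baseline solves

    min_x || S x - b ||_2   subject to  x >= 0

with a Lawson–Hanson active-set NNLS solver, then renormalizes `x` to a
composition. Estimates are RNA fractions (transcript shares), matching
the pseudo-bulk ground truth, which is defined as the fraction of reads
contributed by each cell type's sampled cells — never the cell-count
share. Other deconvolution methods plug in through a method registry
(`register_method()`); the framework supplies the benchmark around them.

The synthetic cohort generator draws annotated single cells from a
gamma–Poisson model (per-type archetypes, per-tumor patient effects,
mRNA-content scales) and matched three-protocol bulk samples
(rRNA-depleted chunk, rRNA-depleted dissociated, poly-A dissociated)
whose enrichment biases are calibrated so the expected depth-normalized
histone fold change (rRNA-depleted vs poly-A) lands in the observed
1.7–10x window and the mitochondrial fold change (poly-A vs
rRNA-depleted) in 10–30x. Paired hash/genetic demultiplexing posterior
tables complete the inputs for reference-perturbation experiments.

## Worked example

The full analysis lives in `analysis/` (numbered scripts, each writing
its tables under `results/`). A condensed run:

```r
library(deconvbench)

ref <- generate_reference(cohort_config(), seed = 20260315)
sig <- build_signature(ref)

# pseudo-bulk accuracy, weighted scenario (epithelial fixed at 70%)
pbs <- build_scenario_dataset(ref, scenario_config("weighted"),
                              seed = 20260315)
est <- results_table(lapply(names(pbs), function(nm) {
  r <- deconvolve(sig, pbs[[nm]]); r$sample_id <- nm; r
}))
rmse(est, truth_table(pbs))
```

On the default cohort the analysis scripts print, for NNLS:

```
average RMSE by scenario (NNLS):
 method  scenario        rmse
   nnls      even 0.011277015
   nnls realistic 0.011624478
   nnls    sparse 0.009672231
   nnls  weighted 0.012065092
```

so the baseline recovers pseudo-bulk compositions to about one
percentage point of RMSE across all four scenarios. The robustness step
(`analysis/04_robustness.R`) reports the variance of estimates across
the three bulk protocols (mean 0.0031 for NNLS with the full reference)
and across six reference profiles (mean 0.0022), and a sequential ANOVA
on the epithelial estimates:

```
           term  df      sum_sq      mean_sq    statistic      p_value
     enrichment   1 2.143952803 2.1439528026 174.66544667 3.645213e-26
 reference_size   5 0.003479403 0.0006958805   0.05669261 9.978932e-01
    dissociated   1 0.002731250 0.0027312498   0.22251188 6.378885e-01
```

i.e. the mRNA enrichment chemistry dominates the variation in epithelial
estimates, while reference-profile size and dissociation status are
negligible — the qualitative pattern this kind of benchmark is designed
to expose.

`analysis/01_simulate_cohort.R` also prints the realized protocol fold
changes (histone 2.45–9.64x, mitochondrial 10.1–23.6x, hemoglobin
depleted 2–14x on dissociation for the study seed), and
`analysis/02_demultiplex.R` the assignment-rate tables at thresholds
0.90/0.85/0.80 plus hash-vs-genetic concordance.

## Layout

| Path | Contents |
| --- | --- |
| `R/` | cohort/bulk/demux generators, pseudo-bulk engine, reference profiles, NNLS + registry, evaluation, I/O, pipeline |
| `analysis/` | numbered workflow drivers (simulate, demultiplex, accuracy, robustness) |
| `tests/testthat/` | unit, property and acceptance tests |
| `vignettes/benchmark-design.Rmd` | the methods vignette: model, parameters, design choices, limitations |
| `scripts/acceptance.R` | standalone recomputation of the calibration quantities |
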