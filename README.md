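# synaptoff

Decomposing excitotoxic shut-off of synaptic activity-induced gene
expression from bulk RNA-seq.

## The problem

Synaptic activity drives protective gene programs in neurons: blocking
GABA-A receptors with bicuculline (Bic) triggers synchronized
action-potential (AP) firing and induces waves of activity-responsive
genes. Excitotoxic signaling through extrasynaptic NMDA receptors
(esNMDARs) disrupts this induction. The disruption has two separable
components:

* a **passive** component — induction decays simply because AP firing
  stops (modeled by silencing with TTX), and
* an **active** component — toxic esNMDAR signaling suppresses induction
  beyond firing cessation (modeled by bath NMDA on top of TTX). Glutamate
  spillover forced by the transporter blocker TBOA provides a milder,
  more disease-like excitotoxic signal.

The experimental design crosses a Bic induction time series (0.5, 1, 2 h)
with interventions placed inside the induction window: a short protocol
(SP; intervention during the second half-hour, sampled at 1 h) targeting
rapidly induced genes, and a long protocol (LP; intervention during the
second hour, sampled at 2 h) targeting delayed genes, nine conditions in
all with five replicates each.

`synaptoff` implements the complete analysis as a tested, reusable
pipeline for gene-by-sample count matrices:

* median-of-ratios size factors and per-contrast negative-binomial Wald
  tests (log2 fold change, standard error, p, Benjamini–Hochberg FDR;
  `NA` for genes undetectable in a comparison), with zero-centered
  normal-prior shrinkage of L2FCs;
* per-gene ANOVA screening across the Bic series and rule-based activity
  classes (`early.induced`, `late.induced`, mirrored repressed classes,
  `transient`, `unresponsive`) with SP/LP protocol allocation;
* shut-off decomposition per gene — passive (TTX vs Bic), active
  (TTX/NMDA vs TTX) and TBOA (TBOA vs Bic) calls with percentage metrics
  `100 * (2^L2FC − 1)` and a ranking of the most affected genes;
* the gene-wise effect concordance statistic
  `s = a·b / sqrt(a² + b²)` and pairwise Pearson correlations between
  interference effect vectors;
* exploratory views: PCA of transformed counts, condition-wise L2FC
  heatmap matrix with Euclidean/complete-linkage clustering, and
  seed-fixed exact t-SNE of candidate genes;
* generic hypergeometric gene-set overrepresentation over GMT files
  against the expressed-gene background;
* a truth-labeled synthetic-data generator emulating the nine-condition
  design (archetype kinetics, intervention effect multipliers, NB
  overdispersion, library-size factors), so every stage is testable
  without downloads.

## Worked example

Simulate a 2,000-gene experiment and run the full pipeline:

```r
library(synaptoff)

cfg <- sim_config(n_genes = 2000, seed = 1)
sim <- simulate_experiment(cfg)
res <- run_pipeline(sim$counts, sim$design)
glance(res)
#> # A tibble: 1 × 9
#>   n_genes n_candidates n_evaluable n_passive_only n_active_only n_both n_boosted
#>     <int>        <int>       <int>          <int>         <int>  <int>     <int>
#> 1    2000          796         483             81           199     60         3
```

Of 2,000 simulated genes, 796 pass candidate selection (Bic-responsive,
classified to an activity class, statistics in every comparison); among
the 483 evaluable activity-induced genes, 199 are shut off only by the
active esNMDAR signal, 81 only passively, 60 by both. The ranking mirrors
a "most affected genes" table, most negative total shut-off first:

```r
res$ranking
#> # A tibble: 20 × 9
#>   gene_id induction_class shutoff_pct passive passive_pct active active_pct
#> 1 g01404  late                  -79.2 down          -43.2 down        -60.1
#> 2 g01832  early                 -78.8 down          -36.2 down        -64.9
#> 3 g00579  early                 -78.4 down          -50.8 down        -51.1
#> ...
```

`shutoff_pct = -79.2` means the TTX/NMDA intervention reduced that gene's
induced expression by 79% relative to uninterrupted firing. Effect-vector
correlations over late-induced candidates summarize how the interference
modes relate (the passive and active effects anticorrelate; spillover
tracks the active effect):

```r
round(res$correlations, 2)
#>             passive spillover total active active_tboa
#> passive        1.00      0.20  0.52  -0.30       -0.78
#> spillover      0.20      1.00  0.82   0.73        0.46
#> total          0.52      0.82  1.00   0.66        0.06
#> active        -0.30      0.73  0.66   1.00        0.74
```

Because the data are simulated, recovery can be scored against the truth
labels:

```r
truth_eval(res$annotation, sim$truth)
#> # A tibble: 9 × 7
#>   section        category  n_true n_called sensitivity specificity     fdr
#> 7 shutoff        passive      147      141       0.952       0.997 0.00709
#> 8 shutoff        active       261      259       0.989       0.995 0.00386
```

For real data, `read_counts()` / `read_design()` ingest TSV inputs and
`write_pipeline_outputs()` emits every table (merged annotated gene
table, per-contrast results, ranking, embeddings, overlap summary) as
TSV/YAML. A thin command-line wrapper lives at
`inst/scripts/synaptoff-cli.R` (subcommands `simulate` and `run`).

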