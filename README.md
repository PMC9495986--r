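# teaflow

Differential expression analysis (DEA) for one-color microarray data and
RNA-seq counts, packaged as a self-contained, deterministic pipeline with a
small command-line interface.

Bulk transcriptomics experiments ask a deceptively simple question: which
genes change expression between two groups of samples (tumor vs normal,
treated vs control)? Answering it well takes a chain of low-level steps —
background correction, between-array normalization, probe summarization,
conservative filtering — followed by statistics that behave sensibly at the
small sample sizes typical of array studies. `teaflow` implements that
chain end to end, records every analysis choice in a single shareable
options file, and guarantees that the same inputs plus the same options
file reproduce byte-identical result tables. It is aimed both at analysts
re-mining the large public archives of microarray data and at anyone who
wants a transparent, scriptable DEA without assembling a pipeline by hand.

## The statistics at the core

**Preparation** (raw intensities → expression matrix):

* *normexp background correction.* Each observed intensity is modeled as
  X = S + B with signal S ~ Exp(α) and background B ~ N(μ, σ²); the
  corrected value is the posterior mean E[S | X = x] =
  m + σ·φ(m/σ)/Φ(m/σ), m = x − μ − σ²/α. Parameters come from negative
  controls when present, otherwise from a maximum-likelihood fit of the
  convolution density.
* *Quantile normalization* forces identical empirical distributions across
  samples (rank-wise averaging; tied values share their rank span's mean).
* *Median-polish summarization* (probe-set platforms) or *replicate
  averaging* (single-probe platforms) collapses probes to one value per
  gene; control probes are removed, and the 95th percentile of the
  negative-control log2 intensities is reported as an "unexpressed"
  threshold θ_E for filtering.

**Filtering.** An entry is kept iff its expression exceeds θ_E in at least
a fraction κ of the samples of at least one group (defaults κ = 0.8, θ_E =
the control-derived estimate or the 20th percentile). The fold-change
threshold θ_F (default 0.5) never removes rows; it only affects marking.

**Moderated t (parametric arm).** Per-gene linear models (group means, plus
indicator columns for batches, pairings and extra covariates) with
empirical-Bayes variance moderation: s̃²_g = (d₀s₀² + d·s²_g)/(d₀ + d),
where (d₀, s₀²) are estimated from all genes by moment matching on
log s²_g. The moderated t̃_g = c'β̂_g / √(s̃²_g·v_g) is referred to a
t distribution with d₀ + d degrees of freedom; Benjamini–Hochberg q-values
control the FDR.

**Rank product (non-parametric arm).** RP_g is the geometric mean of the
gene's fold-change ranks over all between-group sample pairings (within
batch strata, or within pairs for paired designs). Permutation of gene
labels within each comparison column yields p-values and the proportion of
false positives (PFP).

**Marking.** A gene is called up (+1) or down (−1) iff q (or PFP) < α
strictly **and** |log2FC| > θ_F strictly; otherwise 0.

**Counts.** RNA-seq count matrices are transformed to
log2-CPM = log2((count + 0.5)/(libsize + 1)·10⁶) and given precision
weights from a lowess mean–variance trend (predicted √sd to the −4th
power), after which they flow through the moderated-t arm unchanged.

## Worked example

Everything below is generated code — no external data needed.

```r
library(teaflow)

dir.create("demo")
d <- generate_expression_dataset(genes = 1000, n_per_group = 6,
                                 de_fraction = 0.1, log2fc = 1, seed = 19)
write_expression_matrix(d$matrix, "demo/matrix.csv")
opts <- analysis_options(design_spec(d$groups, list(c("treated", "control"))),
                         permutations = 200, rng_seed = 19)
write_options(opts, "demo/options.txt")

tables <- cmd_analyze("demo/matrix.csv", "demo/options.txt", "demo/results")
lt <- tables[["treated_vs_control.limma_like"]]
head(lt[order(lt$q_value), ], 5)
```

```
             entry_id avg_expr log2_fc  stat  p_value  q_value marking
gene_00002 gene_00002     6.95   -1.08 -12.0 8.02e-09 1.90e-06      -1
gene_00043 gene_00043    10.42   -1.24 -11.8 9.53e-09 1.90e-06      -1
gene_00066 gene_00066     6.62   -1.17 -12.0 8.25e-09 1.90e-06      -1
gene_00470 gene_00470     6.17    1.18  13.0 2.80e-09 1.90e-06       1
gene_00063 gene_00063     7.19   -1.03 -10.8 3.01e-08 1.98e-06      -1
```

Each row is one retained entry: its grand-mean log2 expression, the
estimated log2 fold change treated − control, the moderated t statistic,
p, BH q, and the three-state marking. Here the dataset was built with 100
truly shifted genes (|log2FC| = 1); the moderated-t arm marks 39 up + 48
down and the rank-product arm 40 up + 56 down, with the overlap written to
`demo/results/overlap_treated_vs_control.csv`:

```
direction,only_limma_like,shared,only_rankprod
up,0,39,1
down,0,48,8
```

The run log (`demo/results/analyze.log`) records the version, the resolved
seed, the automatically chosen θ_E (here the 20th expression percentile,
5.77), the filter outcome (796 of 1000 entries retained) and the estimated
hyperparameters (d̂₀ = 4.22, ŝ₀² = 0.0506 — the generator drew gene
variances with d₀ = 4, s₀² = 0.05). Re-running `cmd_analyze` with the same
inputs reproduces every CSV byte for byte.

The same analysis runs from a shell:

```sh
teaflow synth --kind expression --output demo/matrix.csv --seed 19 \
    --genes 1000 --n_per_group 6 --de_fraction 0.1
teaflow initialize --output demo/options.txt   # then edit labels/choices
teaflow analyze --matrix demo/matrix.csv --options demo/options.txt --out demo/results
teaflow annotate --table demo/results/deg_treated_vs_control_limma_like.csv \
    --annotations my_annotation.csv --output annotated.csv
```

Raw intensity preparation works the same way: `teaflow prepare --input
<dir> --platform probeset --output matrix.csv` turns one CSV of
`feature_id,intensity,control_class,replicate_key` per sample into a
normalized, summarized, control-free log2 matrix plus QC data files.

## Options file

A flat `key = value` text document (`#` for comments) that fully
determines an analysis — share it together with the matrix to let anyone
replay the run:

| key | meaning | default |
|---|---|---|
| `design.groups` | one level per sample, order-wise; `k*label` shorthand | required |
| `design.contrasts` | comma-separated `test-reference` pairs | required |
| `design.batches` / `design.pairings` | optional per-sample labels | — |
| `filter.kappa` | minimum group-wise presence fraction | 0.8 |
| `filter.theta_e` | log2 expression threshold, or `auto` | `auto` |
| `filter.theta_f` | log2 fold-change threshold for marking | 0.5 |
| `alpha` | q/PFP significance level | 0.05 |
| `methods` | subset of `limma_like,rankprod` | required |
| `input_kind` | `microarray` or `counts` | required |
| `seed` | drives every stochastic stage | required |
| `permutations` | rank-product permutations (≥ 100) | 1000 |
| `renormalize` | quantile-normalize the input first | false |

## Scope

No network access, no GEO retrieval, no binary vendor-format parsing, no
containerization, no annotation auto-download: annotation is a
user-supplied CSV (`entry_id,gene_symbol,gene_name,source_name,
source_version`), and raw inputs use the documented text format above. See
`vignettes/teaflow-methods.Rmd` for the modeling assumptions, tuning
parameters and known limitations.
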