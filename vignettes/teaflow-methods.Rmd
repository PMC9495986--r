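---
title: "teaflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{teaflow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teaflow)
```

This vignette is the package's own account of its science: the models each
stage assumes, the tunable parameters and why their defaults are what they
are, what the synthetic-data generators do and do not emulate, and the
numerical choices made where reasonable implementations could differ.
Every empirical statement here is one the test suite computes itself.

## 1. Preparation: from scanner export to expression matrix

Raw input is one text table per sample
(`feature_id,intensity,control_class,replicate_key`), a documented
stand-in for vendor scanner exports; binary vendor formats are out of
scope. The two platform archetypes are `probeset` (many probes summarized
into one probe-set value, as on high-density chips) and `single_probe`
(replicate probes of the same sequence averaged, as on spotted designs).

### Background correction (normexp)

The observed linear-scale intensity is modeled as $X = S + B$ with signal
$S \sim \mathrm{Exp}(\alpha)$ and background
$B \sim \mathcal{N}(\mu, \sigma^2)$. The corrected value is the posterior
mean

$$E[S \mid X = x] = m + \sigma\,\frac{\phi(m/\sigma)}{\Phi(m/\sigma)},
\qquad m = x - \mu - \sigma^2/\alpha,$$

evaluated through log-scale $\phi$ and $\Phi$ (a numerically stable Mills
ratio), so it is finite, strictly positive and monotone for any $x$ —
including intensities far below the background mean, where a naive
implementation underflows. The test suite checks the closed form against
direct numerical integration of the posterior to $10^{-6}$ relative error.

Parameter estimation has two routes:

* **Negative controls present** (at least two): $\mu$ and $\sigma$ are
  their mean and standard deviation; $\alpha$ is the mean foreground
  excess over $\mu$. Controls are sequences designed not to hybridize, so
  they observe $B$ directly.
* **No controls**: full maximum likelihood on the convolution density,
  initialized from robust moments (5th percentile for $\mu$; s.d. of the
  sub-10th-percentile values for $\sigma$; mean excess over the 5th
  percentile for $\alpha$), Nelder–Mead on $(\mu, \log\sigma,
  \log\alpha)$. Non-convergence is a hard error carrying the optimizer
  state.

$\sigma$ is floored at $10^{-6}$ of the mean intensity in both routes:
constant controls would otherwise give a degenerate $\sigma = 0$ whose
correction is a hard shift with no shrinkage.

### Normalization and summarization

Quantile normalization equalizes the empirical distributions by rank-wise
averaging. Ties within a column receive the mean of the reference values
over their tied rank span — with that rule the operation is exactly
idempotent, which the tests assert. Correction happens on the linear
scale, normalization on log2 values (the conventional order; the
alternative — correcting log-scale values — has no generative
interpretation under the additive model above).

Probe-set summarization is two-way median polish (row sweep first, then
column sweep, at most 10 iterations or until the largest absolute sweep
change drops below $10^{-4}$); the per-sample summary is the overall
effect plus the column effect. Row-first order and the tolerance are
conventional choices; summaries are location- and sample-permutation
equivariant, which the tests verify.

Control probes are removed after normalization, and the 95th percentile
(linear-interpolation definition) of the negative-control log2
intensities is reported as an estimate of the intensity an unexpressed
gene can reach through background and non-specific hybridization. The
percentile is a deliberate, logged choice — "a sensible threshold" is not
a formula — and the resulting value can always be overridden through
`filter.theta_e`.

## 2. Filtering

Three parameters, all on the log2 scale where applicable:

| parameter | meaning | default |
|---|---|---|
| $\kappa \in [0,1]$ | minimum group-wise presence fraction | 0.8 |
| $\theta_E$ | expression threshold (strict $>$) | control estimate, else 20th percentile |
| $\theta_F \ge 0$ | fold-change threshold for marking | 0.5 |

An entry survives iff some group has expression $> \theta_E$ in at least
$\kappa$ of its samples; the count comparison is exact
(`count >= kappa * n`), with no floating rounding of fractions. $\kappa =
0.8$ keeps a gene expressed consistently in one condition even if absent
in the other — the interesting case for differential expression — while
discarding genes that only ever fluctuate around background, which would
otherwise dilute the multiple-testing correction. $\theta_F$ is *not* a
row filter: genes with small fold changes stay in every computation
(including hyperparameter estimation) and are merely marked 0, because
sub-threshold fold changes are hard to validate downstream, not invalid.

## 3. The moderated t arm

Per-gene linear models use a group-means parameterization (one indicator
per level, no intercept) so a contrast is a plain $\pm 1$ vector; batch,
pairing and extra covariates enter as reference-dropped indicator blocks
(levels sorted lexicographically, first level is the reference). Rank
deficiency — e.g. a batch coinciding with a group — is a hard error
naming the collinear columns rather than a silent drop.

Batches are handled **inside the model**, not by pre-correcting the
matrix: subtracting batch effects before testing distorts the residual
degrees of freedom and can fabricate significance. The test suite shows
the concrete failure mode the covariate repairs: with a true additive
batch shift, the plain two-sample $t$-test loses calibration (far too few
rejections, because the shift inflates within-group variance), and adding
the batch column restores the nominal level.

Variance moderation follows the scaled inverse-$\chi^2$ hierarchy: gene
variances $s^2_g$ with $d$ residual degrees of freedom shrink toward a
prior $(d_0, s_0^2)$,

$$\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},\qquad
\tilde t_g = \frac{c^\top\hat\beta_g}{\sqrt{\tilde s^2_g v_g}}
\sim t_{d_0 + d} \text{ under } H_0 .$$

$(d_0, s_0^2)$ are estimated by moment matching on $e_g = \log s^2_g -
\psi(d/2) + \log(d/2)$: solve $\psi'(d_0/2) = \max(\mathrm{var}(e) -
\overline{\psi'(d/2)},\, 0)$ by bisection on $d_0 \in [10^{-6}, 10^8]$
(values beyond are treated as $\infty$, i.e. full shrinkage and a normal
reference). Genes with $s^2_g = 0$ are excluded from estimation (log of
zero) but still tested through the moderated variance. Two limits anchor
the implementation: $d_0 = 0$ reproduces the classical $t$-test to
$10^{-10}$, and $d_0 = \infty$ pins every gene's variance at $s_0^2$.
The arm as a whole reproduces the reference empirical-Bayes
implementation (limma's `squeezeVar`/`eBayes`) to within $10^{-10}$ in
one cross-check test; that library is never used on the analysis path.

P-values are two-sided; q-values are Benjamini–Hochberg step-up, computed
exactly. "Average expression" in the DEG table is the grand mean over all
samples (not the contrast groups only), so the column is identical across
contrasts of the same run.

## 4. The rank product arm

For a contrast, the ratio matrix holds one column per (test, reference)
sample pair within the same batch stratum — cross-batch comparisons are
never formed — or one column per pair in paired designs. $RP_g$ is the
geometric mean of the gene's ranks (descending for up, ascending for
down, average ranks on ties), so $1 \le RP_g \le G$ and a gene top-ranked
everywhere scores exactly 1.

Significance uses the standard rank-product permutation null: gene labels
are shuffled independently within each comparison column; pooling
permuted values over genes and permutations gives, per gene,
$E_g = c_g/n_{\mathrm{perm}}$ expected false positives at its cutoff,
$p_g = c_g/(n_{\mathrm{perm}} G)$ and $\mathrm{PFP}_g = E_g /
\mathrm{rank}(RP_g)$. The count-based estimator is used as-is (no +1
smoothing), PFP is clipped to $[0,1]$ for tables with the raw value kept
in a separate column, and everything is deterministic given the seed.

**A calibration caveat that users should know.** The permutation null
treats the comparison columns as independent. That is exactly true for
paired designs (disjoint sample pairs) and for comparisons pooled across
independent experiments — the setting the rank-product method was
designed for — and the suite verifies calibration there (fraction of
null $p < 0.05$ inside a 3-Monte-Carlo-s.e. band of 0.05). For an
*unpaired* contrast the all-pairs columns share samples and are
positively correlated, which the shuffled null cannot represent; observed
rank products are then more extreme than the null expects, and the
pooled $p$ is anti-conservative. This is a structural property of the
rank-product machinery (shared with the established implementations), not
of this rewrite. In practice it matters for the raw $p$; the marked gene
lists are still controlled by the PFP-and-fold-change double threshold,
and the FDR-on-truth acceptance test passes for the unpaired arm at the
default settings.

The two one-sided results merge into one signed table by taking, per
gene, the direction with the smaller $p$; an exact tie marks the gene 0.
This convention is this package's own (reasonable alternatives exist);
it is stated here and in the table schema so downstream users are not
surprised.

Markings reuse the same rule as the parametric arm with PFP in place of
$q$.

## 5. Counts (voom-style weights)

Counts become $\log_2\!\big((c + 0.5)/(L + 1)\cdot 10^6\big)$ (log2-CPM).
Per-gene residual standard deviations from the design fit are
square-rooted and regressed on mean log2 count with lowess (span 0.5,
tricube weights, 3 robustness iterations); the trend is evaluated at each
cell's fitted log2 count, extrapolating linearly past the range ends, and
the weight is the prediction to the $-4$th power — an inverse predicted
variance of the log value. No TMM-style library-size normalization
factors are applied (deliberately out of scope; the log-CPM offset
handles sequencing depth to first order). Weighted fits then flow through
the moderated-t arm unchanged.

## 6. What the synthetic generators emulate — and what they do not

`generate_expression_dataset` draws exactly the hierarchy the
moderated-t arm assumes: $\sigma^2_g \sim s_0^2 d_0/\chi^2_{d_0}$
(defaults $d_0 = 4$, $s_0^2 = 0.05$, typical of well-normalized arrays),
baselines $\mathcal{N}(7, 1.5^2)$ on log2, a `de_fraction` of genes
shifted $\pm$`log2fc` in the test group, and an optional additive batch
shift on a balanced half of the samples. A green calibration or
FDR/recall test therefore establishes that the machinery is correct *in
its own model*, not that real arrays satisfy that model: gene–gene
correlation, intensity-dependent variance, and outlier samples are all
absent by construction.

`generate_raw_batch` follows the normexp generative model per feature.
Where the literature gave no values, the defaults were fixed once on
realism grounds: probe-set expression factors $2^{\mathcal{N}(0,2^2)}$,
matching the two-to-three orders of magnitude of dynamic range one-color
arrays resolve, and 11 probes per probe set, the standard probe-set size
on the high-density platforms being emulated. Probe-level sequence
effects and spatial artifacts are not modeled, so preparation tests
establish correct plumbing and normalization, not robustness to chip
defects.

`generate_count_dataset` uses log-normal abundances normalized to
proportions and negative-binomial counts with constant dispersion
(default 0.1, a typical bulk RNA-seq value); `fold = 1` gives an exact
null.

## 7. Determinism, logging, and numerical conventions

* One options file fully determines an analysis; `cmd_analyze` validates
  options-matrix consistency before computing anything, and identical
  inputs yield byte-identical DEG tables and QC CSVs (tested). Logs carry
  timestamps and are excluded from the byte contract; figures are
  rendered best-effort (SVG, only when a cairo device exists) and carry
  no tested content.
* All CSV writers format numbers as `%.17g`, which round-trips doubles
  exactly — reproducibility is worth more than pretty decimals.
* The rank-product permutation count defaults to 1000 and is bounded
  below at 100; the resolution of $p$ is $1/(n_{\mathrm{perm}} G)$, so
  small studies should not lower it. The FDR/recall acceptance test runs
  its 20 replicates at the documented minimum of 100 to stay inside its
  time budget; the calibration test uses the full 1000.
* Seeds: every stochastic stage derives from the options seed (the i-th
  contrast's permutations use `seed + i - 1`); generators save and
  restore the caller's RNG state.
* QC conventions: MA statistics compare each sample to the leave-one-out
  median profile; sample ordering scores the RMS deviation of a lowess
  (span 0.3) M-vs-A curve from its own least-squares line — a documented
  stand-in for "least linear", which has no canonical formula; PCA fixes
  component signs by making the largest-magnitude loading positive;
  clustering is complete-linkage on Euclidean distances (chosen for its
  monotone merge heights; "hierarchical" alone underdetermines the
  algorithm); densities use Silverman bandwidths on a shared 512-point
  grid extended three bandwidths past the data range so they integrate
  to 1.
* Design-label shorthand is `k*label` run-length expansion plus literals,
  applied order-wise; labels are restricted to `[A-Za-z0-9_.]` so that
  `-` (contrast separator), `,` (list separator) and `*` (multiplier)
  stay unambiguous.

## 8. Known limitations

* No spatial-artifact or probe-sequence (GC) corrections; no vendor flag
  handling.
* Contrasts are pairwise only — no F-tests across more than two levels,
  no interaction terms, no formula language.
* The rank-product permutation null understates cross-column correlation
  for unpaired designs (section 4).
* Annotation is a user-supplied CSV; there is no packaged annotation
  snapshot and no network retrieval.
* Count support stops at precision weights: no TMM factors, no per-sample
  quality weights.
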