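---
title: "Methods: signature-based cell-type deconvolution of bulk expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-based cell-type deconvolution of bulk expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuedecoder)
```

This vignette documents the statistical model behind `tissuedecoder`, the
choices made where the design was genuinely open, and what the synthetic
benchmarks do and do not demonstrate about real tissue data.

## The mixture model and its assumptions

A bulk expression profile is modeled as a linear combination of cell-type
signatures, $m \approx S f$ with $f \ge 0$ and $\sum_j f_j = 1$. The model
assumes that (i) expression mixes **additively on the linear scale** —
which is why all inputs are coerced to linear scale before fitting — and
(ii) each cell type's expression in the tissue matches its expression when
isolated. Assumption (ii) is the weak point of all reference-based
deconvolution: isolation protocols, tissue micro-environment and platform
differences all perturb it, which is why diagnostics (reconstruction RMSE,
correlation, permutation p-value) accompany every fit.

The estimated fractions are **relative to the transcriptional pool**, not
cell counts: a cell type contributing more mRNA per cell is over-weighted
relative to its cell-number share. Comparisons against counted-cell
literature values (see the unit-conversion section) should be read with
this caveat.

### Scale detection

Public expression matrices arrive log2-transformed about as often as not.
`ensure_linear_scale()` applies the convention of this algorithm family: a
matrix whose maximum is below 50 is taken to be log2 and exponentiated
(`2^x`), anything else passes through. The threshold is a heuristic —
linear-scale data essentially never has a global maximum under 50, and
log2 microarray/RNA-Seq data essentially never exceeds 50 — and it can be
overridden with `assume = "linear"` or `assume = "log2"`. Negative values
in a matrix judged linear are rejected as corrupt rather than clipped.
Duplicate feature ids are collapsed by row-wise mean; missing values are
rejected rather than imputed, since no imputation rule would be defensible
without knowing the upstream platform.

## Signature construction

`build_signature()` turns a labeled reference (isolated-cell profiles, each
sample assigned to one of $K \ge 2$ cell types) into a signature matrix in
two stages.

**Differential selection.** For each cell type, every feature is tested
with a two-sided unequal-variance (Welch) t-test of that type's samples
against all other samples, the p-values are Benjamini–Hochberg adjusted
per cell type, and features passing `q_threshold` (default 0.3) and a
fold-change floor (`min_fold`, default 1, i.e. any up-regulation) are
ranked by decreasing fold-change of the type mean over the mean of the
remaining samples. The permissive default FDR reflects the role of the
filter: it feeds a ranked candidate list into the sweep below, which does
the real selection; tightening `q_threshold` is the right lever when a
reference has many replicates. Cell types represented by a single sample
have no within-type variance; their tests fall back to the residual
variance pooled across all other types (df-weighted), with a warning —
references should have at least two replicates per type.

**Condition-number sweep.** For every per-type marker-set size $G$ from
`g_min` to `g_max` (defaults 50–150, following the published convention of
this algorithm family; small synthetic references use proportionally
smaller sweeps), the union of all types' top-$G$ markers restricts the
mean-profile matrix, and its condition number
$\kappa = \sigma_{\max}/\sigma_{\min}$ is computed by SVD. $\kappa$
measures information overlap between the cell-type columns: collinear
columns (indistinguishable types) drive it to infinity, orthogonal ones
toward 1. The sweep keeps the $G$ with minimal $\kappa$; ties break toward
the smaller $G$, favoring compact signatures. Rank-deficient candidates
report $\kappa = \infty$, and if every candidate is rank-deficient the
reference genuinely cannot separate its cell types and the build fails
with that message.

## ν-SVR deconvolution

`deconvolve()` restricts each mixture and the signature to their shared
features (at least 50% of the signature's features must be present —
below that, cross-platform matching is too lossy to trust, and the fit
errors out with the overlap count), standardizes the signature globally
over all entries and the mixture over its own, and solves a linear-kernel
ν-support-vector regression (`e1071::svm`, the standard R implementation)
for each ν in {0.25, 0.5, 0.75}. ν bounds the fraction of support vectors,
i.e. how many genes actively constrain the fit; rather than fixing it, the
solution with the smallest reconstruction RMSE is kept. The SVR cost
constant defaults to 1 and is exposed as a parameter. Negative coefficients
— which have no compositional meaning — are clipped to zero and the
remainder renormalized to sum to one. If every coefficient is clipped the
sample has no admissible composition and errors (dataset-level runs collect
such failures as warnings). Standardization makes the fractions invariant
to any positive rescaling of the mixture, so unnormalized and normalized
inputs give the same answer.

The optional permutation p-value shuffles the mixture's values across
features `n_perm` times and reports
$(\#\{r_{perm} \ge r_{obs}\} + 1)/(n_{perm} + 1)$ — a guard against
interpreting fractions from a profile that the signature cannot actually
reconstruct. It is off by default (`n_perm = 0`) because it multiplies the
fit cost.

`aggregate_archetypes()` sums member fractions into the four tissue
archetypes (immune, stem/stromal, adipocyte, other). The bundled
21-type mapping places platelets and erythroblasts — included in
references mainly as blood-contamination controls — under "immune" with
the rest of the hematopoietic lineage; the mapping is an explicit argument
precisely so users can move them into "other" if they prefer.

## Marker criteria

With $g'_{ij}$ the mean linear-scale expression of gene $i$ in cell type
$j$, the two criteria are

$$\mathrm{crit}_{primary}(i,j) = g'_{ij} - \max_{k \ne j} g'_{ik}, \qquad
  \mathrm{crit}_{secondary}(i,j) = g'_{ij} - \mathrm{mean}_{k \ne j}\, g'_{ik}.$$

The primary criterion is positive only for genes expressed above **every**
other cell type — the property a single immunostaining marker needs. The
secondary criterion tolerates sharing among a few types; panels of
secondary markers (as in flow-cytometry gating) identify types lacking any
single specific marker. Two identities are useful for testing and
interpretation: $\mathrm{crit}_{primary} \le \mathrm{crit}_{secondary}$
always (the max over others is at least their mean), and each gene's
secondary scores sum to zero across cell types.

Both criteria are in expression units, so highly expressed genes dominate
the rankings — intended behavior, since usable markers must be detectable.
The criteria default to the same linear scale as the mean profiles;
`log2_scale = TRUE` scores $\log_2(g'+1)$ instead, which ranks by relative
rather than absolute separation. Ranked lists break ties lexicographically
by feature id and flag negative scores. `merge_groups()` relabels the
reference under a coarser grouping (e.g. pooling adipocyte depots) so that
markers shared by sibling types — which cancel in depot-by-depot scoring —
surface as markers of the merged group.

## Literature unit conversion

Published cell counts for tissue appear in six units. Four are linearly
convertible to percent of total cells given two explicit assumptions — the
adipocyte fraction of total cells $a$ and the total cells per gram $c$:

| unit | percent of total cells |
|---|---|
| per 100 adipocytes | $x \cdot a$ |
| per gram | $100\,x / c$ |
| percent of SVF | $x (1 - a)$ |
| per total nuclei (fraction) | $100\,x$ |

These are the unique linear conversions implied by the two parameters; both
must be supplied explicitly (`conversion_assumptions()`) because published
estimates of $a$ alone span 15–93% and any silent default would bake in a
contested quantity. Counts per high-power field and per mm² depend on
section geometry and have no such conversion; those records are marked
`excluded` and never receive a number. Standard deviations are scaled by
the same linear factor, with no distributional adjustment.

## Phenotype statistics

Fractions live in $[0,1]$ and are typically skewed, so all tests are
rank-based: Wilcoxon signed-rank for paired designs (zero differences
dropped, the usual convention; exact p-values for small untied samples,
continuity-corrected normal approximation otherwise — `stats::wilcox.test`
throughout), Wilcoxon rank-sum for unpaired two-group comparisons, and for
continuous covariates a permutation test on Spearman's $\rho$ (average
ranks for ties; two-sided $p = (\#\{|\rho_{perm}| \ge |\rho_{obs}|\}+1)/(n_{perm}+1)$,
default 10,000 seeded permutations — enough for stable p-values near 0.05
while keeping a 336-comparison grid under a minute). Benjamini–Hochberg
correction is applied jointly over the whole cell-type × trait grid, and
results carry significance flags both raw and adjusted. The reported
`z_score` summarizes group separation as the difference of group means
over the pooled standard deviation — an effect-size companion to the
rank-based p-value, not the test statistic itself.

## The synthetic generator

`simulate_reference()` draws baseline expression per feature from a
log-normal distribution (meanlog $\log 100$, sdlog 1 — positive,
right-skewed, with the orders-of-magnitude spread typical of linear-scale
intensity data), plants `markers_per_type` disjoint marker features per
cell type by multiplying their baseline by `marker_effect`, and perturbs
replicates with multiplicative log-normal noise of coefficient of
variation `noise_cv` (unit mean, so noise does not bias the profiles).
`simulate_mixtures()` draws fraction vectors from a Dirichlet distribution
and mixes the true type profiles accordingly, with the same multiplicative
noise. For the default 4-type configuration the Dirichlet mean is set to
the average archetype composition of subcutaneous adipose tissue — 74%
adipocytes, 14.9% stem/stromal, 7.4% immune, 3.7% other — with
concentration 10; other type counts default to a flat Dirichlet.
`simulate_phenotypes()` overlays two-group or paired designs with additive
fraction shifts (renormalized), giving null-calibrated designs when no
effect is specified. All generators are reproducible from their seed.

**What the synthetic benchmarks show — and what they don't.** Planted
markers are disjoint and noise is independent across features, so the
synthetic references are *easier* than real ones: real cell types share
marker programs, real noise is correlated (batch, probe effects), and real
references mix laboratories and platforms. Passing the recovery benchmarks
(mean absolute error < 0.05 per type against known fractions; agreement
with a non-negative-least-squares oracle; 100% self-deconvolution of the
reference) demonstrates the estimator's correctness and numerical
behavior, not its field accuracy on tissue biopsies — that depends on
reference quality and platform match, and degrades gracefully with noise
(monotonically in the benchmarks). Benchmark problem sizes (400 features,
6 types, 5 replicates, 100 mixtures; 1000 null replicates at 999
permutations for test calibration) were chosen as the smallest sizes at
which the measured quantities are stable to the reported precision.

## Numerical choices and degenerate inputs

* $\kappa$ uses the SVD directly; singular values below
  $\max(\dim) \cdot \epsilon \cdot \sigma_{\max}$ count as zero
  ($\kappa = \infty$).
* Zero-variance features in the Welch test take the degenerate limit:
  p = 0 when the group means differ (perfect separation), p = 1 when they
  are equal.
* Sweep ties and ranking ties have deterministic tie-breaks (smaller $G$;
  lexicographic feature id), so outputs are byte-reproducible.
* All-zero expression matrices, constant mixture profiles, constant
  signature columns, empty feature intersections and unmapped cell types
  fail fast with named errors rather than propagating NaNs.
* The SMO solver inside the SVR converges to a tolerance, so fractions are
  reproducible bit-for-bit only under identical inputs; scale invariance
  holds to solver tolerance (~1e-3), which the tests assert.

## Known limitations

* No batch or platform correction: cross-platform deconvolution relies on
  feature intersection plus standardization only, and quality must be
  judged from the fit diagnostics.
* Relative mRNA-pool fractions, not cell-number fractions (see above).
* The marker criteria score mean profiles; they do not model within-type
  heterogeneity (a marker of a sub-population scores as a weak marker of
  the whole type).
* Reference preprocessing (normalization across the studies composing a
  reference) is out of scope and assumed done upstream.
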