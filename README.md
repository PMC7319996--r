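# tissuedecoder

Estimating the cell-type composition of bulk tissue from gene expression.

Bulk transcriptome profiles of a tissue biopsy mix the expression of every
cell type present — adipocytes, immune cells, stem/stromal cells, endothelium
and more. `tissuedecoder` recovers the relative fractions of those cell types
from the bulk profile alone, so that archived microarray and RNA-Seq datasets
can be re-read as cell-composition measurements. It is aimed at researchers
studying tissue heterogeneity (the motivating application is human adipose
tissue and its depots) who want composition estimates, candidate cell-type
markers, and composition-vs-phenotype statistics from public expression data.

## The model

A bulk mixture profile $m \in \mathbb{R}^{p}$ over $p$ genes is modeled as a
non-negative combination of cell-type-specific expression signatures:

$$ m \approx S f, \qquad f_j \ge 0, \qquad \textstyle\sum_j f_j = 1, $$

where $S$ is a $p \times K$ **signature matrix** whose column $j$ is the mean
linear-scale expression profile of cell type $j$ over isolated-cell reference
samples, and $f$ is the vector of relative cell-type fractions. The package
provides the full workflow around this model:

* **Signature construction** (`build_signature`) — for each cell type,
  candidate markers are selected by an unequal-variance t-test (that type
  against all other reference samples) with Benjamini–Hochberg FDR control
  and ranked by fold-change; then, for every per-type marker-set size $G$ in
  a sweep, the union of top-$G$ markers is scored by the **condition number**
  $\kappa(S) = \sigma_{\max}/\sigma_{\min}$ of the restricted signature, and
  the $G$ minimizing $\kappa$ is kept. Low $\kappa$ means the cell-type
  columns are mutually distinguishable.
* **Deconvolution** (`deconvolve`) — $f$ is estimated by linear-kernel
  ν-support-vector regression of the standardized mixture on the standardized
  signature, with ν chosen from {0.25, 0.5, 0.75} by reconstruction RMSE;
  negative coefficients are clipped and the rest renormalized to sum to one.
  Fits return per-sample diagnostics (RMSE, Pearson r, optional permutation
  p-value) and support archetype roll-ups (immune / stem-stromal / adipocyte
  / other) via `aggregate_archetypes`.
* **Marker scoring** (`marker_scores`) — every (gene, cell type) pair gets a
  *primary* criterion $g'_{ij} - \max_{k \ne j} g'_{ik}$ (positive only for
  genes expressed above every other type: single-marker material for
  immunostaining or flow cytometry) and a *secondary* criterion
  $g'_{ij} - \mathrm{mean}_{k \ne j}\, g'_{ik}$ (enrichment against the
  average background; combinations of secondary markers identify types that
  lack a single specific marker), where $g'_{ij}$ is the mean expression of
  gene $i$ in cell type $j$.
* **Literature unit conversion** (`to_percent_total`) — published cell counts
  in heterogeneous units (per 100 adipocytes, per gram, percent of SVF, per
  total nuclei) are linearly converted to percent of total cells under
  explicit assumptions; counts per high-power field or per mm² are excluded.
* **Phenotype statistics** (`associate_fractions`) — Wilcoxon signed-rank
  (paired), Wilcoxon rank-sum (unpaired) and Spearman permutation tests
  (continuous covariates) over the cell-type × trait grid, with joint
  Benjamini–Hochberg correction.
* **Synthetic data** (`sim_config`, `simulate_reference`,
  `simulate_mixtures`, `simulate_phenotypes`) — references with planted
  markers and mixtures with known fractions, so every step is testable
  offline with ground truth.

## Worked example

Simulate a 4-type reference (default mixture composition mirrors
subcutaneous adipose tissue: ~74% adipocytes, ~15% stem/stromal, ~7%
immune), build a signature, deconvolve 20 bulk mixtures, and compare against
the known truth:

```r
library(tissuedecoder)

cfg <- sim_config(n_types = 4, n_mixtures = 20, seed = 7)
sim <- simulate_reference(cfg)
sig <- build_signature(sim$ref, g_min = 4, g_max = 10)
sig
#> Signature matrix: 40 features x 4 cell types
#>   condition number kappa = 5.433 (chosen at G = 10 markers/type)

mix <- simulate_mixtures(sim$profiles, cfg)
fit <- deconvolve(mix$mixtures, sig)
summary(fit)
#> Estimated cell-type fractions over 20 sample(s):
#>      cell_type   mean median     q25    q75
#> 1    adipocyte 0.7339 0.7542 0.61759 0.8615
#> 2 stem_stromal 0.1269 0.1089 0.05512 0.1864
#> 3       immune 0.0972 0.0678 0.03746 0.1253
#> 4        other 0.0420 0.0126 0.00507 0.0426

mean(abs(coef(fit) - mix$fractions))
#> [1] 0.00632
```

The summary shows the estimated composition distribution across samples —
here dominated by adipocytes, as in the simulated tissue — and the mean
absolute error against the generating fractions is below 1%. Ranked marker
lists come from the same reference:

```r
rank_markers(marker_scores(sim$ref), "immune", "primary", top_n = 3)
#>   feature_id    score rank negative
#> 1  gene_0023 2539.973    1    FALSE
#> 2  gene_0025 2527.950    2    FALSE
#> 3  gene_0021 1653.570    3    FALSE
```

A `negative` flag would mark genes whose criterion is negative, i.e. genes
some other cell type expresses higher.

The same pipeline is scriptable from a shell via the bundled CLI
(`system.file("cli", "tissuedecoder", package = "tissuedecoder")`), with
subcommands `simulate`, `build-signature`, `deconvolve`, `markers`,
`convert-units` and `compare`.

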