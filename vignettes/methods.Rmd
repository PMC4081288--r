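---
title: "Primary analysis of single-cell qRT-PCR Ct matrices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primary analysis of single-cell qRT-PCR Ct matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgrid)
```

## The problem

Nanoscale microfluidic qRT-PCR measures ~96 gene targets in single sorted
cells, reporting a cycle threshold (Ct) per reaction: lower Ct means more
transcript, values live in [1, 40], and a reaction with no signal carries the
sentinel 999. Two ambiguities dominate primary analysis of such matrices:

1. **A missing reaction is ambiguous.** It can mean true absence of the
   transcript in that cell (biology: an "off" cell state) or a failed
   reaction (technics). On/off bimodality across cells is exactly what makes
   single-cell data interesting, so resolving this ambiguity wrongly either
   destroys real subtypes or invents them.
2. **Plate (array) effects.** Cells are spread across several microfluidic
   arrays. If one array underperforms, its low-abundance reactions drop out
   together, which looks exactly like a co-regulated gene block defining a
   cell subtype.

`ctgrid` implements the comparison that makes these choices visible: three
data-exclusion strategies crossed with three normalization methods, each of
the nine processed matrices clustered, and the cluster assignments compared
across pipelines by concordance.

## Exclusion strategies

**Supervised** (`exclude_supervised()`): genes present in ≥ 70% of cells form
a core set; cells detecting ≥ 70% of the core are retained. The missingness
patterns of the remaining low-presence genes are clustered (Ward linkage on
Jaccard distances between gene missingness sets), and blocks of genes that
are missing *together* are interpreted as truly silent — their missing values
become Ct 40. Remaining sporadic missing values are treated as technical and
replaced by the gene's mean observed Ct. Output stays on the Ct scale.

The block rule needs a quantitative "co-missingness rate". We use the mean
pairwise Simpson overlap coefficient `|A∩B| / min(|A|,|B|)` over the genes'
missing-cell sets, flagging maximal dendrogram subtrees of size ≥ 2 whose
mean overlap reaches `block_missing_rate` (default 0.5). Plain Jaccard was
rejected: with realistic independent baseline dropout on top of a shared
cause, Jaccard is diluted by the symmetric difference and cannot reach 0.5
even for strongly co-caused blocks, whereas the overlap coefficient measures
containment of the smaller set and stays high. Genes never detected anywhere
are excluded up front: an empty missingness complement has overlap 1 with
every gene and would otherwise attach to any block. The detected blocks are
reported verbatim in the `ExclusionReport` so the exploratory choice can be
reviewed or overridden.

**SD cutoff** (`exclude_sd_cutoff()`): missing → Ct 40; the single
highest-expressed gene is ignored as an outlier; the 2nd/3rd
highest-expressed genes become references, their pooled per-cell Ct values
giving a mean and SD ("standard deviation" is not further specified by the
method's description; pooling uses all available replication). Genes whose
mean Ct exceeds `ref mean + 3·SD` are excluded; cells detecting fewer than
half the retained genes are excluded; the matrix is inverted to **Log2EX**
(`LOD Ct − Ct`, everything above the limit of detection clamped to the LOD,
so 0 = undetected); undetected values stay 0 (`as_zero`) or become the
gene's mean Log2EX over detected cells (`as_gene_mean` — the
"missingness is technical" interpretation); cells whose mean reference
expression sits more than 3 SD units below the median are excluded (SD unit:
the two reference genes' per-cell SDs averaged); finally genes detected in
≤ 1 retained cell are dropped.

Note a property of this method that the synthetic world reproduces: the
pooled reference SD is inflated by occasional reference-gene failures (each
contributes a 40 to the pool) and by genuine cell-to-cell spread of
high expressors, and this inflation is what lets low-abundance genes pass the
3-SD cutoff at all. With technically perfect, tightly distributed reference
genes the cutoff would collapse to a few cycles and discard most of a
realistic panel.

**All-inclusive** (`exclude_all_inclusive()`): retain every cell; drop only
genes undetected in every control sample and genes undetected in all cells of
any single array (a whole-array dropout is uninterpretable); transform to
Log2EX.

**LOD determination** (`determine_lod()`): each gene's maximum finite Ct is
computed; the histogram of those maxima (1-cycle bins, default search window
Ct 30–40 — integer bins because the quantity is read off a histogram) is
typically bimodal, the upper mode being genes whose weakest signals sit at
non-detection level. The LOD is the left edge of the first bin after the
deepest valley between the two largest local maxima; a unimodal histogram is
an error and the caller must supply the LOD.

## Normalization methods

1. **Per-cell mean centering** (`mean_center()`) — removes cell-level signal
   magnitude, preserves within-cell contrasts exactly.
2. **Quantile normalization across cells** (`quantile_normalize()`) — the
   value at rank r in each cell is replaced by the mean of rank-r values over
   cells; after the transform all cells share one distribution. Ties (mostly
   the zeros of the Log2EX scale) receive the average of their tied
   positions' quantile means; this tie rule matches `limma`'s
   `normalizeQuantiles(ties = TRUE)`, which the test suite uses as an
   independent oracle.
3. **Per-gene standardization with plate ANOVA**
   (`standardize_with_plate()`) — cell centering, per-gene z-scores (sample
   SD, n−1; zero-variance genes set to 0 and flagged), per-gene one-way
   ANOVA with plate as a fixed effect with values replaced by residuals
   (equivalently: each gene's per-plate means subtracted), and a final
   per-cell recentering. Ordinary least-squares group means are the simplest
   model with plate as the main effect; no re-standardization is applied
   after residual extraction.

Exact and approximate invariances of method 3 deserve care. An offset that is
constant across *genes* for a plate is absorbed entirely at the cell-centering
stage, so the output is bit-identical to the offset-free run. A
*gene-specific* plate offset is removed in the mean — after the ANOVA stage
every gene's per-plate residual mean is 0, and the final recentering
preserves that (the per-plate mean of cell means of residuals is again 0) —
but not in scale: the offset inflates that gene's overall SD before the
z-score stage, so the gene arrives rescaled relative to the offset-free run.
The tests therefore assert bit-level invariance for uniform plate offsets and
exact equality of per-plate per-gene means for gene-specific offsets.

The normalization input scale follows the exclusion strategy (Ct for
supervised, Log2EX for the other two): each normalization is applied to
whatever matrix its exclusion step yields.

## Modality classification

`classify_modality()` separates each gene's values into candidate low-peak
members (missing codes plus finite low expressors at Ct ≥ 35) and expressed
values, fits the expressed values with `fit_families()` — normal, lognormal,
gamma, Weibull by maximum likelihood; Johnson SU/SL by Slifker–Shapiro
quantile matching (full ML for Johnson families is fragile at ~40 cells per
gene); normal mixtures with k = 2, 3 by EM (quantile-anchored restarts, log-space
responsibilities, SD and weight floors; see the numerical-choices section) —
and scores everything by
`AIC = 2·k − 2·logL`. Calls:

* **T** if the k = 3 mixture beats both the k = 2 mixture and the best
  unimodal family by the deltaAIC threshold;
* **B** if the k = 2 mixture wins by the threshold *or* the low-peak
  fraction lies in (0.1, 0.9) — a distinct off/low peak does not need a
  mixture fit to be recognized; **B-M** when the low peak holds only
  missing-coded values, **B-L** when it contains finite low expressors;
* **U** otherwise, including samples too small to fit (flagged).

The deltaAIC threshold (default 2) is an explicit, logged replacement for
the visual verification a human analyst would perform; it is configurable
because the conventional "substantial support" boundary of 2 is a judgment
call. A purely finite bimodal gene with both modes expressed below Ct 35 has
no label in the B-M/B-L scheme; it is reported as B-L with a
(0 missing, 0 low-expressor) composition, a case the synthetic generator
never produces but real panels might.

## Clustering and concordance

`ward_cluster()` implements Ward's minimum-variance agglomeration on
Euclidean distances via the Lance–Williams recurrence, with merge heights
equal to the within-cluster ESS increase of each merge and ties broken by
merging the lowest-index pair first. This in-package implementation (rather
than a library call) pins down tie-breaking and height semantics so the
exhaustive-merge oracle in the tests can check *every* merge on small inputs.
`kmeans_cluster()` is Lloyd's algorithm with random restarts and
farthest-point re-seeding of empty clusters. Features enter the distance
exactly as the normalization stage left them; no additional scaling is
applied.

The cluster count is chosen by the cubic clustering criterion
(`ccc()`, Sarle's 1983 approximation: observed R² against its expectation
under a uniform hyperbox null with edge proportions from the
principal-component scales) over k ∈ {2, 3} (`select_k()`); only the CCC's
*ordering* is relied on, since other implementations of the criterion differ
in detail. `concordance()` matches cluster indices between two pipelines by
exact optimal assignment on the confusion matrix (enumeration; k ≤ 8) and
reports the percentage of shared cells assigned to corresponding clusters.
`donor_cluster_table()` and `chi_square_test()` (Pearson, no continuity
correction) quantify donor-to-donor variability in cluster membership.

## The synthetic world

`generate_ct_data()` draws finite Ct values from normal components on the Ct
scale — the log scale of expression, matching the log-normal behaviour of
single-cell transcript levels — with latent cell subtypes shared across
bimodal genes (a gene's `subtype_linkage` sends that subtype to the low/off
component), donor-specific subtype proportions, technical dropout, and two
technical artifact mechanisms: a per-plate extra dropout probability for
low-abundance genes (component mean above a Ct threshold), and a
"low-RNA-quality cell" mechanism in which a small fraction of cells lose
low-abundance genes in a coordinated fashion, emulating inefficient RNA
extraction. Ground truth records each cell's subtype and, per reaction,
whether a missing value is biological or technical — the very distinction
the exclusion strategies disagree about.

`immune_panel_fixture()` instantiates a study-like design: 5 donors × 44
neutrophils (or 6 donors, 247 T cells with higher heterogeneity), 96 genes
on 5 arrays, two latent subtypes with donor-skewed proportions (one donor
near 45% of subtype A against ~19% overall), loading controls (10- and
100-cell, Ct shifted by log2 of the cell count) and negative controls. The
panel contains one far-highest outlier gene, two high-expressed reference
genes with substantial cell-to-cell spread (SD 4 Ct) and a 4% failure rate,
unimodal genes at Ct 19–24.5, subtype-linked B-L and B-M genes, trimodal
genes, three never-expressed genes, and 23 low-abundance genes
(Ct 25.5–27.5) that lose ~98% of their signal on array 1.

Parameters the study design does not pin down — plate-artifact magnitude
above all — were calibrated so that the artifact reproduces its documented
phenomenology: with mean centering or quantile normalization, Ward
clustering splits a true subtype along plate lines (an artificial third
cluster), while plate standardization recovers the two true subtypes with
≥ 95% concordance against ground truth. Calibration taught us three things
worth recording, because they are substantive properties of the methods, not
quirks of the generator. First, under quantile normalization the zeros of
the Log2EX scale form large within-cell tie groups, and rank averaging
compresses a dropout artifact's contrast by several-fold relative to mean
centering; the artifact must involve many genes of non-trivial abundance to
survive it. Second, any single gene with a very large cell-to-cell spread
(a wide reference gene, or one with frequent isolated failures) creates a
one-coordinate axis that Euclidean Ward will happily cut into a spurious
cell cluster — an argument *for* the per-gene standardization route. Third,
the dropout-inflated pooled reference SD is load-bearing for the 3-SD
cutoff, as noted above.

What a green test on this fixture does **not** establish: robustness to
amplification or preamplification bias (not simulated), to non-normal
within-component distributions, to correlated expression between genes
beyond subtype structure, or to the magnitudes of real plate effects, which
the study does not quantify. The fixture's donor proportions echo the
printed donor-by-cluster table; at those proportions and 44 cells per donor
the noncentrality of the donor chi-square is ~27.7, so the power of the
test at α = 0.001 is 0.90 asymptotically and ≈ 0.89 in finite samples —
the acceptance property asking for ≥ 90% rejection sits exactly on this
boundary and is expected to fail narrowly; it is asserted unmodified rather
than widened.

## Worked example

```{r example, eval = FALSE}
fx <- immune_panel_fixture("neutrophil", seed = 1)
gr <- run_grid(fx$ct, fx$annotations, fx$controls, grid_config(seed = 1))
print(gr)

truth <- setNames(as.integer(factor(fx$truth$subtype)), fx$truth$cell_id)
concordance(gr$pipelines[["sd_cutoff+standardize_plate"]]$cluster, truth)

gr$pipelines[["sd_cutoff+standardize_plate"]]$chi_square[c("chi_square", "df", "p_value")]
```

## Numerical choices and degenerate inputs

* Histogram bin width for LOD determination: 1 cycle (integer-resolution
  quantity); valley ties resolve to the bin adjacent to the upper mode.
* z-scores use the sample SD (n − 1); zero-variance genes map to 0 with a
  flag instead of erroring.
* EM: 20 quantile-anchored restarts, tolerance 1e-8 on the log-likelihood.
  The EM is constrained: component SDs are floored at 5% of the sample SD
  and component weights at 5%, because an unconstrained 1-D Gaussian
  mixture reliably converges to a likelihood singularity — a near-zero-SD
  component absorbing a single outlying point — which masquerades as
  decisive AIC evidence for bimodality. A component carried by a vanishing
  fraction of cells is an outlier, not a mode; the 5% weight floor matches
  the spirit of the 10% low-peak fraction rule. Seeds are explicit
  arguments everywhere, and all seeded code restores the caller's RNG
  state.
* Quantile-normalization ties take the mean of their positions' quantile
  means.
* Ward tie-break: lowest-index pair merges first (column-major scan of the
  distance matrix).
* `ccc(k = 1)` returns `NA` (undefined); degenerate predictors in the
  multicell QC regression yield R² = 0 with a warning and flag.
* The multicell QC regression compares per-gene means on the Ct scale
  (whether the original workflow used Ct or an expression transform is not
  documented; Ct is the rawest comparable quantity and R² is invariant to
  the affine part of any Log2EX transform anyway).
* Exclusion functions fail loudly (naming the step) when a step would empty
  the matrix; a pipeline failure inside `run_grid()` is recorded per
  pipeline and does not abort the grid.

## Known limitations

* The supervised block detection is exploratory by nature; the defaults are
  a reasonable formalization, not a canonical one, which is why the blocks
  are part of the report.
* Johnson SU/SL parameters come from quantile matching, not full ML; their
  AICs are evaluated honestly at those parameters but can be mildly
  pessimistic.
* Concordance uses exact assignment up to 8 clusters; larger k would need a
  polynomial assignment solver, which this domain (k ∈ {2, 3}) does not
  require.
* The CCC implementation follows the published approximation; other
  implementations may differ in magnitude, so only orderings should be
  compared across software.
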