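---
title: "Methods: spatial immune organization around pancreatic lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial immune organization around pancreatic lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlscape)
```

# Scope

`tlscape` implements a two-arm analysis of immune organization around
pancreatic lesions — precursor (PanIN), invasive tumor (PDAC), and chronic
pancreatitis (CP) regions:

* a **proteomic arm** over segmented single-cell tables from multiplexed
  imaging: marker-gated phenotyping, per-ROI immune densities with
  rank-based tests, nearest-neighbour interaction structure, and detection
  plus maturity classification of tertiary lymphoid structures (TLS);
* a **transcriptomic arm** over spot-level expression on a Visium-style
  hexagonal lattice: spot QC and TLS-neighbourhood labelling, sparse
  non-negative matrix factorization (NMF) into latent expression patterns,
  a fractional-expression pattern-marker statistic, bin-matched module
  scoring of a TLS gene signature, and preranked permutation GSEA.

A synthetic-data module plants known ground truth for both arms, so every
stage is validated end to end against planted cells, aggregates, patterns,
markers, and signatures.

# Proteomic arm

## Intensity transform and positivity

Raw marker intensities are variance-stabilized with `asinh(x / 5)`
(`transform_intensities()`), the usual mass-cytometry convention; the
cofactor is configurable. Positivity calls (`call_positivity()`) support
three modes:

* explicit per-marker thresholds (the analyst's gates);
* a per-marker quantile (default `q = 0.75`) — simple, but a fixed
  quantile is only correct when the positive fraction happens to match
  `1 - q`. Markers carried by rare populations (FOXP3 on Tregs, CD57 on
  NK cells — a few percent of cells) land their quantile threshold inside
  the negative mode;
* **density-valley gating** (`thresholds = "bimodal"`), the default in the
  pipeline: a kernel density estimate of the log intensities, thresholded
  at the first *deep* valley right of the dominant (negative) mode. A
  valley qualifies when density falls below half of both the main mode
  and the best mode beyond it, and that positive mode carries at least
  0.8% of the peak density. This mirrors manual flow-cytometry gating,
  works whether 2% or 40% of cells are positive, and degrades safely: a
  unimodal marker gets a threshold above the data, so no cell is called
  positive.

## Gates

Phenotypes are ordered boolean gates over positivity (`apply_gates()`),
ranked by specificity (number of constrained markers; declaration order
breaks ties), so `CD20+CD21+CD23+` germinal-center B cells are claimed
before plain `CD20+` B cells. The packaged panel (`inst/extdata/gates.yaml`)
encodes the phenotypes of interest, including Tregs as
`CD3+CD4+FOXP3+PD1-` and cytotoxic T cells as `CD3+CD8+GZMB+`. Unmatched
cells stay `unassigned` and are carried through density accounting so
counts are conserved. k-means over transformed intensities
(`cluster_cells()`, fixed seed) is provided as a deterministic, desk-scale
stand-in for self-organizing-map or graph clustering, with cluster-level
gate annotation (`annotate_clusters()`, a marker is cluster-positive when
at least half its cells are).

## Densities and tests

Density is count over ROI area (cells/mm²; `cell_density()`), with the ROI
as the statistical unit. Two-group comparisons use the two-sided Wilcoxon
rank-sum test: exact enumeration when both groups have at most 12
observations and no ties, otherwise the normal approximation with tie and
continuity corrections; multi-group comparisons use Kruskal–Wallis. No
multiple-testing correction is applied to density panels (callers can
apply `p.adjust` downstream); GSEA is the one place BH correction is built
in. Degenerate inputs (all values identical) return p = 1 rather than an
error. `density_ratio()` reports ratios such as CD8:Treg per ROI, with an
empty denominator yielding a missing value, never infinity.

## Interaction structure

`interaction_matrix()` computes, for each ordered phenotype pair (A, B),
the mean over A cells of the Euclidean distance to the nearest B cell
(self excluded on the diagonal) — one number per pair, the only reading
under which "average shortest distance" is well defined. Phenotypes below
1% abundance are removed first. The matrix is asymmetric; it is
symmetrized only for network layout (`interaction_network()`, edge length
`(M[A,B] + M[B,A]) / 2`). `top2_neighbor_matrix()` accumulates each cell's
two nearest neighbours (centroid distance, ties broken by smaller
`cell_id` for determinism), so row sums equal twice the focal-type count;
`normalize_contacts()` divides by the most abundant phenotype's count
(an alternative `max_entry` denominator is available). The vectorized
implementations are tested for exact equality against plain per-point
brute-force oracles up to 2000 cells.

## TLS detection, association, and maturity

The originating study's TLSs were pathologist-annotated; the computational
stand-in is density-based clustering (DBSCAN) over lymphoid cells only,
with `eps_um = 30` (a 2–3 lymphocyte-diameter reach), `min_samples = 10`,
and `min_cells = 50`. These defaults are configuration, not biological
claims: no minimum aggregate size separating "aggregate" from "TLS" is
established in the field, and all three are exposed. Note the detection
operating point: a disc must hold roughly `min_samples / (pi eps²)` ≈
3,500 lymphoid cells/mm² to be found, which organized aggregates exceed
several-fold.

Each aggregate's boundary is the convex hull of its member cells.
Association (`associate_tls()`) assigns the class of the nearest lesion
polygon whose boundary lies within 250 µm of the hull boundary
(hull-to-polygon minimum distance, 0 on overlap); farther aggregates are
`excluded`. The cutoff is a parameter because the margin convention varies
between 200 and 250 µm across analyses of this kind. Exact ties are broken
by region order, with a message.

Maturity (`classify_maturity()`) is a computable proxy for "a distinct
germinal-center zone": mature iff at least `gc_min_cells = 10`
germinal-center B members (CD20+CD21+CD23+) are present **and** their
centroid lies in the hull interior eroded by 10% of the hull radius.
Dendritic-cell (DCSIGN+) and high-endothelial-venule (PDPN+) densities
inside the hull, and a B/T zone-segregation index (difference in mean
centroid distance of T versus GC-B members, normalized by hull radius),
are always reported but never used in the call, so the decision rule stays
auditable.

# Transcriptomic arm

## Spot QC and TLS neighbourhoods

`filter_spots()` applies three rules, each logged: a spot is labelled by
its predominant tissue class when that class reaches 70% of its
composition; spots labelled fat, or at least 70% non-tissue, are removed;
whole segments with median UMI below 200 are removed (low-quality segments
of that depth do not support clustering). `label_tls_spots()` marks spots
inside TLS hulls and expands `TLS_neighbor` labels by breadth-first search
on the hex adjacency ((|Δrow|, |Δcol|) ∈ {(0,2), (1,1)}) to depth 2.
"Within 2 spots" is implemented as graph depth, not a 150 µm metric
radius: two lattice steps at 100 µm spacing reach up to 200 µm, so the
metric reading would truncate the second ring; the graph reading matches
how array-based neighbourhood tools behave.

## Pattern decomposition

The NMF (`fit_nmf()`) minimizes
`0.5 ||D - AP||²_F + alpha (||A||_1 + ||P||_1)` over non-negative factors
by multiplicative updates, on `D = log2(counts + 1)`, with `alpha = 0.01`.
Multiplicative updates keep the objective monotonically non-increasing
(asserted at every recorded iteration in the tests); three random restarts
guard against poor local minima, and the best final objective wins.
`P` rows are rescaled to maximum 1, the scale absorbed into `A`, so
pattern weights are comparable across patterns. This deterministic,
desk-scale factorization replaces a Bayesian sparse NMF with Gibbs
sampling: the downstream marker statistic depends only on `(A, P)`, not on
posterior uncertainty. `K` is a user parameter (the bundled analyses use
3 planted patterns; a typical tissue-scale run requests ~10 and keeps the
patterns that stabilize) — no automatic rank selection is attempted.

## The fractional-expression pattern-marker statistic

For gene g and pattern k, with `r_k = sum_j P_kj`:

* total reconstructed expression `T_g = sum_k A_gk r_k`;
* fractional expression `f_gk = A_gk r_k / T_g`, summing to 1 across
  patterns for every expressed gene.

Genes are stratified into tertiles of `T_g` (low / medium / high overall
expression), so each gene's fractions are compared against genes of
similar magnitude; strata with fewer than 5 genes merge into a neighbour.
Within each (stratum, pattern) cell, a gene is a **marker** of the pattern
when `f_gk > Q3 + 1.5 IQR` (the Tukey upper fence), and its robust score
is `z_gk = (f_gk - median) / (MAD + 1e-12)`. Because flags and scores are
computed per pattern independently, a gene with, say, `f = (0.45, 0.45,
0.10)` against a tight `~1/3` background is flagged in patterns 1 *and*
2 — the statistic's defining multi-marker property, verified by a
constructed test case. The number of strata and the fence are
configurable; tertiles-plus-Tukey is a deliberate, simple operating point
validated by recovery tests (F1 ≈ 1 on planted exclusive markers), not a
claim about any particular Bayesian NMF implementation.

## Module scores

`module_score()` is the standard bin-matched signature score: genes are
split into 24 equal-size bins by mean expression; each signature gene
contributes 100 control genes sampled from its bin (with replacement when
the bin is small; fixed seed); the spot score is the mean signature
expression minus the mean pooled-control expression. Control pools
exclude the signature genes themselves — with desk-scale gene universes a
signature can dominate its own bin, which would cancel the very signal
being scored. The score contract is transform-agnostic; the pipeline
scores `log2(CP10K + 1)` by default, while elevation-recovery tests score
`log2(counts + 1)`, the scale on which the generator plants its shift
(scaling by library size re-weights a log-scale shift through the +1
pseudocount). Duplicated signature genes are deduplicated; missing ones
dropped with a warning.

`pattern_vs_module()` reports the Pearson correlation between a pattern's
spot weights and the module score, its t-test p-value, and the regression
R² (= r²). `compare_tls_classes()` runs Kruskal–Wallis across spot classes
plus unadjusted pairwise Wilcoxon tests, excluding singleton classes.

## Preranked GSEA

`gsea_preranked()` ranks genes by a score (the marker `z` for one pattern)
and computes the weighted Kolmogorov–Smirnov enrichment statistic (weight
exponent 1). The null is gene-label permutation; the two-sided p-value is
`(1 + #{|ES_perm| >= |ES_obs|}) / (n_perm + 1)`, BH-adjusted across the
sets tested within one pattern. Sets with fewer than 3 represented genes
are skipped. The ES agrees with an independent implementation (`fgsea`)
to 1e-9 in a cross-check test, and the permutation p-values are calibrated
(null rejection at 5% within [0.03, 0.07] over 1000 simulations).

# The synthetic-data generator

The generator defines the study conditions; it is deliberately simple and
fully documented so that what the tests show — and do not show — is clear.

**Cell maps** (`generate_cell_map()`): 16 axis-aligned 1 mm² ROIs, 4 per
lesion class, with class-specific phenotype densities realized as
homogeneous Poisson point processes (e.g. Tregs at 5 / 10 / 60 / 25 cells
per mm² in normal / PanIN / PDAC / CP — a PDAC-enriched Treg compartment
with a 3–6× contrast, and lesions generally more T-cell-infiltrated than
normal tissue). Twenty TLS discs (radius 120 µm, 250 cells) are planted:
7 immature in PanIN ROIs, 7 mature in PDAC ROIs, 3 + 3 in CP. Immature
discs mix B and T cells uniformly; mature discs place a germinal-center
core (inner half-radius, 40% of cells, CD20+CD21+CD23+) inside a T-cell
annulus. Marker intensities are lognormal with positive markers at median
2.0, negative at 0.2, log-sd 0.4 — a clean bimodal panel the default
gating separates at ~98.5% accuracy.

**Spot data** (`generate_spot_data()`): an even-parity hex lattice
(30 × 40 by default, 100 µm spacing, 600 occupied spots) with 600 genes.
Mean log2 expression is `M = A_true P_true` with K = 3 planted patterns:
each gene has a lognormal overall magnitude (median 2, log-sd 0.5) and a
per-pattern share — marker genes put 85–95% of their loading in one
pattern; background genes spread roughly evenly. Marker status is thereby
independent of overall expression, so markers occur in every expression
stratum, as in real transcriptomes (the property the marker statistic's
stratification exists to exploit). Pattern 1 is TLS-coupled: supported on
Gaussian bumps around three TLS discs scattered across the lattice (so
the TLS + neighbourhood subset spans all pattern supports and the
factorization is identifiable from it); patterns 2–3 are smooth column
bands; all weights carry a 0.15 baseline floor so every spot has RNA.
Twelve of pattern 1's markers form the planted TLS signature, elevated by
`delta = 1` log2 unit in TLS spots. Counts are
`Poisson(s_j (2^M - 1))` with library factors
`s_j ~ LogNormal(0, 0.1)`; a negative-binomial option
(`dispersion`) and a noiseless mode are available. Poisson is the default
because recovery tests need a simple, exactly-known first moment.

**What this does not emulate**: segmentation errors, marker spillover and
batch effects, cell-shape and density anisotropy, pathologist boundary
judgment, spot deconvolution ambiguity, zero inflation and gene-gene
correlation beyond the factor model. Passing tests therefore demonstrate
that the implementations compute their definitions correctly and recover
structure under idealized noise — not that the defaults are optimal for
any particular real dataset.

# Numerical choices and degenerate inputs

* All randomness is seed-controlled; fixed seeds give bit-identical
  outputs (asserted for generators and both pipeline arms via output
  checksums).
* Tie-breaks are explicit: neighbour ties by smaller `cell_id`,
  equidistant lesion ties by region order (logged), gate ties by
  declaration order.
* Degenerate cases return documented values instead of errors where a
  value is meaningful: identical samples give p = 1; a zero denominator
  gives a missing ratio; a single-cell phenotype leaves its diagonal
  interaction entry missing (logged); an all-identical fractional
  expression stratum flags no markers (IQR = 0 with a strict inequality).
* NMF convergence: relative objective change below 1e-6, cap 5000
  iterations; epsilon guards (1e-12) in the update denominators and the
  MAD-based z.
* Problem sizes in the tests and the acceptance script — ~18,000 cells
  across 16 ROIs, 600 × 600 spot matrices, oracle checks up to 2000
  cells, 1000–2000 null simulations per calibration — were chosen so the
  full suite exercises every claim at the study's scale while remaining
  comfortable on a laptop.

# Limitations

* Aggregate detection depends on DBSCAN parameters; sparse or elongated
  aggregates outside the default operating point require retuning.
* The maturity call is a two-condition proxy; it cannot distinguish a true
  germinal center from any sufficiently interior clump of
  CD20+CD21+CD23+ cells.
* The NMF is a point estimate; pattern uncertainty is not quantified, and
  `K` must be supplied.
* Density-valley gating assumes the negative population is the densest
  mode per marker; panels where a marker is positive in a majority of
  cells need explicit thresholds.
* ROI-level tests treat ROIs as exchangeable units; patient-level
  clustering of ROIs is not modelled (a pooling flag exists, mixed models
  do not).
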