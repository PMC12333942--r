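# tlscape

Spatial analysis of immune organization around pancreatic lesions:
precursor lesions (PanIN), invasive tumor (PDAC), and chronic pancreatitis
(CP). The package is for computational biologists working with segmented
multiplexed-imaging cell tables and Visium-style spot expression who want
the full chain — phenotyping, densities, spatial interaction, tertiary
lymphoid structure (TLS) characterization, and latent expression
patterns — as tested, scriptable R functions, with a synthetic-data module
that plants ground truth so every stage is verifiable without any
download.

## What it computes

**Proteomic arm** (segmented cells with x/y in µm and marker intensities):

- marker gating after `asinh(x/5)` transform, with density-valley
  positivity thresholds robust to rare populations (e.g. Tregs gated
  CD3+CD4+FOXP3+PD1−);
- per-ROI phenotype densities (cells/mm²), CD8:Treg-style ratios, and
  two-sided Wilcoxon / Kruskal–Wallis tests (exact rank-sum enumeration
  for small tie-free groups), unadjusted as is conventional for density
  panels;
- interaction structure: `M[A][B]` = mean distance from each A cell to its
  nearest B cell (phenotypes under 1% abundance excluded), symmetrized
  into a network, plus top-2 nearest-neighbour contact matrices normalized
  by the dominant phenotype count;
- TLS: DBSCAN detection over lymphoid cells, convex-hull boundaries,
  lesion association by a 250 µm hull-to-boundary rule, composition, and
  maturity — mature iff ≥ 10 germinal-center B cells (CD20+CD21+CD23+)
  sit in the eroded hull interior.

**Transcriptomic arm** (gene × spot counts on a 100 µm hex lattice):

- spot QC (70% predominant-tissue labelling, fat removal, low-UMI segment
  exclusion) and TLS-neighbourhood labelling by depth-2 hex expansion;
- sparse NMF on `D = log2(counts + 1)`: minimize
  `½‖D − AP‖²_F + α(‖A‖₁ + ‖P‖₁)`, α = 0.01, multiplicative updates,
  best of 3 restarts;
- the fractional-expression pattern-marker statistic: with
  `r_k = Σ_j P_kj`, `T_g = Σ_k A_gk r_k`, and `f_gk = A_gk r_k / T_g`,
  genes are stratified into tertiles of `T_g` and flagged as markers of
  pattern k when `f_gk > Q3 + 1.5·IQR` within their stratum, scored by
  `z_gk = (f_gk − median)/MAD`. A gene can mark several patterns;
- bin-matched module scores for a TLS gene signature (24 expression bins,
  100 controls per gene), Pearson r / R² of pattern weights against the
  score, Kruskal–Wallis plus pairwise Wilcoxon across spot classes, and
  preranked permutation GSEA (weighted KS, gene-label permutations,
  BH across sets).

The methods vignette (`vignettes/spatial-immune-methods.Rmd`) documents
the models, parameter defaults with units, numerical choices, and what the
synthetic generator does and does not emulate.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
tissue:

```sh
Rscript analysis/01_simulate.R       # cell map + spot counts -> results/data/
Rscript analysis/02_proteomic.R      # densities, interactions, TLS -> results/proteomic/
Rscript analysis/03_transcriptomic.R # patterns, markers, scores -> results/transcriptomic/
```

Step 1 plants 16 ROIs (4 per lesion class), ~18,000 cells, 20 TLS discs
(immature near PanIN, mature near PDAC, both in CP), and a 600 × 600
spot matrix with 3 latent patterns, one coupled to three TLS discs.
Step 2 prints, among other tables:

```
== CD8:Treg density ratio by class ==
       CP    normal     PanIN      PDAC
 5.279830  3.250000 17.900000  2.659752

== TLS summary ==
         immature mature
  CP            3      3
  PanIN         7      0
  PDAC          0      7
```

i.e. the planted biology is recovered: the CD8:Treg balance is far more
favourable around PanIN (17.9) than PDAC (2.7) because the generator
plants a PDAC-enriched Treg compartment, and all 20 TLS are detected with
the correct maturity and lesion association. Step 3 prints:

```
TLS-coupled pattern: pattern_2
pattern weight vs module score: r = 0.883 (R^2 = 0.780, p = 2.24e-61)
pattern weights across spot classes: Kruskal-Wallis p = 1.76e-25
34 marker genes for the TLS-coupled pattern
```

the recovered TLS-coupled pattern's weights track the planted 12-gene
signature score spot by spot, and its marker set is essentially the
planted marker set (Jaccard ≈ 0.85).

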