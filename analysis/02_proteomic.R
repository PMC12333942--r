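#!/usr/bin/env Rscript
# Step 2 — proteomic (cell-map) arm.
#
# Phenotypes cells by marker gating, computes per-ROI immune densities with
# pairwise rank tests, builds the nearest-neighbour interaction network and
# top-2 contact matrices, and detects/associates/classifies TLS. Reads the
# files written by 01_simulate.R; writes tables + manifest under
# results/proteomic/.

suppressMessages(library(tlscape))

cells <- read.csv("results/data/cells/cells.csv")
regions <- read_regions_geojson("results/data/cells/regions.geojson")

res <- run_proteomic_arm(cells, regions, out_dir = "results/proteomic")

cat("\n== phenotype composition ==\n")
print(sort(table(res$cells$phenotype), decreasing = TRUE))

cat("\n== Treg density by lesion class (cells per mm^2) ==\n")
dens <- res$density
treg <- dens[dens$phenotype == "Treg", ]
print(tapply(treg$density, treg$tissue_class, median))

cat("\n== significant pairwise density differences (p <= 0.05) ==\n")
sig <- res$density_tests[res$density_tests$p_value <= 0.05, ]
print(sig[order(sig$p_value), ], row.names = FALSE)

cat("\n== CD8:Treg density ratio by class ==\n")
ratio <- density_ratio(dens, "T_CD8_cytotoxic", "Treg")
cls <- dens$tissue_class[match(ratio$region_id, dens$region_id)]
print(tapply(ratio$ratio, cls, median, na.rm = TRUE))

cat("\n== TLS summary ==\n")
print(table(res$tls_table$lesion_class, res$tls_table$maturity))
cat(sprintf("\n%d TLS detected; tables in results/proteomic/\n",
            nrow(res$tls_table)))
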