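#!/usr/bin/env Rscript
# Step 1 — simulate the study tissue.
#
# Generates (a) a multiplexed-imaging-style cell map: 16 ROIs (4 per lesion
# class: normal, PanIN, PDAC, CP) with class-specific immune densities and
# 20 planted TLS discs (immature near PanIN, mature near PDAC, both in CP);
# (b) a Visium-style hex-lattice count matrix with 3 planted expression
# patterns, one coupled to three TLS discs, and a 12-gene TLS signature
# elevated by 1 log2 unit in TLS spots. Everything downstream reads these
# files, so the whole workflow is reproducible from this seed.

suppressMessages(library(tlscape))

seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cell_sim <- generate_cell_map(tissue_sim_config(seed = seed))
write_cell_map(cell_sim, file.path(out, "cells"))
cat(sprintf("cell map: %d cells in %d ROIs, %d planted TLS (%d mature)\n",
            nrow(cell_sim$cells), length(cell_sim$regions),
            nrow(cell_sim$truth$tls),
            sum(cell_sim$truth$tls$maturity == "mature")))

spot_sim <- generate_spot_data(visium_sim_config(seed = seed + 1))
write_spot_data(spot_sim, file.path(out, "spots"))
cat(sprintf("spot data: %d genes x %d spots, %d TLS spots, %d signature genes\n",
            nrow(spot_sim$spots$counts), ncol(spot_sim$spots$counts),
            length(spot_sim$truth$tls_spots),
            length(spot_sim$truth$signature_genes)))
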