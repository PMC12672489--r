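#!/usr/bin/env Rscript
# Step 1: simulate the survey inputs.
#
# Generates the synthetic counterpart of the field campaign: a 10-pattern x
# 3-plot soil indicator table (20 indicators whose correlation structure
# follows the packaged reference PCA solution) and matching tree
# inventories with plot metadata and allometric coefficients. All later
# steps read only the CSV files written here.

suppressPackageStartupMessages(library(soilqualkit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 20103
dir.create("results", showWarnings = FALSE)

soil <- generate_indicator_table(reference_factor_spec(seed = seed))
write_indicator_table(soil, "results/soil_indicators.csv")

sim <- generate_inventory(stand_sim_spec(seed = seed,
                                         trees_per_plot = 80,
                                         broadleaf_fraction = 0.6))
write.csv(sim$inventory, "results/tree_inventory.csv", row.names = FALSE)
write.csv(sim$plot_meta, "results/plot_meta.csv", row.names = FALSE)
write.csv(sim$coefs, "results/allometric_coefs.csv", row.names = FALSE)

cat(sprintf("simulated %d soil samples (%d patterns x %d plots, %d indicators)\n",
            nrow(soil), length(unique(soil$pattern_id)),
            nrow(soil) / length(unique(soil$pattern_id)),
            ncol(indicator_matrix(soil))))
cat(sprintf("simulated %d trees over %d plots (seed %d)\n",
            nrow(sim$inventory), nrow(sim$plot_meta), seed))
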