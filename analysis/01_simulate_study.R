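#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study feature table.
#
# Emulates the culturing design behind the pipeline: 15 endophyte strains
# (4 highbush, 11 wild blueberry) x 2 media (ML, PDB) x 2 extract matrices
# (filtrate, mycelium) = 60 samples over 3856 aligned LC-MS features, with
# 30 planted discriminant markers per contrast (medium, host-within-ML,
# host-within-PDB). Writes the feature/metadata CSVs and the ground truth.

suppressPackageStartupMessages(library(cyclometab))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- study_design(seed = seed)
sim <- simulate_study(design)

paths <- write_feature_table(sim$table, file.path(out_dir, "study"))
utils::write.csv(sim$truth, file.path(out_dir, "ground_truth.csv"),
                 row.names = FALSE)

cat(sprintf("simulated %d features x %d samples (seed %d)\n",
            nrow(sim$table$features), nrow(sim$table$samples), seed))
cat(sprintf("planted %d markers per contrast (%s)\n",
            sum(sim$truth$contrast == "medium"),
            paste(unique(sim$truth$contrast), collapse = ", ")))
cat("wrote:", paths["features"], paths["metadata"], "\n")
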