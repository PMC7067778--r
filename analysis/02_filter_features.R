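#!/usr/bin/env Rscript
# Stage 2: derive the final metabolite feature lists.
#
# Splits the study table by extract matrix, then removes isotope-flagged
# features, features whose maximum integrated area falls under 10,000, and
# (for the mycelium metabolome only) features eluting after 25 min.

suppressPackageStartupMessages(library(cyclometab))

in_dir <- "results/simulated"
out_dir <- "results/filtered"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tab <- read_feature_table(file.path(in_dir, "study_features.csv"),
                          file.path(in_dir, "study_metadata.csv"))
cat(sprintf("read %d features x %d samples\n", nrow(tab$features),
            nrow(tab$samples)))

for (part in split_by_matrix(tab)) {
  matrix_level <- part$samples$matrix[1]
  filtered <- filter_features(part, area_min = 10000, mycelium_rt_max = 25)
  cat(sprintf("%s: %d -> %d features\n", matrix_level,
              nrow(part$features), nrow(filtered$features)))
  write_feature_table(filtered, file.path(out_dir, matrix_level))
}
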