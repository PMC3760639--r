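#!/usr/bin/env Rscript
# Step 1 — simulate the paired study.
#
# Generates the ground-truth probe table and, from it, the two input data
# sets the downstream analyses consume: a triplicate two-channel slide set
# (4 replicate spots per probe, Hy3 = exosome, Hy5 = cell) and a
# single-channel expression study (4 arrays per compartment with P/M/A
# calls). Everything is written as tab-delimited text under results/simdata/.

suppressPackageStartupMessages(library(exocargo))

out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260920L)
truth <- generate_truth(cfg)
slides <- simulate_two_channel_slides(truth, cfg)
study <- simulate_expression_study(truth, cfg)

write_truth_table(truth, file.path(out, "truth.tsv"))
write_slide_set(slides, file.path(out, "slides.tsv"))
write_expression_study(study, file.path(out, "signals.tsv"),
                       file.path(out, "calls.tsv"), file.path(out, "groups.tsv"))

cls <- table(truth$compartment_class)
cat("Simulated", nrow(truth), "probes:",
    paste(names(cls), as.integer(cls), collapse = ", "), "\n")
cat("Slide set:", nrow(slides), "spots across", cfg$n_slides, "slides\n")
cat("Expression study:", ncol(study$signals), "arrays (",
    sum(study$groups$group == "exosome"), "exosome /",
    sum(study$groups$group == "cell"), "cell )\n")
cat("Inputs written under", out, "\n")
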