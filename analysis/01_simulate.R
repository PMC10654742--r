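#!/usr/bin/env Rscript
# Simulate the study cohort: 16 healthy controls (baseline only) and 33
# preclinical patients (19 stable / 14 evolving, paired baseline and
# 4-year follow-up samples), 200 pathways over 4000 genes, with 20
# pathways carrying a baseline disease effect and 15 a follow-up
# progression effect. Writes the raw inputs every later step consumes.

suppressMessages(library(pathsig))

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec(seed = 1)
sets <- generate_gene_sets(spec)
sim <- generate_cohort(spec, sets)

write_count_matrix(sim$counts, file.path(out, "counts.tsv"),
                   file.path(out, "metadata.tsv"))
write_gene_sets(sets, file.path(out, "sets.gmt"))
write_hierarchy(sets$hierarchy, file.path(out, "hierarchy.tsv"))
jsonlite::write_json(sim$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

md <- sim$counts$metadata
cat(sprintf("cohort: %d samples (%d HC, %d patient baseline, %d follow-up)\n",
            nrow(md), sum(md$group == "HC"),
            sum(md$group == "PreSSc" & md$timepoint == "baseline"),
            sum(md$timepoint == "followup")))
cat(sprintf("gene sets: %d pathways, %d root categories\n",
            length(sets$sets), length(unique(sets$hierarchy))))
cat(sprintf("truth: %d affected, %d progression pathways\n",
            length(sim$truth$affected), length(sim$truth$progression)))
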