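#!/usr/bin/env Rscript
# Low-expression filtering (genes with CPM > 1 in at least two samples),
# median-of-ratios size factors, and log2 normalization.

suppressMessages(library(pathsig))

cm <- read_count_matrix("results/simulated/counts.tsv",
                        "results/simulated/metadata.tsv")
expr <- preprocess_counts(cm, threshold = 1, min_samples = 2)
prov <- attr(expr, "provenance")

dir.create("results", showWarnings = FALSE)
utils::write.table(data.frame(gene = rownames(expr), expr,
                              check.names = FALSE),
                   "results/expr.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
jsonlite::write_json(
  list(n_genes_before = prov$n_before, n_genes_after = prov$n_after,
       size_factors = as.list(prov$size_factors)),
  "results/preprocess_provenance.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("kept %d of %d genes after the CPM filter\n",
            prov$n_after, prov$n_before))
cat(sprintf("size factors span %.3f-%.3f\n",
            min(prov$size_factors), max(prov$size_factors)))
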