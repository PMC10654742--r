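#!/usr/bin/env Rscript
# Single-sample FAIME pathway scoring: rank-exponential gene weights per
# sample, set-vs-complement score per pathway, plus the [-1, 1] view used
# for heat maps and clustering.

suppressMessages(library(pathsig))

tab <- utils::read.delim("results/expr.tsv", check.names = FALSE)
expr <- as.matrix(tab[, -1]); rownames(expr) <- tab[[1]]
sets <- read_gene_sets("results/simulated/sets.gmt")

scores <- score_matrix(expr, sets, min_genes = 5)
mm <- minmax_normalize(scores)

utils::write.table(data.frame(pathway = rownames(scores$scores),
                              scores$scores, check.names = FALSE),
                   "results/scores.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(data.frame(pathway = rownames(mm$scores), mm$scores,
                              check.names = FALSE),
                   "results/scores_minmax.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cat(sprintf("scored %d pathways x %d samples (mapped genes %d-%d)\n",
            nrow(scores$scores), ncol(scores$scores),
            min(scores$n_mapped), max(scores$n_mapped)))
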