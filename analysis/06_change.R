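#!/usr/bin/env Rscript
# Longitudinal change analysis: per pathway, the follow-up minus baseline
# score change of each patient is regressed on outcome (evolving vs
# stable), adjusting for the baseline score and the baseline clinical
# cluster; then root-category enrichment of the change-associated
# pathways and pre/post group means for the strongest hit.

suppressMessages(library(pathsig))

tab <- utils::read.delim("results/scores.tsv", check.names = FALSE)
scores <- as.matrix(tab[, -1]); rownames(scores) <- tab[[1]]
md <- utils::read.delim("results/simulated/metadata.tsv")
clusters <- utils::read.delim("results/clusters.tsv")
roots_tab <- utils::read.delim("results/roots.tsv")
truth <- jsonlite::read_json("results/simulated/truth.json",
                             simplifyVector = TRUE)

pat <- md$group == "PreSSc"
pre_ids <- md$sample_id[pat & md$timepoint == "baseline"]
post_ids <- md$sample_id[pat & md$timepoint == "followup"]
pre <- scores[, pre_ids]
post <- scores[, post_ids]
colnames(pre) <- md$subject_id[match(pre_ids, md$sample_id)]
colnames(post) <- md$subject_id[match(post_ids, md$sample_id)]
outcome <- md$outcome[match(pre_ids, md$sample_id)]
cl <- clusters$cluster[match(pre_ids, clusters$sample_id)]

change <- ancova_change_table(pre, post, outcome, clusters = cl)
utils::write.table(format(as.data.frame(change), digits = 10),
                   "results/change.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
called <- change$pathway[change$significant]
cat(sprintf("change analysis: %d of %d pathways associated with progression (q<0.05)\n",
            length(called), nrow(change)))
cat(sprintf("  recovery vs truth: sensitivity %.2f, FDP %.2f\n",
            mean(truth$progression %in% called),
            if (length(called)) mean(!(called %in% truth$progression)) else 0))

roots <- setNames(roots_tab$root, roots_tab$pathway)
sig <- setNames(change$significant, change$pathway)
target <- names(which.max(table(roots[names(sig)[sig]])))
enr <- root_enrichment(sig, roots, target)
cat(sprintf("root '%s': %.0f%% of significant vs %.0f%% of other pathways (chi-square p = %.3f)\n",
            target, 100 * enr$prop_significant,
            100 * enr$prop_nonsignificant, enr$p))
utils::write.table(as.data.frame(enr$table), "results/root_enrichment.tsv",
                   sep = "\t", quote = FALSE)

top <- change$pathway[which.min(change$q)]
m <- pre_post_group_means(pre, post, outcome, top)
cat(sprintf("top pathway %s: stable %.3f -> %.3f; evolving %.3f -> %.3f\n",
            top, m["stable_pre"], m["stable_post"],
            m["evolving_pre"], m["evolving_post"]))
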