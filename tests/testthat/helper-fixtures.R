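# Small fixtures built in code, shared across test files.

toy_metadata <- function(sample_ids, groups,
                         outcomes = ifelse(groups == "HC", "none", "stable"),
                         timepoints = rep("baseline", length(sample_ids)),
                         subjects = sample_ids) {
  data.frame(sample_id = sample_ids, subject_id = subjects, group = groups,
             outcome = outcomes, timepoint = timepoints,
             stringsAsFactors = FALSE)
}

toy_counts <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# A tiny cohort used by several modules: 6 HC + 6 patients, 8 genes.
tiny_cohort <- function(seed = 11) {
  set.seed(seed)
  genes <- paste0("g", 1:8)
  samples <- c(paste0("h", 1:6), paste0("p", 1:6))
  counts <- matrix(rpois(96, 50), nrow = 8,
                   dimnames = list(genes, samples))
  md <- toy_metadata(samples, rep(c("HC", "PreSSc"), each = 6))
  count_matrix(counts, md)
}

write_gmt_lines <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# Default-size synthetic cohort scored end to end; cached per seed within a
# test run since several tests share it.
scored_cohort <- local({
  cache <- list()
  function(seed = 0, ...) {
    key <- paste(seed, ..., sep = "_")
    if (is.null(cache[[key]])) {
      spec <- synthetic_spec(seed = seed, ...)
      sets <- generate_gene_sets(spec)
      sim <- generate_cohort(spec, sets)
      expr <- preprocess_counts(sim$counts)
      sc <- suppressMessages(score_matrix(expr, sets))
      cache[[key]] <<- list(spec = spec, sets = sets, counts = sim$counts,
                            truth = sim$truth, expr = expr, scores = sc,
                            metadata = sim$counts$metadata)
    }
    cache[[key]]
  }
})
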