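#' Build a validated pipeline configuration
#'
#' Either `paths` (counts, metadata, gmt, optional hierarchy) or `simulate`
#' (arguments for [synthetic_spec()]) must be given, not neither. Stage
#' parameters default to the pipeline's standard analysis settings.
#'
#' @param paths named list: `counts`, `metadata`, `gmt`, optional
#'   `hierarchy`.
#' @param simulate named list of [synthetic_spec()] arguments.
#' @param params named list overriding stage parameters: `cpm_threshold`,
#'   `min_samples`, `min_genes`, `gamma`, `alpha`, `dr_threshold`,
#'   `k_clusters`, `cv_runs`, `cv_folds`, `seed`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(paths = NULL, simulate = NULL, params = list()) {
  if (is.null(paths) && is.null(simulate))
    stop("either data paths or a simulate block is required")
  if (!is.null(paths)) {
    need <- c("counts", "metadata", "gmt")
    missing <- setdiff(need, names(paths))
    if (length(missing) > 0)
      stop("paths lacks: ", paste(missing, collapse = ", "))
  }
  defaults <- list(cpm_threshold = 1, min_samples = 2, min_genes = 5,
                   gamma = 0.2, alpha = 0.05, dr_threshold = 0.62897,
                   k_clusters = 4, cv_runs = 20, cv_folds = 10, seed = 1L)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, params)
  stopifnot(p$gamma >= 0, p$gamma < 0.5, p$alpha > 0, p$alpha < 1,
            p$min_genes >= 1, p$k_clusters >= 2, p$cv_runs >= 1,
            p$cv_folds >= 2)
  structure(list(paths = paths, simulate = simulate, params = p),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with optional `paths:`, `simulate:`, `params:`
#'   blocks.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(paths = y$paths, simulate = y$simulate,
                  params = if (is.null(y$params)) list() else y$params)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: preprocess (CPM filter, median-of-ratios, log2) ->
#' FAIME scoring -> baseline differential-pathway table (patients vs
#' controls) -> Ward clustering of baseline samples on the minmax view of
#' significant pathways (all pathways if none is significant) -> repeated
#' cross-validated classification -> ANCOVA change analysis of the paired
#' patient samples. All tables are written as TSV, reports as JSON, plus a
#' `manifest.json` recording versions, seeds, parameters, input hashes and
#' per-stage row counts; re-running with the same config reproduces every
#' output bit-for-bit.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  manifest <- list(
    package = as.character(utils::packageVersion("pathsig")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    params = p, stages = list())
  truth <- NULL

  if (!is.null(config$simulate)) {
    spec <- do.call(synthetic_spec, config$simulate)
    sets <- generate_gene_sets(spec)
    sim <- generate_cohort(spec, sets)
    cm <- sim$counts
    truth <- sim$truth
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$simulate <- unclass(spec)
  } else {
    cm <- read_count_matrix(config$paths$counts, config$paths$metadata)
    sets <- read_gene_sets(config$paths$gmt)
    if (!is.null(config$paths$hierarchy))
      sets$hierarchy <- read_hierarchy(config$paths$hierarchy)
    manifest$input_md5 <- as.list(tools::md5sum(unlist(config$paths)))
  }

  # preprocess
  expr <- preprocess_counts(cm, p$cpm_threshold, p$min_samples)
  prov <- attr(expr, "provenance")
  utils::write.table(
    data.frame(gene = rownames(expr), expr, check.names = FALSE),
    file.path(out_dir, "expr.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  manifest$stages$preprocess <- list(
    n_genes_before = prov$n_before, n_genes_after = prov$n_after,
    size_factors = as.list(round(prov$size_factors, 6)))

  # FAIME scoring
  scores <- score_matrix(expr, sets, min_genes = p$min_genes)
  utils::write.table(
    data.frame(pathway = rownames(scores$scores), scores$scores,
               check.names = FALSE),
    file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  manifest$stages$score <- list(n_pathways = nrow(scores$scores))

  md <- cm$metadata
  base <- md$timepoint == "baseline"
  base_ids <- md$sample_id[base]

  # baseline differential pathways
  dep <- dep_table(scores$scores[, base_ids, drop = FALSE],
                   md$group[base], gamma = p$gamma, alpha = p$alpha,
                   dr_threshold = p$dr_threshold)
  utils::write.table(format(dep, digits = 10),
                     file.path(out_dir, "dep.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$dep <- list(n_tested = nrow(dep),
                              n_significant = sum(dep$significant))

  # clustering on the visualization view of the significant pathways
  sig_ids <- dep$pathway[dep$significant]
  if (length(sig_ids) < 2) sig_ids <- dep$pathway
  mm <- minmax_normalize(scores)
  cl <- ward_clusters(mm$scores[sig_ids, base_ids, drop = FALSE],
                      k = min(p$k_clusters, length(base_ids)))
  comp <- cluster_composition(cl$assignment, md)
  utils::write.table(
    data.frame(sample_id = names(cl$assignment), cluster = cl$assignment),
    file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  manifest$stages$cluster <- list(k = cl$k,
                                  composition = lapply(seq_len(nrow(comp)),
                                                       function(i) as.list(comp[i, ])))

  # cross-validated baseline classification
  cv <- repeated_cv_classifier(scores$scores[, base_ids, drop = FALSE],
                               md$group[base], runs = p$cv_runs,
                               folds = p$cv_folds, seed = p$seed,
                               gamma = p$gamma, alpha = p$alpha,
                               dr_threshold = p$dr_threshold)
  jsonlite::write_json(
    list(design = cv$design, mean_auroc = cv$mean_auroc,
         sd_auroc = cv$sd_auroc, n_skipped = cv$n_skipped,
         auroc = cv$auroc),
    file.path(out_dir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  manifest$stages$classify <- list(mean_auroc = cv$mean_auroc,
                                   sd_auroc = cv$sd_auroc)

  # ANCOVA change analysis on paired patients
  pat <- md$group == "PreSSc"
  pre_ids <- md$sample_id[pat & md$timepoint == "baseline"]
  post_ids <- md$sample_id[pat & md$timepoint == "followup"]
  change <- NULL
  if (length(post_ids) > 0) {
    subj_pre <- md$subject_id[match(pre_ids, md$sample_id)]
    subj_post <- md$subject_id[match(post_ids, md$sample_id)]
    pre_m <- scores$scores[, pre_ids, drop = FALSE]
    post_m <- scores$scores[, post_ids, drop = FALSE]
    colnames(pre_m) <- subj_pre
    colnames(post_m) <- subj_post
    post_m <- post_m[, subj_pre, drop = FALSE]
    outcome <- md$outcome[match(pre_ids, md$sample_id)]
    clusters <- cl$assignment[pre_ids]
    change <- ancova_change_table(pre_m, post_m, outcome,
                                  clusters = clusters, alpha = p$alpha)
    utils::write.table(format(as.data.frame(change), digits = 10),
                       file.path(out_dir, "change.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$change <- list(n_tested = nrow(change),
                                   n_significant = sum(change$significant))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(counts = cm, sets = sets, expr = expr, scores = scores,
                 dep = dep, clusters = cl, composition = comp, cv = cv,
                 change = change, truth = truth, manifest = manifest))
}
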