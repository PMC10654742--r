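#' Specification of a synthetic blood-transcriptome cohort
#'
#' Describes a two-group (healthy control vs preclinical patient) cohort
#' with paired baseline/follow-up sampling for the patients, pathway-level
#' group effects at baseline and progression effects at follow-up, on a
#' negative-binomial count model. The defaults mirror the study design the
#' pipeline targets: 16 controls and 33 patients (19 stable, 14 evolving),
#' 200 pathways over 4000 genes.
#'
#' @param n_genes size of the gene universe.
#' @param n_hc number of healthy controls (baseline sample only).
#' @param n_stable,n_evolving numbers of patients with a stable / evolving
#'   4-year outcome; every patient has a baseline and a follow-up sample.
#' @param n_pathways number of gene sets to simulate.
#' @param size_range inclusive range of pathway sizes (must be >= 5 so sets
#'   survive the downstream minimum-gene rule).
#' @param n_roots number of root categories in the synthetic hierarchy.
#' @param n_affected number of pathways carrying a baseline patient-vs-control
#'   effect.
#' @param delta_baseline magnitude of the log2 shift applied to
#'   affected-pathway genes in every patient sample; its sign alternates
#'   across affected pathways (recorded in the truth record), mirroring the
#'   mix of up- and down-regulated pathways in real cohorts and keeping the
#'   within-sample rank distribution balanced (the scoring statistic is
#'   competitive, so a one-sided shift would displace every other gene's
#'   rank).
#' @param n_progression number of pathways whose expression shifts at
#'   follow-up in evolving patients only.
#' @param delta_progression magnitude of the follow-up log2 shift; its sign
#'   alternates across progression pathways (recorded in the truth record).
#' @param nb_dispersion negative-binomial dispersion (so `size = 1/dispersion`).
#' @param lib_meanlog,lib_sdlog log-normal parameters of the per-sample
#'   library scale factor.
#' @param base_mean,base_sd normal parameters of the gene baseline log2 mean.
#' @param seed integer seed; all generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 4000, n_hc = 16, n_stable = 19,
                           n_evolving = 14, n_pathways = 200,
                           size_range = c(8, 60), n_roots = 18,
                           n_affected = 20, delta_baseline = 1.0,
                           n_progression = 15, delta_progression = 1.0,
                           nb_dispersion = 0.2,
                           lib_meanlog = 0, lib_sdlog = 0.25,
                           base_mean = 5, base_sd = 2, seed = 1L) {
  spec <- list(n_genes = n_genes, n_hc = n_hc, n_stable = n_stable,
               n_evolving = n_evolving, n_pathways = n_pathways,
               size_range = size_range, n_roots = n_roots,
               n_affected = n_affected, delta_baseline = delta_baseline,
               n_progression = n_progression,
               delta_progression = delta_progression,
               nb_dispersion = nb_dispersion,
               lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
               base_mean = base_mean, base_sd = base_sd,
               seed = as.integer(seed))
  pos <- c("n_genes", "n_hc", "n_stable", "n_evolving", "n_pathways",
           "nb_dispersion")
  for (f in pos)
    if (spec[[f]] <= 0) stop(f, " must be positive")
  if (spec$n_affected < 0 || spec$n_progression < 0)
    stop("effect pathway counts must be nonnegative")
  if (spec$n_affected + spec$n_progression > spec$n_pathways)
    stop("n_affected + n_progression exceeds n_pathways")
  if (length(size_range) != 2 || size_range[1] > size_range[2])
    stop("size_range must be an increasing pair")
  if (size_range[1] < 5)
    stop("pathway sizes must be >= 5 to survive the minimum-gene rule")
  if (n_genes < size_range[2])
    stop("gene universe smaller than the maximum pathway size")
  structure(spec, class = "synthetic_spec")
}

# Alternate effect signs across pathways, greedily balancing the total
# number of up- vs down-shifted genes (largest sets first). The scoring
# statistic downstream is competitive in ranks, so an unbalanced shift
# would leak signal into every unaffected pathway and blur the truth.
balance_signs <- function(sizes) {
  sign <- stats::setNames(numeric(length(sizes)), names(sizes))
  up <- 0; down <- 0
  for (i in order(sizes, decreasing = TRUE)) {
    if (up <= down) { sign[i] <- 1; up <- up + sizes[i] }
    else { sign[i] <- -1; down <- down + sizes[i] }
  }
  sign
}

# Run `expr` under a private Mersenne-Twister stream, restoring the caller's
# RNG state afterwards. Every stochastic piece of the generator goes through
# this so results are reproducible from the spec alone.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Generate synthetic gene sets with a root hierarchy
#'
#' Pathway membership is drawn from a universe of `n_genes` synthetic gene
#' symbols. The pathways earmarked for injected effects (the first
#' `n_affected + n_progression`, before shuffling of ids) are drawn from a
#' reserved block of the universe and are mutually disjoint, so the ground
#' truth of which pathways carry signal is unambiguous; the remaining
#' pathways may overlap freely within the rest of the universe. Every
#' pathway is assigned to one of `n_roots` synthetic root categories.
#'
#' @param spec a [synthetic_spec()].
#' @return A [gene_set_collection()] with an attached hierarchy; the ids of
#'   the disjoint (effect-eligible) pathways are stored in
#'   `attr(x, "effect_pool")`.
#' @export
generate_gene_sets <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("G%05d", seq_len(spec$n_genes))
    sizes <- sample(seq(spec$size_range[1], spec$size_range[2]),
                    spec$n_pathways, replace = TRUE)
    n_eff <- spec$n_affected + spec$n_progression
    if (sum(sizes[seq_len(n_eff)]) >= spec$n_genes)
      stop("gene universe too small for disjoint effect pathways")
    sets <- vector("list", spec$n_pathways)
    # reserved, pairwise-disjoint block for effect-eligible pathways
    pool <- sample(genes)
    used <- 0L
    for (i in seq_len(n_eff)) {
      sets[[i]] <- sort(pool[(used + 1L):(used + sizes[i])])
      used <- used + sizes[i]
    }
    rest <- pool[-seq_len(used)]
    for (i in setdiff(seq_len(spec$n_pathways), seq_len(n_eff))) {
      if (sizes[i] > length(rest)) stop("infeasible pathway size range")
      sets[[i]] <- sort(sample(rest, sizes[i]))
    }
    ids <- sprintf("PW%04d", seq_len(spec$n_pathways))
    names(sets) <- ids
    roots <- sprintf("ROOT%02d", seq_len(spec$n_roots))
    # every root represented at least once, remainder assigned at random
    assignment <- c(roots[seq_len(min(spec$n_roots, spec$n_pathways))],
                    sample(roots, max(0L, spec$n_pathways - spec$n_roots),
                           replace = TRUE))
    assignment <- sample(assignment)  # decouple root from pathway index
    hierarchy <- stats::setNames(assignment[seq_len(spec$n_pathways)], ids)
    out <- gene_set_collection(sets, hierarchy = NULL)
    # roots are category labels, not set ids, so bypass the known-id check
    out$hierarchy <- hierarchy
    attr(out, "effect_pool") <- ids[seq_len(n_eff)]
    out
  })
}

#' Generate a synthetic paired cohort of counts with known truth
#'
#' Counts are negative binomial with mean `mu_gs = 2^(b_g + delta_gs) * L_s`
#' where `b_g` is the gene baseline log2 mean, `L_s` a log-normal library
#' factor, and `delta_gs` collects the injected effects: a signed
#' `delta_baseline` for affected-pathway genes in every patient sample, plus
#' a signed `delta_progression` for progression-pathway genes in follow-up
#' samples of evolving patients (both signs alternate per pathway and are
#' recorded in the truth record). Stable
#' patients' follow-up samples are fresh draws from their baseline
#' distribution. Controls have baseline samples only.
#'
#' @param spec a [synthetic_spec()].
#' @param sets a [gene_set_collection()] from [generate_gene_sets()].
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (affected pathway ids, progression pathway ids with signs, parameters).
#' @export
generate_cohort <- function(spec, sets) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(sets, "gene_set_collection"))
  genes <- sort(unique(unlist(sets$sets, use.names = FALSE)))
  all_genes <- sprintf("G%05d", seq_len(spec$n_genes))
  if (!all(genes %in% all_genes))
    stop("gene sets reference genes outside the spec universe")
  with_seed(spec$seed + 1L, {
    pool <- attr(sets, "effect_pool")
    if (is.null(pool)) pool <- names(sets$sets)
    picked <- sample(pool, spec$n_affected + spec$n_progression)
    affected <- sort(picked[seq_len(spec$n_affected)])
    progression <- sort(picked[spec$n_affected + seq_len(spec$n_progression)])
    aff_sign <- balance_signs(lengths(sets$sets[affected]))
    prog_sign <- balance_signs(lengths(sets$sets[progression]))

    b <- stats::setNames(stats::rnorm(spec$n_genes, spec$base_mean, spec$base_sd),
                         all_genes)

    hc_ids <- sprintf("HC%02d", seq_len(spec$n_hc))
    pat <- sprintf("P%02d", seq_len(spec$n_stable + spec$n_evolving))
    outcome <- c(rep("stable", spec$n_stable), rep("evolving", spec$n_evolving))
    sample_id <- c(hc_ids, paste0(pat, "_B"), paste0(pat, "_F"))
    metadata <- data.frame(
      sample_id = sample_id,
      subject_id = c(hc_ids, pat, pat),
      group = c(rep("HC", spec$n_hc), rep("PreSSc", 2 * length(pat))),
      outcome = c(rep("none", spec$n_hc), outcome, outcome),
      timepoint = c(rep("baseline", spec$n_hc + length(pat)),
                    rep("followup", length(pat))),
      stringsAsFactors = FALSE)

    n_samp <- nrow(metadata)
    L <- stats::rlnorm(n_samp, spec$lib_meanlog, spec$lib_sdlog)
    counts <- matrix(0, nrow = spec$n_genes, ncol = n_samp,
                     dimnames = list(all_genes, metadata$sample_id))
    size <- 1 / spec$nb_dispersion
    for (j in seq_len(n_samp)) {
      delta <- numeric(spec$n_genes)
      names(delta) <- all_genes
      if (metadata$group[j] == "PreSSc") {
        for (pw in affected) {
          g <- sets$sets[[pw]]
          delta[g] <- delta[g] + aff_sign[[pw]] * spec$delta_baseline
        }
      }
      if (metadata$timepoint[j] == "followup" &&
          metadata$outcome[j] == "evolving") {
        for (pw in progression) {
          g <- sets$sets[[pw]]
          delta[g] <- delta[g] + prog_sign[[pw]] * spec$delta_progression
        }
      }
      mu <- 2^(b + delta) * L[j]
      counts[, j] <- stats::rnbinom(spec$n_genes, size = size, mu = mu)
    }
    truth <- list(affected = affected, progression = progression,
                  affected_sign = aff_sign, progression_sign = prog_sign,
                  seed = spec$seed, spec = unclass(spec))
    list(counts = count_matrix(counts, metadata), truth = truth)
  })
}
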