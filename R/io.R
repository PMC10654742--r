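#' Construct and validate a count matrix with sample metadata
#'
#' The central input container of the pipeline: a genes x samples matrix of
#' raw, nonnegative integer counts together with per-sample metadata. The
#' metadata must carry `sample_id`, `subject_id`, `group` (HC / PreSSc),
#' `outcome` (stable / evolving / none) and `timepoint` (baseline /
#' followup); any further columns are treated as clinical covariates.
#'
#' Invariants enforced here: counts are nonnegative integers; gene symbols
#' and sample ids are unique; every count column has a metadata row; healthy
#' controls have outcome `none`; every followup sample's subject also owns a
#' baseline sample.
#'
#' @param counts integer matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param metadata data.frame of per-sample records (see Details).
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `metadata` (metadata reordered to match the count columns).
#' @export
count_matrix <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene symbols as rownames and sample ids as colnames")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- rownames(counts)[bad[1, 1]]; s <- colnames(counts)[bad[1, 2]]
    stop(sprintf("count for gene '%s', sample '%s' is not a nonnegative integer (%s)",
                 g, s, format(counts[bad[1, 1], bad[1, 2]])))
  }
  storage.mode(counts) <- "double"  # keeps exact integers, avoids overflow on sums
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene symbols: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  required <- c("sample_id", "subject_id", "group", "outcome", "timepoint")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols) > 0)
    stop("metadata lacks required columns: ", paste(missing_cols, collapse = ", "))
  absent <- setdiff(colnames(counts), metadata$sample_id)
  if (length(absent) > 0)
    stop("samples missing from metadata: ", paste(absent, collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL

  ok_group <- metadata$group %in% c("HC", "PreSSc")
  if (!all(ok_group))
    stop("unknown group label(s): ", paste(unique(metadata$group[!ok_group]), collapse = ", "))
  ok_out <- metadata$outcome %in% c("stable", "evolving", "none")
  if (!all(ok_out))
    stop("unknown outcome label(s): ", paste(unique(metadata$outcome[!ok_out]), collapse = ", "))
  ok_tp <- metadata$timepoint %in% c("baseline", "followup")
  if (!all(ok_tp))
    stop("unknown timepoint label(s): ", paste(unique(metadata$timepoint[!ok_tp]), collapse = ", "))
  hc_bad <- metadata$group == "HC" & metadata$outcome != "none"
  if (any(hc_bad))
    stop("HC samples must have outcome 'none': ",
         paste(metadata$sample_id[hc_bad], collapse = ", "))
  fu <- metadata$timepoint == "followup"
  base_subj <- metadata$subject_id[metadata$timepoint == "baseline"]
  orphan <- fu & !(metadata$subject_id %in% base_subj)
  if (any(orphan))
    stop("followup sample(s) without a baseline sample for the subject: ",
         paste(metadata$sample_id[orphan], collapse = ", "))

  structure(list(counts = counts, metadata = metadata), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d HC, %d PreSSc)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$metadata$group == "HC"), sum(x$metadata$group == "PreSSc")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a gene-set collection
#'
#' @param sets named list of unique gene-symbol character vectors, one per
#'   pathway id.
#' @param descriptions optional named character vector of display names.
#' @param hierarchy optional named character vector mapping child pathway id
#'   to parent pathway id; must be acyclic.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, hierarchy = NULL) {
  if (length(sets) == 0) stop("empty gene-set collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique pathway ids as names")
  sizes <- lengths(sets)
  if (any(sizes == 0))
    stop("empty gene set(s): ", paste(names(sets)[sizes == 0], collapse = ", "))
  dup_in <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dup_in))
    stop("duplicate genes within set(s): ", paste(names(sets)[dup_in], collapse = ", "))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  if (!is.null(hierarchy) && length(hierarchy) > 0) {
    unknown <- setdiff(names(hierarchy), names(sets))
    if (length(unknown) > 0)
      stop("hierarchy keys are not known pathway ids: ",
           paste(unknown, collapse = ", "))
    assert_acyclic(hierarchy)
  } else {
    hierarchy <- character(0)
  }
  structure(list(sets = sets, descriptions = descriptions, hierarchy = hierarchy),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d, %d hierarchy links\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              length(x$hierarchy)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

# Walk parent links; stop with one printed cycle if any node revisits itself.
assert_acyclic <- function(parent_of) {
  for (start in names(parent_of)) {
    seen <- character(0)
    node <- start
    while (node %in% names(parent_of)) {
      if (node %in% seen) {
        cyc <- c(seen[which(seen == node):length(seen)], node)
        stop("hierarchy contains a cycle: ", paste(cyc, collapse = " -> "))
      }
      seen <- c(seen, node)
      node <- unname(parent_of[[node]])
    }
  }
  invisible(TRUE)
}

default_symbol_regex <- "^[A-Za-z][A-Za-z0-9.-]*$"

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated, `id<TAB>description<TAB>`
#' then one gene symbol per field. Duplicate genes within a set are
#' de-duplicated. Tokens that do not look like official gene symbols
#' (by default: anything not matching `^[A-Za-z][A-Za-z0-9.-]*$`, which in
#' particular drops bare numeric database ids) are removed; the number of
#' dropped tokens is reported via `message()`.
#'
#' @param path GMT file path.
#' @param symbol_regex regular expression a token must match to be kept as a
#'   gene symbol; set to `NULL` to keep everything.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path, symbol_regex = default_symbol_regex) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  desc <- character(length(lines))
  dropped <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields", i))
    ids[i] <- fields[1]
    desc[i] <- fields[2]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!is.null(symbol_regex)) {
      keep <- grepl(symbol_regex, genes)
      dropped <- dropped + sum(!keep)
      genes <- genes[keep]
    }
    sets[[i]] <- genes
  }
  if (anyDuplicated(ids))
    stop("duplicate pathway id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sets) <- ids
  if (dropped > 0)
    message(sprintf("read_gene_sets: dropped %d token(s) without an official gene symbol", dropped))
  gene_set_collection(sets, descriptions = stats::setNames(desc, ids))
}

#' Write gene sets to a GMT file
#' @param x a [gene_set_collection()].
#' @param path output file path.
#' @export
write_gene_sets <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(id) {
    paste(c(id, x$descriptions[[id]], x$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a count matrix and its sample metadata from TSV files
#'
#' The counts file has a header row of sample ids; the first column holds
#' gene symbols (its header cell is ignored). The metadata file must contain
#' the columns `sample_id`, `subject_id`, `group`, `outcome`, `timepoint`.
#' All validation of [count_matrix()] applies; row and column order are
#' preserved.
#'
#' @param counts_path,metadata_path TSV file paths.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, metadata_path) {
  tab <- utils::read.delim(counts_path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           colClasses = "character")
  if (ncol(tab) < 2) stop("counts TSV needs a gene column plus >= 1 sample column")
  genes <- tab[[1]]
  num <- suppressWarnings(
    vapply(tab[-1], function(col) as.numeric(col), numeric(nrow(tab))))
  if (nrow(tab) == 1) num <- matrix(num, nrow = 1)
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count for gene '%s', sample '%s'",
                 genes[bad[1]], colnames(tab)[-1][bad[2]]))
  }
  counts <- matrix(num, nrow = nrow(tab),
                   dimnames = list(genes, colnames(tab)[-1]))
  metadata <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                                check.names = FALSE, quote = "",
                                stringsAsFactors = FALSE)
  count_matrix(counts, metadata)
}

#' Write a count matrix (and optionally its metadata) to TSV
#' @param x a [count_matrix()].
#' @param counts_path output TSV for the counts.
#' @param metadata_path optional output TSV for the metadata.
#' @export
write_count_matrix <- function(x, counts_path, metadata_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(x$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(counts_path)
}

#' Read a child-to-parent pathway hierarchy from TSV
#'
#' Two columns, `child_id` and `parent_id` (with or without a header line of
#' those names). Returns an acyclic named character vector mapping each
#' child to its parent; an empty file yields an empty map, in which case
#' every pathway is its own root.
#'
#' @param path TSV file path.
#' @return Named character vector (child -> parent).
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(character(0))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2))
    stop(sprintf("hierarchy format error at line %d: expected 2 tab-separated columns, found %d",
                 which(nf != 2)[1], nf[nf != 2][1]))
  if (identical(tolower(parts[[1]]), c("child_id", "parent_id")))
    parts <- parts[-1]
  if (length(parts) == 0) return(character(0))
  child <- vapply(parts, `[`, character(1), 1)
  parent <- vapply(parts, `[`, character(1), 2)
  if (anyDuplicated(child))
    stop("duplicate child id(s) in hierarchy: ",
         paste(unique(child[duplicated(child)]), collapse = ", "))
  map <- stats::setNames(parent, child)
  assert_acyclic(map)
  map
}

#' Write a child-to-parent hierarchy map to TSV
#' @param hierarchy named character vector (child -> parent).
#' @param path output file path.
#' @export
write_hierarchy <- function(hierarchy, path) {
  df <- data.frame(child_id = names(hierarchy), parent_id = unname(hierarchy),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
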