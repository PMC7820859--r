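#' Read a GMT gene set file
#'
#' GMT is the de-facto exchange format for gene set collections: one set
#' per line, tab-separated as `id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Trailing whitespace is tolerated; duplicate genes within a line are
#' removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()] preserving file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", lineno[bad[1]],
         ": fewer than 3 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate set id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(genes, anyDuplicated, 0L) > 0L)
  if (ndup > 0) {
    warning(ndup, " set(s) contained duplicate genes; duplicates removed")
    genes <- lapply(genes, unique)
  }
  names(genes) <- ids
  gene_set_collection(genes, desc)
}

#' Write a gene set collection to GMT
#'
#' @param collection A `GeneSetCollection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  desc <- attr(collection, "descriptions")
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], desc[i], collection[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter a collection by gene set size
#'
#' Retains sets whose size is within `[min_size, max_size]`, preserving
#' order. Defaults mirror the customary 5-500 restriction used when
#' benchmarking KEGG/GO collections.
#'
#' @param collection A `GeneSetCollection`.
#' @param min_size,max_size Inclusive size bounds.
#' @return The filtered collection; a warning is raised (not an error) if
#'   nothing survives.
#' @export
filter_by_size <- function(collection, min_size = 5L, max_size = 500L) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (min_size < 1L || min_size > max_size)
    stop("require 1 <= min_size <= max_size")
  sz <- lengths(collection)
  keep <- sz >= min_size & sz <= max_size
  if (!any(keep)) {
    warning("no gene sets within size range [", min_size, ", ", max_size, "]")
    return(gene_set_collection(stats::setNames(list(), character(0))[0]))
  }
  collection[keep]
}

#' Read a two-column relevance table
#'
#' Parses a TSV with columns `set_id` and non-negative `score`, with or
#' without a header line.
#'
#' @param path Path to the TSV.
#' @param phenotype Phenotype label attached to the result.
#' @return A [relevance_ranking()].
#' @export
read_relevance_table <- function(path, phenotype = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("relevance table has no rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("relevance table line ", which(lengths(fields) < 2L)[1],
         ": expected 2 tab-separated columns")
  start <- 1L
  if (length(fields) > 1L &&
      suppressWarnings(is.na(as.numeric(fields[[1]][2]))))
    start <- 2L  # header line
  fields <- fields[start:length(fields)]
  ids <- vapply(fields, `[[`, "", 1L)
  raw <- vapply(fields, `[[`, "", 2L)
  scores <- suppressWarnings(as.numeric(raw))
  if (anyNA(scores))
    stop("non-numeric relevance score at line ",
         which(is.na(scores))[1] + start - 1L, ": '", raw[is.na(scores)][1], "'")
  if (any(scores < 0))
    stop("negative relevance score at line ",
         which(scores < 0)[1] + start - 1L)
  relevance_ranking(stats::setNames(scores, ids), phenotype)
}

#' Write a relevance ranking as TSV
#' @param relevance A `RelevanceRanking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relevance_table <- function(relevance, path) {
  stopifnot(inherits(relevance, "RelevanceRanking"))
  df <- data.frame(set_id = names(relevance),
                   score = format(as.numeric(relevance), digits = 15,
                                  trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write an expression matrix as TSV
#'
#' The serialization is a plain TSV with gene ids in the first column
#' (named `gene_id`) and one column per sample. Group and block labels
#' travel in the scenario's `truth.json` (see [write_scenario()]), not in
#' the matrix file.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs gene_id plus >=1 sample column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_expression_matrix
#' @param matrix Numeric matrix with rownames and colnames.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a benchmark scenario to a directory
#'
#' Writes the triple the benchmark consumes -- expression matrix
#' (`matrix.tsv`), gene set collection (`sets.gmt`), relevance ranking
#' (`relevance.tsv`) -- plus `truth.json` recording sample metadata
#' (sample ids, groups, blocks, value kind) and the simulation ground
#' truth (DE genes, signed log2 effects, enriched sets, seed).
#'
#' @param dataset An `ExpressionDataset`.
#' @param collection A `GeneSetCollection`.
#' @param relevance A `RelevanceRanking`.
#' @param truth A `SimulationTruth` (or NULL for real data).
#' @param dir Output directory (created if needed).
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(dataset, collection, relevance, truth = NULL,
                           dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory exists and is non-empty (use force = TRUE): ", dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(dataset$matrix, file.path(dir, "matrix.tsv"))
  write_gmt(collection, file.path(dir, "sets.gmt"))
  write_relevance_table(relevance, file.path(dir, "relevance.tsv"))
  meta <- list(
    kind = dataset$kind,
    phenotype = attr(relevance, "phenotype"),
    samples = data.frame(sample_id = colnames(dataset$matrix),
                         group = as.character(dataset$groups),
                         block = if (is.null(dataset$blocks)) NA_character_
                                 else as.character(dataset$blocks),
                         stringsAsFactors = FALSE),
    truth = if (is.null(truth)) NULL else list(
      de_genes = truth$de_genes,
      effect_sizes = as.list(truth$effect_sizes),
      enriched_sets = truth$enriched_sets,
      seed = truth$seed,
      cor_blocks = truth$cor_blocks))
  jsonlite::write_json(meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  invisible(dir)
}

#' Load a scenario directory written by [write_scenario()]
#'
#' @param dir Scenario directory.
#' @return List with elements `dataset`, `collection`, `relevance`,
#'   `truth` (NULL when absent).
#' @export
read_scenario <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  m <- read_expression_matrix(file.path(dir, "matrix.tsv"))
  blocks <- meta$samples$block
  if (all(is.na(blocks))) blocks <- NULL
  ds <- expression_dataset(m[, meta$samples$sample_id, drop = FALSE],
                           groups = meta$samples$group, blocks = blocks,
                           kind = meta$kind)
  truth <- NULL
  if (!is.null(meta$truth)) {
    eff <- unlist(meta$truth$effect_sizes)
    truth <- .simulation_truth(meta$truth$de_genes, eff,
                               enriched_sets = meta$truth$enriched_sets %||% character(0),
                               seed = meta$truth$seed %||% NA_integer_,
                               cor_blocks = meta$truth$cor_blocks)
  }
  list(dataset = ds,
       collection = read_gmt(file.path(dir, "sets.gmt")),
       relevance = read_relevance_table(file.path(dir, "relevance.tsv"),
                                        phenotype = meta$phenotype %||% "scenario"),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
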