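#' Construct an expression dataset
#'
#' Bundles a genes x samples expression matrix with a binary grouping
#' vector, an optional blocking vector (pairing/batch), and a tag saying
#' what kind of values the matrix holds. All enrichment methods and
#' gene-level statistics in this package consume this container.
#'
#' @param matrix Numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids).
#' @param groups Binary group label per sample (character, factor or
#'   anything coercible); exactly two distinct values, each with at least
#'   two samples. The first level (order of appearance if not a factor)
#'   is the reference: statistics are reported as level1 minus level2.
#' @param blocks Optional label per sample encoding pairing or batch;
#'   permutations are restricted within blocks when present.
#' @param kind One of `"log_intensity"` (microarray-scale log values),
#'   `"counts"` (non-negative integer RNA-seq counts) or `"tpm"`.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `groups` (factor), `blocks` (factor or NULL), `kind`.
#' @examples
#' m <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' expression_dataset(m, groups = c("a", "a", "b", "b"))
#' @export
expression_dataset <- function(matrix,
                               groups,
                               blocks = NULL,
                               kind = c("log_intensity", "counts", "tpm")) {
  kind <- match.arg(kind)
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  gene_ids <- rownames(matrix)
  sample_ids <- colnames(matrix)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`matrix` must have rownames (gene ids) and colnames (sample ids)")
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                        collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids")
  if (length(groups) != ncol(matrix))
    stop("`groups` must have one label per sample")
  groups <- if (is.factor(groups)) droplevels(groups)
            else factor(as.character(groups), levels = unique(as.character(groups)))
  if (nlevels(groups) != 2L)
    stop("`groups` must take exactly two distinct values, got ",
         nlevels(groups))
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples")
  if (!is.null(blocks)) {
    if (length(blocks) != ncol(matrix))
      stop("`blocks` must have one label per sample")
    blocks <- factor(as.character(blocks))
  }
  if (anyNA(matrix)) stop("expression matrix contains missing values")
  if (kind == "counts") {
    if (any(matrix < 0) || any(matrix != round(matrix)))
      stop("kind = \"counts\" requires non-negative integer entries")
  }
  if (kind == "tpm" && any(matrix < 0))
    stop("kind = \"tpm\" requires non-negative entries")
  structure(list(matrix = matrix, groups = groups, blocks = blocks,
                 kind = kind),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$matrix), "genes x", ncol(x$matrix),
      "samples (", x$kind, ")\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", levels(x$groups),
                                 table(x$groups)), collapse = ", "), "\n")
  if (!is.null(x$blocks))
    cat("  blocks:", nlevels(x$blocks), "levels\n")
  invisible(x)
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors; names are set ids, values
#'   are member gene ids. Order is preserved.
#' @param descriptions Optional character vector of per-set descriptions,
#'   recycled to length of `sets`.
#' @return An object of class `GeneSetCollection`: the named list with a
#'   `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a named list of gene id vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicated set ids: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, as.character)
  if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
  dup <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dup))
    stop("duplicate genes within set(s): ",
         paste(names(sets)[dup], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sz <- lengths(x)
  cat("GeneSetCollection:", length(x), "sets")
  if (length(x))
    cat(", sizes", min(sz), "-", max(sz), "(median", stats::median(sz), ")")
  cat("\n")
  invisible(x)
}

#' @export
`[.GeneSetCollection` <- function(x, i) {
  gene_set_collection(unclass(x)[i], attr(x, "descriptions")[i])
}

#' Construct a phenotype relevance ranking
#'
#' An a-priori scoring of gene sets for relevance to a phenotype, the
#' reference against which enrichment-method rankings are benchmarked.
#' Scores are non-negative; larger means more relevant.
#'
#' @param scores Named non-negative numeric vector (names = set ids).
#' @param phenotype Free-text phenotype label.
#' @return Object of class `RelevanceRanking`.
#' @export
relevance_ranking <- function(scores, phenotype = "synthetic") {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("`scores` must be uniquely named by set id")
  scores <- stats::setNames(as.numeric(scores), names(scores))
  if (anyNA(scores) || any(scores < 0))
    stop("relevance scores must be non-negative")
  if (!any(scores > 0))
    stop("at least one relevance score must be positive")
  structure(scores, phenotype = phenotype, class = "RelevanceRanking")
}

#' @export
print.RelevanceRanking <- function(x, ...) {
  cat("RelevanceRanking (", attr(x, "phenotype"), "): ", length(x),
      " sets, score range [", min(x), ", ", max(x), "]\n", sep = "")
  invisible(x)
}

# Assemble an EARanking data.frame from per-set results. Rows are ordered
# by the deterministic ranking rule: p ascending, ties broken by |stat|
# descending, then set_id. The weight column follows the tie-aware
# rank-to-weight transformation applied to the p-values.
.make_ea_ranking <- function(set_id, size, statistic, p_value,
                             method, hypothesis) {
  stopifnot(length(set_id) == length(p_value))
  adj_p <- bh_adjust(p_value)
  ord <- order(p_value, -abs(statistic), set_id)
  rnk <- integer(length(ord))
  rnk[ord] <- seq_along(ord)
  w <- ranks_to_weights(p_value, orientation = "smaller")
  out <- data.frame(set_id = set_id, size = size, statistic = statistic,
                    p_value = p_value, adj_p = adj_p, rank = rnk,
                    weight = w, stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, method = method, hypothesis = hypothesis,
            n_sets = nrow(out),
            class = c("EARanking", "data.frame"))
}

#' @export
print.EARanking <- function(x, ...) {
  cat("EARanking:", attr(x, "method"), "(", attr(x, "hypothesis"), "),",
      attr(x, "n_sets"), "gene sets\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more sets\n")
  invisible(x)
}

#' Build a ranking from arbitrary per-set scores
#'
#' Wraps a named score vector as a minimal ranking object usable by the
#' relevance-scoring machinery, e.g. for oracle rankings that order sets
#' by their true differential-expression content.
#'
#' @param scores Named numeric vector of ranking statistics.
#' @param orientation `"larger"` if larger values rank higher (scores),
#'   `"smaller"` if smaller values rank higher (p-values).
#' @return Object of class `ScoreRanking`.
#' @export
score_ranking <- function(scores, orientation = c("larger", "smaller")) {
  orientation <- match.arg(orientation)
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("`scores` must be uniquely named by set id")
  structure(stats::setNames(as.numeric(scores), names(scores)),
            orientation = orientation, class = "ScoreRanking")
}

# Extract (values named by set id, orientation) from anything the
# relevance machinery accepts as a ranking.
.ranking_stat <- function(ranking) {
  if (inherits(ranking, "EARanking")) {
    list(values = stats::setNames(ranking$p_value, ranking$set_id),
         orientation = "smaller")
  } else if (inherits(ranking, "ScoreRanking")) {
    list(values = stats::setNames(as.numeric(ranking), names(ranking)),
         orientation = attr(ranking, "orientation"))
  } else {
    stop("`ranking` must be an EARanking or a score_ranking()")
  }
}

# Validated container for what the simulator planted in a dataset.
.simulation_truth <- function(de_genes, effect_sizes, enriched_sets = character(0),
                              seed = NA_integer_, cor_blocks = NULL,
                              samples = NULL, kind = NULL) {
  structure(list(de_genes = as.character(de_genes),
                 effect_sizes = effect_sizes,
                 enriched_sets = as.character(enriched_sets),
                 seed = seed, cor_blocks = cor_blocks,
                 samples = samples, kind = kind),
            class = "SimulationTruth")
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat("SimulationTruth:", length(x$de_genes), "DE genes,",
      length(x$enriched_sets), "enriched sets, seed", x$seed, "\n")
  invisible(x)
}
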