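# Method registry: one addressable entry per benchmarked method plus
# stubs reserving names for methods a plugin may provide later.

.method_registry <- list(
  ora = list(hypothesis = "competitive", needs_permutations = FALSE),
  gsea = list(hypothesis = "competitive", needs_permutations = TRUE),
  safe = list(hypothesis = "competitive", needs_permutations = TRUE),
  padog = list(hypothesis = "competitive", needs_permutations = TRUE),
  camera = list(hypothesis = "competitive", needs_permutations = FALSE),
  samgs = list(hypothesis = "self_contained", needs_permutations = TRUE),
  globaltest = list(hypothesis = "self_contained", stub = TRUE),
  gsa = list(hypothesis = "competitive", stub = TRUE),
  roast = list(hypothesis = "self_contained", stub = TRUE),
  gsva = list(hypothesis = "self_contained", stub = TRUE)
)

#' List registered enrichment methods
#'
#' @param implemented_only Drop registry stubs that are reserved for
#'   future plugins.
#' @return A data.frame with columns `name`, `hypothesis`,
#'   `needs_permutations`, `implemented`.
#' @export
ea_methods <- function(implemented_only = TRUE) {
  df <- data.frame(
    name = names(.method_registry),
    hypothesis = vapply(.method_registry, `[[`, "", "hypothesis"),
    needs_permutations = vapply(.method_registry, function(m)
      isTRUE(m$needs_permutations), NA),
    implemented = !vapply(.method_registry, function(m)
      isTRUE(m$stub), NA),
    stringsAsFactors = FALSE, row.names = NULL)
  if (implemented_only) df <- df[df$implemented, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ORA needs a DE gene list; derive it from moderated-t statistics with
# the conventional dual criterion (BH-adjusted p < 0.05 and |log2 FC| >
# 1), falling back to nominal p < 0.05 when that list is empty (as it is
# on null or label-shuffled data).
.ora_from_dataset <- function(dataset, collection,
                              lfc_threshold = 1, fdr_threshold = 0.05) {
  if (!is.null(dataset$blocks))
    warning("ORA has no paired mode; blocks ignored")
  stats <- suppressWarnings(gene_level_stats(dataset, "moderated_t",
                                             paired = FALSE))
  de <- call_de_genes(stats, lfc_threshold, fdr_threshold,
                      criterion = "both")
  if (!length(de)) {
    warning("no genes pass the DE criterion; falling back to nominal ",
            "p < 0.05")
    de <- stats$gene[!is.na(stats$p) & stats$p < 0.05]
  }
  run_ora(de, stats$gene, collection)
}

#' Run a registered enrichment method by name
#'
#' Uniform front door for the benchmark harness: every method consumes a
#' dataset and collection and returns an `EARanking`.
#'
#' @param name Method name (see [ea_methods()]).
#' @param dataset An `ExpressionDataset`.
#' @param collection A `GeneSetCollection`.
#' @param n_perm Permutations for sample-permutation methods.
#' @param seed Seed for permutation draws.
#' @param ... Method-specific arguments (e.g. `weight_exponent` for
#'   GSEA, `inter_gene_cor` for CAMERA, `local_stat` for SAFE).
#' @return An `EARanking`.
#' @export
run_method <- function(name, dataset, collection, n_perm = 1000L,
                       seed = 1L, ...) {
  name <- match.arg(name, names(.method_registry))
  entry <- .method_registry[[name]]
  if (isTRUE(entry$stub))
    stop("method '", name, "' is a registry stub and not implemented; ",
         "register a plugin implementation to use it")
  switch(name,
    ora = .ora_from_dataset(dataset, collection, ...),
    gsea = run_gsea(dataset, collection, n_perm = n_perm, seed = seed, ...),
    safe = run_safe(dataset, collection, n_perm = n_perm, seed = seed, ...),
    padog = run_padog(dataset, collection, n_perm = n_perm, seed = seed, ...),
    camera = run_camera(dataset, collection, ...),
    samgs = run_samgs(dataset, collection, n_perm = n_perm, seed = seed, ...))
}

#' Export an EA ranking as TSV
#' @param ranking An `EARanking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ea_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "EARanking"))
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
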