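# Benchmark assays: fraction-significant bookkeeping, type-I error
# under sample-label randomization, gene-set-size dependency on random
# sets, runtime capture, and cross-method aggregation.

#' Fraction of significant gene sets in a ranking
#'
#' @param ranking An `EARanking`.
#' @param alpha Significance level (default 0.05).
#' @param adjusted Use BH-adjusted p-values instead of nominal.
#' @return Fraction in `[0, 1]`.
#' @export
significance_fraction <- function(ranking, alpha = 0.05, adjusted = FALSE) {
  stopifnot(inherits(ranking, "EARanking"))
  p <- if (adjusted) ranking$adj_p else ranking$p_value
  mean(p < alpha)
}

.assay_result <- function(assay, method, fractions, params) {
  structure(list(assay = assay, method = method, fractions = fractions,
                 mean = vapply(fractions, mean, 0),
                 sd = vapply(fractions, stats::sd, 0),
                 params = params),
            class = "AssayResult")
}

#' @export
print.AssayResult <- function(x, ...) {
  cat("AssayResult [", x$assay, "] for method '", x$method, "'\n", sep = "")
  print(data.frame(bin = names(x$mean), mean = round(x$mean, 4),
                   sd = round(x$sd, 4), row.names = NULL))
  invisible(x)
}

#' Tidy a set of assay results for export
#' @param results List of `AssayResult` objects.
#' @return A long data.frame (`method`, `assay`, `bin`, `replicate`,
#'   `fraction`).
#' @export
assay_table <- function(results) {
  if (inherits(results, "AssayResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    do.call(rbind, lapply(names(r$fractions), function(b) {
      data.frame(method = r$method, assay = r$assay, bin = b,
                 replicate = seq_along(r$fractions[[b]]),
                 fraction = r$fractions[[b]], stringsAsFactors = FALSE)
    }))
  }))
}

#' Type-I error under sample-label randomization
#'
#' Shuffles the binary group labels `n_shuffles` times (within blocks
#' when present), re-runs the method on each shuffled dataset, and
#' records the fraction of gene sets with nominal `p < alpha`. On data
#' with no group structure a well-calibrated method should average near
#' `alpha`.
#'
#' @param method Method name (see [ea_methods()]).
#' @param dataset An `ExpressionDataset`.
#' @param collection A `GeneSetCollection`.
#' @param n_shuffles Number of label shuffles (>= 10).
#' @param alpha Nominal significance level.
#' @param seed Integer seed.
#' @param n_perm Permutations inside permutation-based methods.
#' @param ... Passed to [run_method()].
#' @return An `AssayResult` with one bin (`"shuffle"`) holding the
#'   per-shuffle fraction vector.
#' @export
type_one_error_assay <- function(method, dataset, collection,
                                 n_shuffles = 100L, alpha = 0.05,
                                 seed = 1L, n_perm = 100L, ...) {
  if (n_shuffles < 10) stop("`n_shuffles` must be >= 10")
  perms <- .permute_groups(dataset$groups, dataset$blocks, n_shuffles, seed)
  fractions <- rep(NA_real_, n_shuffles)
  for (i in seq_len(n_shuffles)) {
    ds <- dataset
    ds$groups <- perms[[i]]
    rk <- tryCatch(
      suppressWarnings(run_method(method, ds, collection, n_perm = n_perm,
                                  seed = seed + i, ...)),
      error = function(e) NULL)
    if (!is.null(rk)) fractions[i] <- significance_fraction(rk, alpha)
  }
  failed <- sum(is.na(fractions))
  if (failed > 0) {
    warning(failed, " shuffle(s) failed and were dropped")
    if (failed > 0.1 * n_shuffles) stop("more than 10% of shuffles failed")
  }
  .assay_result("type1", method,
                list(shuffle = fractions[!is.na(fractions)]),
                list(alpha = alpha, n_shuffles = n_shuffles,
                     n_perm = n_perm, seed = seed))
}

#' Gene-set-size dependency on random gene sets
#'
#' For each size, samples `n_sets` random gene sets from the measured
#' universe, runs the method with the true sample labels, and records
#' the fraction of sets with nominal `p < alpha`. Competitive methods
#' should be flat in size; self-contained methods on data with
#' background differential expression grow with size.
#'
#' @inheritParams type_one_error_assay
#' @param sizes Integer vector of set sizes; the default follows the
#'   customary grid `{5, 10, 25, 50, 100, 250, 500}`.
#' @param n_sets Random sets per size (default 100).
#' @return An `AssayResult` with one bin per size; each bin holds the
#'   per-set significance indicators' mean as a single fraction.
#' @export
random_set_size_assay <- function(method, dataset,
                                  sizes = c(5L, 10L, 25L, 50L, 100L, 250L, 500L),
                                  n_sets = 100L, alpha = 0.05, seed = 1L,
                                  n_perm = 100L, ...) {
  universe <- rownames(dataset$matrix)
  if (max(sizes) > length(universe))
    stop("max(sizes) exceeds the dataset universe size")
  fractions <- lapply(seq_along(sizes), function(j) {
    coll <- sample_random_sets(universe, sizes[j], n_sets, seed = seed + j)
    rk <- suppressWarnings(run_method(method, dataset, coll,
                                      n_perm = n_perm, seed = seed + j, ...))
    significance_fraction(rk, alpha)
  })
  names(fractions) <- as.character(sizes)
  .assay_result("setsize", method, fractions,
                list(alpha = alpha, sizes = sizes, n_sets = n_sets,
                     n_perm = n_perm, seed = seed))
}

#' Wall-clock runtime of one method run
#'
#' @inheritParams type_one_error_assay
#' @return Elapsed seconds (single number); the ranking is attached as
#'   attribute `ranking`.
#' @export
runtime_profile <- function(method, dataset, collection, n_perm = 1000L,
                            seed = 1L, ...) {
  t0 <- proc.time()[["elapsed"]]
  rk <- run_method(method, dataset, collection, n_perm = n_perm,
                   seed = seed, ...)
  structure(proc.time()[["elapsed"]] - t0, ranking = rk)
}

#' Compare relative relevance scores across methods or hypothesis types
#'
#' Groups a collection of relevance results and reports median and IQR
#' of the relative score `X_bar` per group plus pairwise two-sample
#' Wilcoxon rank-sum p-values between groups.
#'
#' @param results A data.frame with columns `method`, `hypothesis`,
#'   `X_bar` (e.g. rows of a benchmark report), or a list of such rows.
#' @param grouping `"hypothesis_type"` or `"method"`.
#' @return A data.frame (`group`, `n`, `median`, `q1`, `q3`) with the
#'   pairwise p-value matrix in attribute `pairwise_p`.
#' @export
aggregate_compare <- function(results,
                              grouping = c("hypothesis_type", "method")) {
  grouping <- match.arg(grouping)
  if (!is.data.frame(results)) results <- do.call(rbind, results)
  key <- if (grouping == "hypothesis_type") results$hypothesis
         else results$method
  ok <- !is.na(results$X_bar)
  key <- key[ok]
  x <- results$X_bar[ok]
  groups <- split(x, key)
  if (length(groups) < 2) stop("need at least 2 groups to compare")
  if (any(lengths(groups) < 2)) stop("need >= 2 results per group")
  tab <- data.frame(
    group = names(groups),
    n = lengths(groups),
    median = vapply(groups, stats::median, 0),
    q1 = vapply(groups, function(v) stats::quantile(v, 0.25, names = FALSE), 0),
    q3 = vapply(groups, function(v) stats::quantile(v, 0.75, names = FALSE), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  gn <- names(groups)
  pm <- matrix(NA_real_, length(gn), length(gn), dimnames = list(gn, gn))
  for (i in seq_along(gn)) for (j in seq_along(gn)) {
    if (i < j) {
      pv <- suppressWarnings(
        stats::wilcox.test(groups[[i]], groups[[j]])$p.value)
      if (!is.finite(pv)) pv <- 1  # fully tied groups: no evidence
      pm[i, j] <- pm[j, i] <- pv
    }
  }
  structure(tab, pairwise_p = pm)
}
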