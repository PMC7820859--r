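# Six enrichment methods behind one interface: dataset + collection in,
# EARanking out. Competitive methods compare set genes against the rest
# of the measured universe; the self-contained SAMGS tests the set in
# isolation. Sample-permutation methods share one label-shuffling engine
# (block-restricted when blocks are present) and recompute their gene
# statistic in every permutation.

# Intersect a collection with the dataset's measured universe and set up
# the matrices every method works from.
.prepare_method_data <- function(dataset, collection, prior_count = "auto") {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(collection, "GeneSetCollection"))
  dataset <- .as_log_expression(dataset, prior_count)
  universe <- rownames(dataset$matrix)
  idx <- lapply(collection, function(s) which(universe %in% s))
  empty <- lengths(idx) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) had no genes in the dataset ",
            "universe and were dropped")
    idx <- idx[!empty]
  }
  if (!length(idx)) stop("no gene sets left after intersecting with universe")
  x <- dataset$matrix
  list(x = x, x2 = x^2, groups = dataset$groups, blocks = dataset$blocks,
       universe = universe, set_idx = idx, sizes = lengths(idx))
}

.group_indices <- function(groups) {
  list(i1 = which(groups == levels(groups)[1]),
       i2 = which(groups == levels(groups)[2]))
}

# Gene statistic vector for one label assignment; non-finite values
# (zero-variance genes) carry no evidence and are zeroed.
.gene_stat_vector <- function(prep, groups, statistic) {
  gi <- .group_indices(groups)
  mom <- .two_group_moments(prep$x, prep$x2, gi$i1, gi$i2)
  s <- .stat_core_safe(mom, statistic)$stat
  s[!is.finite(s)] <- 0
  s
}

# .stat_core with a degenerate-variance guard so constant matrices do
# not break the empirical-Bayes fit.
.stat_core_safe <- function(mom, statistic) {
  if (statistic == "moderated_t") {
    df <- mom$n1 + mom$n2 - 2
    sp2 <- ((mom$n1 - 1) * mom$v1 + (mom$n2 - 1) * mom$v2) / df
    if (all(sp2 <= 0))
      return(list(stat = rep(0, length(sp2)), p = rep(1, length(sp2)),
                  df = df))
  }
  .stat_core(mom, statistic)
}

# Run `set_stats(gene_stat_vector)` for the observed labels and n_perm
# permuted labels; returns list(observed=, null=matrix sets x n_perm).
.permute_set_stats <- function(prep, statistic, set_stats, n_perm, seed) {
  observed <- set_stats(.gene_stat_vector(prep, prep$groups, statistic))
  perms <- .permute_groups(prep$groups, prep$blocks, n_perm, seed)
  null <- vapply(perms, function(g) {
    set_stats(.gene_stat_vector(prep, g, statistic))
  }, numeric(length(observed)))
  if (is.null(dim(null))) null <- matrix(null, nrow = 1L)
  list(observed = observed, null = null)
}

.perm_pvalues <- function(observed, null, tail = "upper") {
  vapply(seq_along(observed), function(i) {
    permutation_pvalue(observed[i], null[i, ], tail = tail)
  }, 0)
}

#' Over-representation analysis (ORA)
#'
#' Competitive test of the overlap between a differentially expressed
#' (DE) gene list and each gene set: one-sided hypergeometric upper-tail
#' probability `P(X >= k)` of observing at least the overlap `k` given
#' the universe, DE-list and set sizes (Fisher's exact test one-sided).
#'
#' @param de_genes Character vector of DE gene ids (non-empty, subset of
#'   `universe`).
#' @param universe Character vector of all measured gene ids.
#' @param collection A `GeneSetCollection`; sets are intersected with the
#'   universe and sets emptied by the intersection are dropped.
#' @return An `EARanking` with the overlap count as statistic.
#' @export
run_ora <- function(de_genes, universe, collection) {
  universe <- unique(as.character(universe))
  de_genes <- unique(as.character(de_genes))
  if (!length(universe)) stop("`universe` must be non-empty")
  if (!length(de_genes))
    stop("`de_genes` is empty; provide a fallback gene list ",
         "(e.g. nominal p < 0.05) before running ORA")
  if (!all(de_genes %in% universe))
    stop("`de_genes` must be a subset of `universe`")
  sets <- lapply(collection, intersect, universe)
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " set(s) empty after intersection; dropped")
    sets <- sets[!empty]
  }
  if (!length(sets)) stop("no gene sets overlap the universe")
  N <- length(universe); K <- length(de_genes)
  m <- lengths(sets)
  k <- vapply(sets, function(s) sum(s %in% de_genes), 0L)
  p <- stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
  .make_ea_ranking(names(sets), m, as.numeric(k), p,
                   method = "ora", hypothesis = "competitive")
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score. Hits add
# |stat|^exponent (normalized), misses subtract 1/(N - m); ES is the
# signed maximal deviation of the running sum from zero. The extrema of
# the running sum occur at hit positions (maxima) or just before them
# (minima), so only the sorted hit positions need visiting.
.gsea_es_at <- function(sorted_stat, pos, exponent = 1) {
  N <- length(sorted_stat)
  m <- length(pos)
  w <- abs(sorted_stat[pos])^exponent
  if (sum(w) == 0) w <- rep(1, m)
  ch <- cumsum(w) / sum(w)
  step <- if (N > m) 1 / (N - m) else 0
  miss_before <- (pos - seq_len(m)) * step
  at_hit <- ch - miss_before
  before_hit <- c(0, ch[-m]) - miss_before
  es_pos <- max(0, at_hit)
  es_neg <- min(0, before_hit)
  if (es_pos >= -es_neg) es_pos else es_neg
}

.gsea_es <- function(stat, set_idx, exponent = 1) {
  ord <- order(stat, decreasing = TRUE)
  pos_of <- integer(length(stat))
  pos_of[ord] <- seq_along(stat)
  .gsea_es_at(stat[ord], sort(pos_of[set_idx]), exponent)
}

#' Gene set enrichment analysis (GSEA)
#'
#' Competitive method: genes are ranked by the signal-to-noise statistic
#' and each set scored by the enrichment score (ES), the maximal
#' deviation of a weighted Kolmogorov-Smirnov running sum (hit
#' increments proportional to `|stat|^weight_exponent`, miss decrements
#' `1/(N - m)`). Significance is the two-sided sample-permutation
#' p-value of `|ES|`.
#'
#' @param dataset An `ExpressionDataset` (>= 2 samples per group).
#' @param collection A `GeneSetCollection`.
#' @param n_perm Number of sample-label permutations (>= 1).
#' @param seed Integer seed for the permutations.
#' @param weight_exponent Exponent on `|stat|` for hit increments;
#'   0 gives the unweighted (classic KS) form, default 1.
#' @return An `EARanking` with ES as statistic.
#' @export
run_gsea <- function(dataset, collection, n_perm = 1000L, seed = 1L,
                     weight_exponent = 1) {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  prep <- .prepare_method_data(dataset, collection)
  set_stats <- function(s) {
    ord <- order(s, decreasing = TRUE)
    pos_of <- integer(length(s))
    pos_of[ord] <- seq_along(s)
    ss <- s[ord]
    vapply(prep$set_idx, function(idx) {
      .gsea_es_at(ss, sort(pos_of[idx]), weight_exponent)
    }, 0)
  }
  ps <- .permute_set_stats(prep, "s2n", set_stats, n_perm, seed)
  p <- .perm_pvalues(ps$observed, ps$null, tail = "two_sided")
  .make_ea_ranking(names(prep$set_idx), prep$sizes, ps$observed, p,
                   method = "gsea", hypothesis = "competitive")
}

#' Significance analysis of function and expression (SAFE)
#'
#' Competitive two-layer permutation test: a local (per-gene) statistic
#' is computed for every gene, then a global (per-set) statistic
#' compares set genes against the background; significance comes from
#' recomputing both layers under sample-label permutations. Defaults
#' follow the classic pairing of a Student t local statistic with a
#' Wilcoxon rank sum of `|t|` (set genes versus all genes).
#'
#' @param dataset An `ExpressionDataset`.
#' @param collection A `GeneSetCollection`; a set equal to the whole
#'   universe has no background and is an error.
#' @param local_stat One of `"ordinary_t"`, `"moderated_t"`, `"sam_t"`.
#' @param global_stat `"wilcoxon"` (rank sum of `|local|`) or
#'   `"meanabs"` (mean of `|local|` over set genes).
#' @param n_perm,seed Permutation count and seed.
#' @return An `EARanking` with the global statistic as statistic.
#' @export
run_safe <- function(dataset, collection,
                     local_stat = c("ordinary_t", "moderated_t", "sam_t"),
                     global_stat = c("wilcoxon", "meanabs"),
                     n_perm = 1000L, seed = 1L) {
  local_stat <- match.arg(local_stat)
  global_stat <- match.arg(global_stat)
  prep <- .prepare_method_data(dataset, collection)
  if (any(prep$sizes == length(prep$universe)))
    stop("a gene set equal to the entire universe leaves no background ",
         "for a competitive statistic")
  set_stats <- switch(global_stat,
    wilcoxon = function(s) {
      r <- rank(abs(s))
      vapply(prep$set_idx, function(idx) sum(r[idx]), 0)
    },
    meanabs = function(s) {
      a <- abs(s)
      vapply(prep$set_idx, function(idx) mean(a[idx]), 0)
    })
  ps <- .permute_set_stats(prep, local_stat, set_stats, n_perm, seed)
  p <- .perm_pvalues(ps$observed, ps$null, tail = "upper")
  .make_ea_ranking(names(prep$set_idx), prep$sizes, ps$observed, p,
                   method = "safe", hypothesis = "competitive")
}

# PADOG gene weights: down-weight genes appearing in many sets.
.padog_weights <- function(set_idx, n_genes) {
  f <- tabulate(unlist(set_idx), nbins = n_genes)
  fmax <- max(f); fmin <- min(f[f > 0])
  w <- rep(1, n_genes)
  if (fmax > fmin) {
    pos <- f > 0
    w[pos] <- 1 + sqrt((fmax - f[pos]) / (fmax - fmin))
  }
  w
}

#' Pathway analysis with down-weighting of overlapping genes (PADOG)
#'
#' Competitive permutation method. Each gene is weighted by
#' `w_g = 1 + sqrt((f_max - f_g) / (f_max - f_min))` where `f_g` is the
#' number of sets containing the gene (all weights 1 when every gene has
#' the same frequency), so genes shared by many sets count less. The set
#' statistic is the mean of `w_g * |moderated t|` over set genes; the
#' observed and each permutation's set statistics are standardized
#' across sets (mean 0, SD 1) before the permutation p-value.
#'
#' @inheritParams run_gsea
#' @return An `EARanking` with the standardized weighted mean as
#'   statistic.
#' @export
run_padog <- function(dataset, collection, n_perm = 1000L, seed = 1L) {
  if (n_perm < 20) warning("n_perm < 20 makes the cross-set ",
                           "standardization unstable")
  prep <- .prepare_method_data(dataset, collection)
  gw <- .padog_weights(prep$set_idx, length(prep$universe))
  standardize <- function(v) {
    if (length(v) > 1L && stats::sd(v) > 0) (v - mean(v)) / stats::sd(v)
    else v - mean(v)
  }
  set_stats <- function(s) {
    ws <- gw * abs(s)
    standardize(vapply(prep$set_idx, function(idx) mean(ws[idx]), 0))
  }
  ps <- .permute_set_stats(prep, "moderated_t", set_stats, n_perm, seed)
  p <- .perm_pvalues(ps$observed, ps$null, tail = "upper")
  .make_ea_ranking(names(prep$set_idx), prep$sizes, ps$observed, p,
                   method = "padog", hypothesis = "competitive")
}

#' Correlation-adjusted mean-rank gene set test (CAMERA)
#'
#' Competitive parametric test. Per-gene moderated t statistics are
#' mapped to normal-equivalent z scores; each set is tested by a
#' two-sample t statistic comparing set z scores against background z
#' scores, with the set-side variance inflated by
#' `VIF = 1 + (m - 1) * rho` to account for inter-gene correlation.
#' `rho` is either a fixed value (default 0.01) or estimated per set as
#' the mean pairwise correlation of group-centered residuals.
#'
#' @param dataset An `ExpressionDataset`.
#' @param collection A `GeneSetCollection`; a set equal to the universe
#'   is an error.
#' @param inter_gene_cor Fixed correlation in `(-1/(m-1), 1)`, or
#'   `"estimate"`.
#' @return An `EARanking` with the variance-inflated t as statistic and
#'   two-sided p from the t reference distribution.
#' @export
run_camera <- function(dataset, collection, inter_gene_cor = 0.01) {
  prep <- .prepare_method_data(dataset, collection)
  N <- length(prep$universe)
  if (any(prep$sizes == N))
    stop("a gene set equal to the entire universe leaves no background")
  gi <- .group_indices(prep$groups)
  mom <- .two_group_moments(prep$x, prep$x2, gi$i1, gi$i2)
  res <- .stat_core_safe(mom, "moderated_t")
  z <- limma::zscoreT(res$stat, df = res$df, approx = FALSE)
  z[!is.finite(z)] <- 0
  resid <- NULL
  if (identical(inter_gene_cor, "estimate")) {
    resid <- prep$x
    resid[, gi$i1] <- resid[, gi$i1, drop = FALSE] - mom$m1
    resid[, gi$i2] <- resid[, gi$i2, drop = FALSE] - mom$m2
  }
  out <- vapply(prep$set_idx, function(idx) {
    m <- length(idx)
    rho <- if (is.null(resid)) inter_gene_cor else {
      if (m < 2) 0 else {
        cm <- suppressWarnings(stats::cor(t(resid[idx, , drop = FALSE])))
        cm[!is.finite(cm)] <- 0
        (sum(cm) - m) / (m * (m - 1))
      }
    }
    rho <- min(max(rho, -1 / max(m - 1, 1) + 1e-8), 1 - 1e-8)
    vif <- 1 + (m - 1) * rho
    zs <- z[idx]; zr <- z[-idx]
    delta <- mean(zs) - mean(zr)
    s2 <- if (m >= 2)
      ((m - 1) * stats::var(zs) + (N - m - 1) * stats::var(zr)) / (N - 2)
    else stats::var(zr)
    if (s2 <= 0) return(c(0, 1))
    tt <- delta / sqrt(s2 * (vif / m + 1 / (N - m)))
    c(tt, 2 * stats::pt(-abs(tt), N - 2))
  }, numeric(2))
  .make_ea_ranking(names(prep$set_idx), prep$sizes, out[1, ], out[2, ],
                   method = "camera", hypothesis = "competitive")
}

#' Significance analysis of microarrays for gene sets (SAMGS)
#'
#' Self-contained permutation method: the set statistic is the sum of
#' squared SAM t statistics over the genes of the set (a T-squared-like
#' aggregate of per-gene moderated evidence), with significance from the
#' upper tail of the sample-permutation null. Being self-contained, it
#' makes no comparison against background genes and its statistic is
#' non-decreasing in set size on fixed data.
#'
#' @inheritParams run_gsea
#' @return An `EARanking` with the sum of squared SAM t as statistic.
#' @export
run_samgs <- function(dataset, collection, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  prep <- .prepare_method_data(dataset, collection)
  set_stats <- function(s) {
    s2 <- s^2
    vapply(prep$set_idx, function(idx) sum(s2[idx]), 0)
  }
  ps <- .permute_set_stats(prep, "sam_t", set_stats, n_perm, seed)
  p <- .perm_pvalues(ps$observed, ps$null, tail = "upper")
  .make_ea_ranking(names(prep$set_idx), prep$sizes, ps$observed, p,
                   method = "samgs", hypothesis = "self_contained")
}
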