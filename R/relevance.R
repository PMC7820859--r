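# Rank-to-weight transformation and the phenotype relevance score: the
# heart of the benchmark. An enrichment ranking of N gene sets is turned
# into weights w in [0,1] that decay linearly down the ranking, and the
# relevance score X is the weight-by-relevance dot product against an
# a-priori relevance ranking S_p, normalized by its theoretical optimum.

#' Transform ranking statistics into top-weighted weights
#'
#' Tie-free case: a set with absolute rank `r_A` among `N` sets gets
#' weight `w = 1 - r_A / N`, so the top set gets `1 - 1/N` and the last
#' gets 0. With ties, the relative rank is generalized to the fraction
#' of sets whose statistic is at least as extreme, so tied sets share
#' one weight; the tie-free formula is recovered when all values are
#' distinct.
#'
#' @param statistics Numeric vector of ranking statistics.
#' @param orientation `"smaller"` if smaller values are more extreme
#'   (p-values), `"larger"` for scores.
#' @return Weights in `[0, 1]`, aligned with `statistics`.
#' @export
ranks_to_weights <- function(statistics,
                             orientation = c("smaller", "larger")) {
  orientation <- match.arg(orientation)
  if (!length(statistics)) stop("`statistics` must be non-empty")
  if (anyNA(statistics)) stop("`statistics` contains missing values")
  n <- length(statistics)
  r_star <- if (orientation == "smaller") {
    vapply(statistics, function(s) sum(statistics <= s), 0) / n
  } else {
    vapply(statistics, function(s) sum(statistics >= s), 0) / n
  }
  1 - r_star
}

# Zero the weights of sets ranked below the top `top_fraction` of the
# ranking (weights w >= 1 - top_fraction are kept; the rest contribute
# nothing). Restricting the evaluation to the top of a ranking asks
# whether relevance accumulates where analysts actually look.
.truncate_weights <- function(w, top_fraction) {
  if (top_fraction < 1) w[w < 1 - top_fraction] <- 0
  w
}

# Reconcile a ranking with a relevance ranking: keep shared sets only
# and recompute weights on the intersection.
.shared_weights <- function(ranking, relevance) {
  rs <- .ranking_stat(ranking)
  shared <- intersect(names(rs$values), names(relevance))
  if (!length(shared))
    stop("ranking and relevance ranking share no gene sets")
  dropped <- (length(rs$values) - length(shared)) +
    (length(relevance) - length(shared))
  if (dropped > 0)
    message(dropped, " set(s) present in only one of ranking/relevance ",
            "dropped before scoring")
  list(w = ranks_to_weights(rs$values[shared], rs$orientation),
       s = as.numeric(relevance)[match(shared, names(relevance))],
       shared = shared)
}

#' Phenotype relevance score of an enrichment ranking
#'
#' Computes `X = sum_i w(i) * S_p(i)` over the gene sets shared between
#' the enrichment ranking and the relevance ranking, where `w` are the
#' rank weights ([ranks_to_weights()], recomputed on the shared subset)
#' and `S_p` the relevance scores. The more relevance the ranking
#' accumulates near its top, the larger `X`.
#'
#' @param ranking An `EARanking` or [score_ranking()].
#' @param relevance A `RelevanceRanking`.
#' @param top_fraction Restrict the evaluation to the top fraction of
#'   the ranking: weights below `1 - top_fraction` are zeroed (default
#'   1, no truncation).
#' @return The relevance score `X >= 0`.
#' @export
relevance_score <- function(ranking, relevance, top_fraction = 1) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("`top_fraction` must be in (0, 1]")
  sw <- .shared_weights(ranking, relevance)
  sum(.truncate_weights(sw$w, top_fraction) * sw$s)
}

#' Optimal and relative relevance score
#'
#' The theoretical optimum `O_p` is the relevance score of the ranking
#' that orders sets by `S_p` itself (ties in `S_p` handled by the
#' tie-aware weights), and the relative score `X_bar = X / O_p` lies in
#' `[0, 1]` for tie-free rankings, making methods comparable across
#' datasets whose relevance scores scale differently.
#'
#' @inheritParams relevance_score
#' @return A list with `X`, `O` (optimal score) and `X_bar`; when
#'   `O = 0`, `X_bar` is defined as 0 with a warning.
#' @export
optimal_and_relative <- function(ranking, relevance, top_fraction = 1) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("`top_fraction` must be in (0, 1]")
  sw <- .shared_weights(ranking, relevance)
  X <- sum(.truncate_weights(sw$w, top_fraction) * sw$s)
  O <- sum(.truncate_weights(ranks_to_weights(sw$s, "larger"),
                             top_fraction) * sw$s)
  if (O == 0) {
    warning("optimal score is 0; relative score defined as 0")
    return(list(X = X, O = 0, X_bar = 0))
  }
  list(X = X, O = O, X_bar = X / O)
}

# All permutations of 1..n (n <= 7 in practice).
.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Random-ranking null p-value for a relevance score
#'
#' Compares the observed relevance score against scores of rankings that
#' place the gene sets in uniformly random order. When `N! <= 10^4` all
#' permutations are enumerated and the p-value is exact
#' (`p = b / N!`); otherwise `n_random` permutations are sampled and the
#' add-one convention `p = (b + 1) / (n_random + 1)` applies.
#'
#' @inheritParams relevance_score
#' @param n_random Number of sampled random rankings (>= 1).
#' @param seed Integer seed for the sampled mode.
#' @return p-value in `(0, 1]`, with attributes `null_scores` and
#'   `exhaustive`.
#' @export
random_ranking_pvalue <- function(ranking, relevance, n_random = 1000L,
                                  seed = 1L) {
  if (n_random < 1) stop("`n_random` must be >= 1")
  sw <- .shared_weights(ranking, relevance)
  X <- sum(sw$w * sw$s)
  n <- length(sw$s)
  w_free <- 1 - seq_len(n) / n  # tie-free weights by rank position
  exhaustive <- factorial(n) <= 1e4
  if (exhaustive) {
    perms <- .all_permutations(n)
    null_scores <- vapply(seq_len(nrow(perms)), function(i) {
      sum(w_free[perms[i, ]] * sw$s)
    }, 0)
    p <- sum(null_scores >= X) / length(null_scores)
    p <- max(p, .Machine$double.eps)  # guard: X above every enumerated score
  } else {
    set.seed(seed)
    null_scores <- vapply(seq_len(n_random), function(i) {
      sum(w_free[sample.int(n)] * sw$s)
    }, 0)
    p <- (sum(null_scores >= X) + 1) / (n_random + 1)
  }
  structure(p, null_scores = null_scores, exhaustive = exhaustive)
}

#' Label-permutation null p-value for a relevance score
#'
#' Re-runs an enrichment method on the dataset with permuted sample
#' labels (block-restricted when blocks are present), scores every
#' resulting ranking against the relevance ranking, and returns the
#' upper-tail permutation p-value of the observed score. Unlike the
#' random-ranking null, this null preserves ranking dependencies imposed
#' by structural overlaps between gene sets.
#'
#' @param method Method name (see [ea_methods()]).
#' @param dataset An `ExpressionDataset`.
#' @param collection A `GeneSetCollection`.
#' @param relevance A `RelevanceRanking`.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param ... Passed on to [run_method()] (e.g. the method's own
#'   `n_perm` via `method_n_perm`).
#' @param method_n_perm Permutation count used inside the method itself.
#' @return p-value in `(0, 1]` with attribute `null_scores`.
#' @export
label_permutation_pvalue <- function(method, dataset, collection, relevance,
                                     n_perm = 100L, seed = 1L,
                                     method_n_perm = 100L, ...) {
  observed <- run_method(method, dataset, collection,
                         n_perm = method_n_perm, seed = seed, ...)
  X <- relevance_score(observed, relevance)
  perms <- .permute_groups(dataset$groups, dataset$blocks, n_perm, seed)
  null_scores <- rep(NA_real_, n_perm)
  for (b in seq_len(n_perm)) {
    ds_b <- dataset
    ds_b$groups <- perms[[b]]
    rk <- tryCatch(
      suppressWarnings(run_method(method, ds_b, collection,
                                  n_perm = method_n_perm,
                                  seed = seed + b, ...)),
      error = function(e) NULL)
    if (!is.null(rk))
      null_scores[b] <- suppressMessages(relevance_score(rk, relevance))
  }
  failed <- sum(is.na(null_scores))
  if (failed > 0) {
    warning(failed, " permutation(s) failed and were dropped")
    if (failed > 0.1 * n_perm)
      stop("more than 10% of label permutations failed")
    null_scores <- null_scores[!is.na(null_scores)]
  }
  structure(permutation_pvalue(X, null_scores, tail = "upper"),
            null_scores = null_scores, observed = X)
}
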