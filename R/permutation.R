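#' Empirical p-value from a permutation null
#'
#' Uses the add-one convention `p = (b + 1) / (B + 1)`, where `b` counts
#' null values at least as extreme as the observed value under the
#' declared tail, so a permutation p-value is never exactly zero.
#'
#' @param observed Observed statistic (single number).
#' @param null_values Numeric vector of null statistics (length >= 1).
#' @param tail `"upper"` (extreme = `>= observed`), `"lower"`
#'   (`<= observed`) or `"two_sided"` (`|null| >= |observed|`).
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed,
                               null_values,
                               tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  if (length(null_values) < 1L) stop("`null_values` must be non-empty")
  if (length(observed) != 1L || is.na(observed))
    stop("`observed` must be a single non-missing number")
  b <- switch(tail,
              upper = sum(null_values >= observed),
              lower = sum(null_values <= observed),
              two_sided = sum(abs(null_values) >= abs(observed)))
  (b + 1) / (length(null_values) + 1)
}

# Generate n_perm permuted group factors. With blocks, labels are
# shuffled within each block so the pairing structure is preserved.
.permute_groups <- function(groups, blocks = NULL, n_perm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx_by_block <- if (is.null(blocks)) list(seq_along(groups))
                  else split(seq_along(groups), blocks)
  lapply(seq_len(n_perm), function(b) {
    g <- groups
    for (ii in idx_by_block) g[ii] <- g[ii][sample(length(ii))]
    g
  })
}

# Shuffle a dataset's labels once (used by the type-I-error assay).
.shuffle_dataset <- function(dataset) {
  dataset$groups <- .permute_groups(dataset$groups, dataset$blocks, 1L)[[1]]
  dataset
}
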