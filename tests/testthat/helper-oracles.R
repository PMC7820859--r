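# Independent brute-force oracles and tiny fixture builders shared
# across the suite. Oracles are written to be obviously correct, not
# fast, and never reuse code from the implementation paths they check.

# Step-up BH, written from the definition: sort p ascending, multiply by
# n/i, enforce monotonicity from the largest down, cap at 1.
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Hypergeometric upper tail P(X >= k) by direct summation of the
# probability mass, using exact binomial coefficients.
brute_force_hyper_tail <- function(k, K, N, m) {
  j <- max(k, 0):min(K, m)
  if (k > min(K, m)) return(0)
  sum(choose(K, j) * choose(N - K, m - j)) / choose(N, m)
}

# GSEA enrichment score by materializing the full running sum over all
# N positions and taking the signed maximal deviation (positive wins
# ties with equal magnitude).
brute_force_es <- function(stat, set_idx, exponent = 1) {
  N <- length(stat)
  ord <- order(stat, decreasing = TRUE)
  hit <- ord %in% set_idx
  w <- abs(stat[ord])^exponent * hit
  if (sum(w) == 0) w <- as.numeric(hit)
  inc <- w / sum(w)
  dec <- (!hit) / max(N - sum(hit), 1)
  rs <- cumsum(inc - dec)
  mx <- max(rs); mn <- min(rs)
  es_pos <- max(0, mx); es_neg <- min(0, mn)
  if (es_pos >= -es_neg) es_pos else es_neg
}

# Mean relevance score over ALL rankings by full enumeration (n <= 6).
enumerate_mean_relevance <- function(s) {
  n <- length(s)
  perms <- .all_perms_helper(n)
  w <- 1 - seq_len(n) / n
  mean(apply(perms, 1, function(pp) sum(w[pp] * s)))
}

.all_perms_helper <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms_helper(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(seq_len(n)[-k][sub], nrow(sub)))
  }))
}

# Tiny deterministic dataset: `n_genes` Gaussian genes, two groups of
# `n_per_group`, a leading block of genes shifted by `shift`.
toy_dataset <- function(n_genes = 50, n_per_group = 4, shift = 0,
                        n_shifted = 0, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per_group), n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("s%02d", 1:(2 * n_per_group))))
  g <- rep(c("a", "b"), each = n_per_group)
  if (n_shifted > 0)
    m[seq_len(n_shifted), g == "b"] <- m[seq_len(n_shifted), g == "b"] + shift
  expression_dataset(m, g)
}

toy_collection <- function(universe, sizes, seed = 7) {
  set.seed(seed)
  sets <- lapply(seq_along(sizes), function(i) sample(universe, sizes[i]))
  names(sets) <- sprintf("ts%02d", seq_along(sizes))
  gene_set_collection(sets)
}
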