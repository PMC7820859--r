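#' Simulate an expression dataset with planted differential expression
#'
#' Generates a genes x samples matrix for a two-group design with a
#' controlled fraction of differentially expressed (DE) genes. In
#' `log_intensity` mode values are Gaussian around gene-wise baselines
#' (N(7, 1)) with unit noise; DE genes receive a mean shift of
#' `effect_size` log2 units in the second group, sign drawn at random per
#' gene. In `counts` mode counts are negative binomial with log-normal
#' gene means (meanlog 4, sdlog 1), mild library-size variation and a
#' common dispersion `phi` (`phi = 0` gives Poisson); DE genes have their
#' second-group mean multiplied by `2^(+-effect_size)`. In `tpm` mode the
#' Gaussian log-scale matrix is exponentiated and each sample rescaled to
#' a column sum of 1e6.
#'
#' Inter-gene correlation is induced by latent factors: with
#' `within_set_cor = rho > 0` the genes are partitioned into consecutive
#' blocks of `cor_block_size`, each block sharing a per-sample latent
#' normal factor with loading `sqrt(rho)`, so genes in a block have
#' pairwise correlation `rho`. The block memberships are recorded in the
#' returned truth so gene sets can be built on top of them.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_per_group Samples per group (>= 2).
#' @param de_fraction Fraction of genes simulated as DE, in `[0, 1]`.
#' @param effect_size Absolute log2 effect for DE genes (> 0).
#' @param within_set_cor Pairwise correlation within latent blocks, in
#'   `[0, 1)`; 0 disables the latent factors.
#' @param cor_block_size Genes per latent block when correlation is on.
#' @param kind `"log_intensity"`, `"counts"` or `"tpm"`.
#' @param phi Common NB dispersion for `kind = "counts"`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `dataset` (an `ExpressionDataset`) and `truth`
#'   (a `SimulationTruth` with `de_genes`, signed `effect_sizes`,
#'   `cor_blocks`, `seed`).
#' @export
simulate_expression <- function(n_genes, n_per_group,
                                de_fraction = 0, effect_size = 1,
                                within_set_cor = 0, cor_block_size = 20L,
                                kind = c("log_intensity", "counts", "tpm"),
                                phi = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  if (n_genes < 10) stop("`n_genes` must be >= 10")
  if (n_per_group < 2) stop("`n_per_group` must be >= 2")
  if (de_fraction < 0 || de_fraction > 1) stop("`de_fraction` in [0,1]")
  if (within_set_cor < 0 || within_set_cor >= 1)
    stop("`within_set_cor` in [0,1)")
  set.seed(seed)

  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  n <- 2L * n_per_group
  sample_ids <- sprintf("s%03d", seq_len(n))
  groups <- rep(c("control", "case"), each = n_per_group)
  case <- which(groups == "case")

  n_de <- 0L
  if (de_fraction > 0) {
    n_de <- round(de_fraction * n_genes)
    if (n_de < 1L) {
      warning("de_fraction * n_genes < 1; rounding up to 1 DE gene")
      n_de <- 1L
    }
  }
  de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
  signs <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
  effects <- stats::setNames(signs * effect_size, gene_ids[de_idx])

  cor_blocks <- NULL
  make_noise <- function() {
    eps <- matrix(stats::rnorm(n_genes * n), n_genes, n)
    if (within_set_cor > 0) {
      block <- ceiling(seq_len(n_genes) / cor_block_size)
      z <- matrix(stats::rnorm(max(block) * n), max(block), n)
      eps <- sqrt(within_set_cor) * z[block, , drop = FALSE] +
        sqrt(1 - within_set_cor) * eps
      cor_blocks <<- split(gene_ids, block)
      names(cor_blocks) <<- sprintf("block%03d", seq_along(cor_blocks))
    }
    eps
  }

  if (kind %in% c("log_intensity", "tpm")) {
    base <- stats::rnorm(n_genes, mean = 7, sd = 1)
    m <- base + make_noise()
    if (n_de > 0) m[de_idx, case] <- m[de_idx, case] + signs * effect_size
    if (kind == "tpm") {
      m <- 2^m
      m <- sweep(m, 2, 1e6 / colSums(m), `*`)
    }
  } else {
    mu <- stats::rlnorm(n_genes, meanlog = 4, sdlog = 1)
    libf <- stats::runif(n, 0.7, 1.3)
    mu_mat <- outer(mu, libf)
    if (n_de > 0)
      mu_mat[de_idx, case] <- mu_mat[de_idx, case] * 2^(signs * effect_size)
    m <- if (phi > 0) {
      matrix(stats::rnbinom(n_genes * n, mu = mu_mat, size = 1 / phi),
             n_genes, n)
    } else {
      matrix(stats::rpois(n_genes * n, lambda = mu_mat), n_genes, n)
    }
    if (within_set_cor > 0)
      warning("within_set_cor is ignored for kind = \"counts\"")
  }
  dimnames(m) <- list(gene_ids, sample_ids)
  ds <- expression_dataset(m, groups, kind = kind)
  list(dataset = ds,
       truth = .simulation_truth(gene_ids[de_idx], effects,
                                 seed = seed, cor_blocks = cor_blocks))
}

#' Sample random gene sets of fixed size
#'
#' Draws `count` sets, each a uniform sample without replacement from the
#' gene universe, as used for gene-set-size dependency assays.
#'
#' @param universe Character vector of gene ids.
#' @param size Genes per set; must not exceed `length(universe)`.
#' @param count Number of sets.
#' @param seed Integer seed.
#' @return A `GeneSetCollection` of `count` sets named `rs<size>_<i>`.
#' @export
sample_random_sets <- function(universe, size, count, seed = 1L) {
  universe <- as.character(universe)
  if (size > length(universe))
    stop("`size` (", size, ") exceeds universe size (", length(universe), ")")
  if (size < 1 || count < 1) stop("`size` and `count` must be >= 1")
  set.seed(seed)
  sets <- lapply(seq_len(count), function(i) sample(universe, size))
  names(sets) <- sprintf("rs%d_%03d", size, seq_len(count))
  gene_set_collection(sets, sprintf("random set of size %d", size))
}

#' Build a full benchmark scenario on top of a simulated dataset
#'
#' Creates a gene set collection with a controlled fraction of truly
#' enriched sets plus a phenotype relevance ranking that tracks the true
#' DE content of each set. Enriched sets draw a proportion
#' `enrich_prop` of their genes from the planted DE genes; the remaining
#' sets are uniform draws from the universe (and therefore contain DE
#' genes only at the background rate). Relevance scores are
#' `10 * (true DE fraction of the set)` plus half-normal noise with scale
#' `relevance_noise`, so the relevance ranking is informative but
#' imperfect, mimicking literature-derived disease rankings.
#'
#' @param dataset An `ExpressionDataset` from [simulate_expression()].
#' @param truth The matching `SimulationTruth`.
#' @param n_sets Number of gene sets.
#' @param set_size_range Integer vector `c(min, max)` of set sizes.
#' @param frac_enriched Fraction of sets planted as truly enriched.
#' @param enrich_prop Proportion of an enriched set's genes drawn from
#'   the DE genes.
#' @param relevance_noise SD of the half-normal relevance noise; 0 makes
#'   the relevance ranking order sets exactly by true DE fraction.
#' @param seed Integer seed.
#' @return A list with `collection`, `relevance`, and `truth` (updated
#'   with `enriched_sets`).
#' @export
make_scenario <- function(dataset, truth, n_sets = 50L,
                          set_size_range = c(10L, 60L),
                          frac_enriched = 0.2, enrich_prop = 0.6,
                          relevance_noise = 1, seed = 1L) {
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(truth, "SimulationTruth"))
  if (relevance_noise < 0) stop("`relevance_noise` must be >= 0")
  universe <- rownames(dataset$matrix)
  de <- intersect(truth$de_genes, universe)
  n_enr <- round(frac_enriched * n_sets)
  if (n_enr > 0 && length(de) == 0)
    stop("frac_enriched > 0 requires a truth with non-empty de_genes")
  set.seed(seed)
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                  replace = TRUE)
  non_de <- setdiff(universe, de)
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    if (i <= n_enr) {
      k <- min(round(enrich_prop * sizes[i]), length(de))
      sets[[i]] <- c(sample(de, k),
                     sample(non_de, sizes[i] - k))
    } else {
      sets[[i]] <- sample(universe, sizes[i])
    }
  }
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  coll <- gene_set_collection(
    sets, ifelse(seq_len(n_sets) <= n_enr, "enriched", "background"))
  de_frac <- vapply(coll, function(s) mean(s %in% de), 0)
  scores <- 10 * de_frac + abs(stats::rnorm(n_sets, 0, relevance_noise))
  if (!any(scores > 0)) scores[1] <- .Machine$double.eps  # degenerate all-zero case
  relevance <- relevance_ranking(stats::setNames(scores, names(coll)),
                                 phenotype = "synthetic")
  truth$enriched_sets <- names(coll)[seq_len(n_enr)]
  list(collection = coll, relevance = relevance, truth = truth)
}

#' True DE-fraction oracle ranking for a scenario
#'
#' Ranks gene sets by the fraction of planted DE genes they contain --
#' the best ranking achievable with knowledge of the simulation truth.
#' Useful as an upper-reference "method" in benchmark comparisons.
#'
#' @param collection A `GeneSetCollection`.
#' @param truth A `SimulationTruth`.
#' @return A [score_ranking()] with orientation `"larger"`.
#' @export
oracle_ranking <- function(collection, truth) {
  de_frac <- vapply(collection, function(s) mean(s %in% truth$de_genes), 0)
  score_ranking(stats::setNames(de_frac, names(collection)), "larger")
}
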