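#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment, delegating to
#' [stats::p.adjust()] after validating the input range. Adjusted values
#' are monotone in the sorted order and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Estimate a common negative-binomial dispersion
#'
#' Method-of-moments estimate of a single dispersion phi shared across
#' genes: counts are scaled to a common library size, within-group means
#' and variances are pooled per gene, and phi_g = (v - m) / m^2 is
#' summarized by its median over informative genes, clipped at 0.
#'
#' @param dataset An `ExpressionDataset` with `kind = "counts"`.
#' @return A single non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (dataset$kind != "counts")
    stop("common dispersion is defined for count data (kind = \"counts\")")
  x <- dataset$matrix
  lib <- colSums(x)
  if (any(lib == 0))
    stop("all-zero sample(s): ",
         paste(colnames(x)[lib == 0], collapse = ", "))
  y <- sweep(x, 2, mean(lib) / lib, `*`)
  g <- dataset$groups
  i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(y[, i1, drop = FALSE]); m2 <- rowMeans(y[, i2, drop = FALSE])
  v1 <- .row_vars(y[, i1, drop = FALSE], m1)
  v2 <- .row_vars(y[, i2, drop = FALSE], m2)
  v <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  m <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ok <- m > 0
  if (!any(ok)) return(0)
  phi_g <- (v[ok] - m[ok]) / m[ok]^2
  max(0, stats::median(phi_g))
}

.row_vars <- function(x, means = rowMeans(x)) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  (rowSums(x^2) - n * means^2) / (n - 1)
}

#' Variance-stabilizing log-CPM transformation of counts
#'
#' Computes moderated log2 counts-per-million via [edgeR::cpm()]. With
#' `prior_count = "auto"` the prior is set to `0.5 / phi` using the
#' common-dispersion estimate, which stabilizes the variance of NB counts
#' enough for microarray-era t-like statistics to apply; a dispersion
#' estimate below 0.01 is clipped to 0.01 so the prior stays finite.
#'
#' @param dataset An `ExpressionDataset` with `kind = "counts"`.
#' @param prior_count Positive prior count, or `"auto"` for `0.5 / phi`.
#' @return An `ExpressionDataset` with `kind = "log_intensity"` carrying
#'   the transformed matrix; the chosen prior is stored in attribute
#'   `prior_count`.
#' @export
log_cpm_transform <- function(dataset, prior_count = "auto") {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (dataset$kind != "counts")
    stop("log_cpm_transform expects kind = \"counts\"")
  lib <- colSums(dataset$matrix)
  if (any(lib == 0))
    stop("all-zero sample(s): ",
         paste(colnames(dataset$matrix)[lib == 0], collapse = ", "))
  if (identical(prior_count, "auto")) {
    phi <- max(estimate_common_dispersion(dataset), 0.01)
    prior_count <- 0.5 / phi
  }
  if (!is.numeric(prior_count) || prior_count <= 0)
    stop("`prior_count` must be a positive number or \"auto\"")
  lc <- edgeR::cpm(dataset$matrix, log = TRUE, prior.count = prior_count,
                   lib.size = lib)
  dimnames(lc) <- dimnames(dataset$matrix)
  out <- expression_dataset(lc, dataset$groups, dataset$blocks,
                            kind = "log_intensity")
  attr(out, "prior_count") <- prior_count
  out
}

# Coerce any dataset to the log scale the t-like statistics expect.
# counts -> log-CPM (auto prior); tpm -> log2(tpm + 1).
.as_log_expression <- function(dataset, prior_count = "auto") {
  switch(dataset$kind,
    log_intensity = dataset,
    counts = log_cpm_transform(dataset, prior_count),
    tpm = expression_dataset(log2(dataset$matrix + 1), dataset$groups,
                             dataset$blocks, kind = "log_intensity"))
}

# Two-group first and second moments from a precomputed squared matrix;
# the workhorse of every permutation loop.
.two_group_moments <- function(x, x2, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- (rowSums(x2[, i1, drop = FALSE]) - n1 * m1^2) / (n1 - 1)
  v2 <- (rowSums(x2[, i2, drop = FALSE]) - n2 * m2^2) / (n2 - 1)
  list(m1 = m1, m2 = m2, v1 = pmax(v1, 0), v2 = pmax(v2, 0),
       n1 = n1, n2 = n2)
}

# Per-gene statistic vectors used both by gene_level_stats() and inside
# method permutation loops. Each returns list(stat, df, p or NULL).
.stat_core <- function(mom, statistic) {
  n1 <- mom$n1; n2 <- mom$n2
  d <- mom$m1 - mom$m2
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * mom$v1 + (n2 - 1) * mom$v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  switch(statistic,
    logfc = list(stat = d, p = NULL, df = df),
    ordinary_t = {
      t <- d / se
      list(stat = t, p = 2 * stats::pt(-abs(t), df), df = df)
    },
    s2n = list(stat = d / (sqrt(mom$v1) + sqrt(mom$v2)), p = NULL, df = df),
    sam_t = {
      s0 <- stats::median(se[is.finite(se)], na.rm = TRUE)
      list(stat = d / (se + s0), p = NULL, df = df, s0 = s0)
    },
    moderated_t = {
      sq <- limma::squeezeVar(sp2, df = df)
      dft <- df + sq$df.prior
      t <- d / sqrt(sq$var.post * (1 / n1 + 1 / n2))
      list(stat = t, p = 2 * stats::pt(-abs(t), dft), df = dft)
    },
    stop("unknown statistic: ", statistic))
}

# Paired versions operate on within-block differences (one sample per
# group per block); reduces to one-sample forms of the same statistics.
.paired_diffs <- function(dataset) {
  b <- dataset$blocks
  if (is.null(b)) stop("paired statistics require `blocks`")
  g <- dataset$groups
  tab <- table(b, g)
  if (any(tab != 1L))
    stop("paired analysis requires exactly one sample per group per block")
  l1 <- levels(g)[1]; l2 <- levels(g)[2]
  blocks <- levels(b)
  i1 <- vapply(blocks, function(bl) which(b == bl & g == l1), 0L)
  i2 <- vapply(blocks, function(bl) which(b == bl & g == l2), 0L)
  dataset$matrix[, i1, drop = FALSE] - dataset$matrix[, i2, drop = FALSE]
}

.stat_core_paired <- function(d, statistic) {
  nb <- ncol(d)
  md <- rowMeans(d)
  vd <- .row_vars(d, md)
  df <- nb - 1
  se <- sqrt(vd / nb)
  switch(statistic,
    logfc = list(stat = md, p = NULL, df = df),
    ordinary_t = {
      t <- md / se
      list(stat = t, p = 2 * stats::pt(-abs(t), df), df = df)
    },
    s2n = list(stat = md / sqrt(vd), p = NULL, df = df),
    sam_t = {
      s0 <- stats::median(se[is.finite(se)], na.rm = TRUE)
      list(stat = md / (se + s0), p = NULL, df = df, s0 = s0)
    },
    moderated_t = {
      sq <- limma::squeezeVar(vd, df = df)
      dft <- df + sq$df.prior
      t <- md / sqrt(sq$var.post / nb)
      list(stat = t, p = 2 * stats::pt(-abs(t), dft), df = dft)
    },
    stop("unknown statistic: ", statistic))
}

#' Gene-level differential expression statistics
#'
#' Computes a per-gene two-group statistic on the log scale. Count data
#' are first variance-stabilized via [log_cpm_transform()] and TPMs are
#' log2(x+1)-transformed. When the dataset carries `blocks` and
#' `paired = TRUE` (the default in that case), statistics are computed on
#' within-block paired differences.
#'
#' Available statistics: `ordinary_t` (pooled-variance two-sample t),
#' `moderated_t` (empirical-Bayes shrunken variances), `sam_t`
#' (t with additive fudge constant `s0` = median standard error), `s2n`
#' (signal-to-noise, mean difference over the sum of group SDs) and
#' `logfc` (mean log2 difference). Differences are reported as first
#' group level minus second. Genes with zero variance in both groups get
#' `NA` statistics and are flagged with a warning.
#'
#' @param dataset An `ExpressionDataset`.
#' @param statistic Statistic name (see Details).
#' @param paired Use paired differences; defaults to TRUE when the
#'   dataset has blocks.
#' @return A data.frame (`gene`, `stat`, `p`, `logfc`) with attributes
#'   `statistic`, `df` and `flagged` (ids of zero-variance genes).
#'   `p` is `NA` for statistics without a parametric reference
#'   distribution (`s2n`, `sam_t`, `logfc`).
#' @export
gene_level_stats <- function(dataset,
                             statistic = c("ordinary_t", "moderated_t",
                                           "sam_t", "s2n", "logfc"),
                             paired = !is.null(dataset$blocks)) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  statistic <- match.arg(statistic)
  dataset <- .as_log_expression(dataset)
  g <- dataset$groups
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  x <- dataset$matrix
  if (paired) {
    d <- .paired_diffs(dataset)
    res <- .stat_core_paired(d, statistic)
    lfc <- rowMeans(d)
    zero <- .row_vars(d) == 0
  } else {
    i1 <- which(g == levels(g)[1]); i2 <- which(g == levels(g)[2])
    mom <- .two_group_moments(x, x^2, i1, i2)
    res <- .stat_core(mom, statistic)
    lfc <- mom$m1 - mom$m2
    zero <- (mom$v1 + mom$v2) == 0
  }
  stat <- res$stat
  p <- if (is.null(res$p)) rep(NA_real_, nrow(x)) else res$p
  flagged <- rownames(x)[zero]
  if (length(flagged)) {
    warning(length(flagged),
            " zero-variance gene(s) flagged and excluded from ranking")
    stat[zero] <- NA_real_
    p[zero] <- NA_real_
  }
  out <- data.frame(gene = rownames(x), stat = stat, p = p, logfc = lfc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, statistic = statistic, df = res$df, flagged = flagged)
}

#' Call differentially expressed genes
#'
#' Applies the customary dual criterion: BH-adjusted p below
#' `fdr_threshold` and, with `criterion = "both"`, absolute log2 fold
#' change above `lfc_threshold`.
#'
#' @param stats A data.frame from [gene_level_stats()] with non-missing
#'   `p` (and `logfc` when `criterion = "both"`).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1).
#' @param fdr_threshold BH-adjusted p cutoff (default 0.05).
#' @param criterion `"both"` (fold change and FDR) or `"p_only"`.
#' @return Character vector of gene ids passing the criterion.
#' @export
call_de_genes <- function(stats, lfc_threshold = 1, fdr_threshold = 0.05,
                          criterion = c("both", "p_only")) {
  criterion <- match.arg(criterion)
  if (!all(c("gene", "p") %in% names(stats)))
    stop("`stats` must contain columns gene and p")
  ok <- !is.na(stats$p)
  adj <- rep(NA_real_, nrow(stats))
  adj[ok] <- bh_adjust(stats$p[ok])
  pass <- !is.na(adj) & adj < fdr_threshold
  if (criterion == "both") {
    if (!"logfc" %in% names(stats) || all(is.na(stats$logfc)))
      stop("criterion = \"both\" requires a logfc column")
    pass <- pass & !is.na(stats$logfc) & abs(stats$logfc) > lfc_threshold
  }
  stats$gene[pass]
}

#' Export a gene statistic table as TSV
#' @param stats Output of [gene_level_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_stats <- function(stats, path) {
  ok <- !is.na(stats$p)
  stats$adj_p <- NA_real_
  stats$adj_p[ok] <- bh_adjust(stats$p[ok])
  utils::write.table(stats[, c("gene", "stat", "p", "adj_p", "logfc")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
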