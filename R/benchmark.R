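# Benchmark driver: every configured method on every dataset, collecting
# runtime, significance fractions, relevance results and optional null
# p-values into one report.

#' Run the full method x dataset benchmark
#'
#' For every combination of method and dataset, runs the method, records
#' wall-clock runtime, the fractions of nominally and FDR-significant
#' sets, the relevance score `X`, its optimum `O`, the relative score
#' `X_bar`, and (optionally) the random-ranking and label-permutation
#' null p-values. A method failing on one dataset yields an NA row and
#' the run continues.
#'
#' @param datasets Named list; each element is a list with `dataset`,
#'   `collection`, `relevance` (a scenario as returned by
#'   [read_scenario()] or [make_scenario()] plus its dataset).
#' @param methods Character vector of method names (default: all
#'   implemented methods).
#' @param n_perm Permutations inside permutation methods.
#' @param seed Integer seed.
#' @param alpha Significance level for the fraction columns.
#' @param with_random_null Compute the random-ranking null p-value.
#' @param with_label_null Compute the label-permutation null p-value
#'   (costly: re-runs each method `n_label_perm` times per dataset).
#' @param n_random,n_label_perm Null sizes.
#' @return A `BenchmarkReport`: data.frame with one row per method x
#'   dataset.
#' @export
run_benchmark <- function(datasets,
                          methods = ea_methods()$name,
                          n_perm = 1000L, seed = 1L, alpha = 0.05,
                          with_random_null = TRUE,
                          with_label_null = FALSE,
                          n_random = 1000L, n_label_perm = 100L) {
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("dataset%02d", seq_along(datasets))
  reg <- ea_methods()
  bad <- setdiff(methods, reg$name)
  if (length(bad)) stop("unknown/unimplemented method(s): ",
                        paste(bad, collapse = ", "))
  rows <- list()
  for (dn in names(datasets)) {
    sc <- datasets[[dn]]
    for (mth in methods) {
      row <- data.frame(method = mth,
                        hypothesis = reg$hypothesis[reg$name == mth],
                        dataset = dn, runtime = NA_real_,
                        frac_nominal = NA_real_, frac_fdr = NA_real_,
                        X = NA_real_, O = NA_real_, X_bar = NA_real_,
                        p_random = NA_real_, p_labelperm = NA_real_,
                        error = NA_character_, stringsAsFactors = FALSE)
      res <- tryCatch({
        el <- runtime_profile(mth, sc$dataset, sc$collection,
                              n_perm = n_perm, seed = seed)
        rk <- attr(el, "ranking")
        rel <- suppressMessages(optimal_and_relative(rk, sc$relevance))
        row$runtime <- as.numeric(el)
        row$frac_nominal <- significance_fraction(rk, alpha)
        row$frac_fdr <- significance_fraction(rk, alpha, adjusted = TRUE)
        row$X <- rel$X; row$O <- rel$O; row$X_bar <- rel$X_bar
        if (with_random_null)
          row$p_random <- as.numeric(suppressMessages(
            random_ranking_pvalue(rk, sc$relevance, n_random, seed)))
        if (with_label_null)
          row$p_labelperm <- as.numeric(suppressMessages(
            label_permutation_pvalue(mth, sc$dataset, sc$collection,
                                     sc$relevance, n_perm = n_label_perm,
                                     seed = seed,
                                     method_n_perm = n_perm)))
        TRUE
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("method '", mth, "' failed on dataset '", dn, "': ",
                conditionMessage(res))
        row$error <- conditionMessage(res)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(report,
            params = list(n_perm = n_perm, seed = seed, alpha = alpha,
                          n_random = n_random,
                          with_label_null = with_label_null),
            class = c("BenchmarkReport", "data.frame"))
}

#' Write a benchmark report as TSV + JSON with provenance
#'
#' The JSON carries a provenance block (package version, seed and
#' parameters) alongside the rows so a run can be reproduced.
#'
#' @param report A `BenchmarkReport`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  stopifnot(inherits(report, "BenchmarkReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(report), file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(provenance = c(list(package = "eabench",
                             version = as.character(utils::packageVersion("eabench")),
                             date = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                        attr(report, "params")),
         results = as.data.frame(report)),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(dir)
}
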