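test_that("significance_fraction counts nominal and adjusted calls", {
  ds <- toy_dataset(n_genes = 40, n_per_group = 4, seed = 55)
  coll <- toy_collection(rownames(ds$matrix), c(5, 7, 9))
  rk <- run_camera(ds, coll)
  rk$p_value <- c(0.01, 0.2, 0.03)
  rk$adj_p <- bh_adjust(rk$p_value)
  expect_equal(significance_fraction(rk, 0.05), 2 / 3)
  expect_equal(significance_fraction(rk, alpha = 1), 1)
  # nominal fraction >= adjusted fraction (BH monotonicity)
  set.seed(5)
  for (i in 1:50) {
    rk$p_value <- runif(3)
    rk$adj_p <- bh_adjust(rk$p_value)
    expect_gte(significance_fraction(rk, 0.05),
               significance_fraction(rk, 0.05, adjusted = TRUE))
  }
})

test_that("type-I error assay returns per-shuffle fractions with sane summaries", {
  sim <- simulate_expression(200, 5, de_fraction = 0, seed = 61)
  coll <- sample_random_sets(rownames(sim$dataset$matrix), 10, 20, seed = 62)
  res <- type_one_error_assay("camera", sim$dataset, coll,
                              n_shuffles = 20, seed = 63)
  expect_s3_class(res, "AssayResult")
  expect_length(res$fractions$shuffle, 20L)
  expect_true(all(res$fractions$shuffle >= 0 & res$fractions$shuffle <= 1))
  expect_equal(res$mean[["shuffle"]], mean(res$fractions$shuffle))
  expect_error(type_one_error_assay("camera", sim$dataset, coll,
                                    n_shuffles = 5), ">= 10")
  tab <- assay_table(res)
  expect_identical(nrow(tab), 20L)
  expect_identical(unique(tab$method), "camera")
})

test_that("self-contained statistics show right-skewed shuffle fractions on DE-heavy data", {
  sim <- simulate_expression(400, 8, de_fraction = 0.5, effect_size = 1.2,
                             seed = 64)
  coll <- sample_random_sets(rownames(sim$dataset$matrix), 25, 20, seed = 65)
  res <- suppressWarnings(
    type_one_error_assay("samgs", sim$dataset, coll, n_shuffles = 40,
                         seed = 66, n_perm = 60))
  fr <- res$fractions$shuffle
  skew <- mean((fr - mean(fr))^3) / stats::sd(fr)^3
  expect_gt(skew, 0)
})

test_that("random-set-size assay uses the canonical size grid and runs per size", {
  expect_identical(formals(random_set_size_assay)$sizes,
                   quote(c(5L, 10L, 25L, 50L, 100L, 250L, 500L)))
  sim <- simulate_expression(300, 4, de_fraction = 0, seed = 71)
  res <- suppressWarnings(
    random_set_size_assay("ora", sim$dataset, sizes = c(5, 10, 25),
                          n_sets = 15, seed = 72))
  expect_identical(names(res$mean), c("5", "10", "25"))
  expect_true(all(unlist(res$fractions) >= 0 & unlist(res$fractions) <= 1))
  expect_error(random_set_size_assay("ora", sim$dataset, sizes = 400),
               "universe")
})

test_that("runtime profile reports elapsed seconds and scales with permutations", {
  ds <- toy_dataset(n_genes = 200, n_per_group = 5, seed = 73)
  coll <- toy_collection(rownames(ds$matrix), rep(10, 10))
  el <- runtime_profile("samgs", ds, coll, n_perm = 50, seed = 1)
  expect_gte(as.numeric(el), 0)
  expect_s3_class(attr(el, "ranking"), "EARanking")
  t_small <- as.numeric(runtime_profile("samgs", ds, coll, n_perm = 100))
  t_big <- as.numeric(runtime_profile("samgs", ds, coll, n_perm = 1600))
  # ~linear in n_perm: 16x the permutations cost clearly more
  expect_gt(t_big, 3 * t_small)
})

test_that("aggregate_compare summarizes groups and runs rank-sum tests", {
  res <- data.frame(
    method = rep(c("a", "b"), each = 10),
    hypothesis = rep(c("competitive", "self_contained"), each = 10),
    X_bar = c(rep(0.9, 10), rep(0.1, 10)))
  out <- aggregate_compare(res, "hypothesis_type")
  expect_identical(out$group, c("competitive", "self_contained"))
  expect_equal(out$median, c(0.9, 0.1))
  expect_lt(attr(out, "pairwise_p")["competitive", "self_contained"], 0.001)
  # identical vectors -> maximal p for the tie convention
  res2 <- res; res2$X_bar <- rep(0.5, 20)
  out2 <- suppressWarnings(aggregate_compare(res2, "method"))
  expect_gt(attr(out2, "pairwise_p")["a", "b"], 0.99)
  expect_error(aggregate_compare(res[res$method == "a", ], "method"),
               "2 groups")
})

test_that("benchmark driver produces one row per method x dataset and survives failures", {
  mk <- function(seed) {
    sim <- simulate_expression(150, 4, de_fraction = 0.2, seed = seed)
    sc <- make_scenario(sim$dataset, sim$truth, n_sets = 10,
                        set_size_range = c(5, 15), seed = seed)
    list(dataset = sim$dataset, collection = sc$collection,
         relevance = sc$relevance)
  }
  datasets <- list(d1 = mk(1), d2 = mk(2))
  rep <- suppressWarnings(
    run_benchmark(datasets, methods = c("ora", "samgs"), n_perm = 30,
                  seed = 1, n_random = 50))
  expect_s3_class(rep, "BenchmarkReport")
  expect_identical(nrow(rep), 4L)
  ok <- !is.na(rep$X_bar)
  expect_true(all(rep$X_bar[ok] >= 0 & rep$X_bar[ok] <= 1))
  expect_true(all(rep$p_random[ok] > 0 & rep$p_random[ok] <= 1))
  # determinism end to end
  rep2 <- suppressWarnings(
    run_benchmark(datasets, methods = c("ora", "samgs"), n_perm = 30,
                  seed = 1, n_random = 50))
  expect_equal(rep[, setdiff(names(rep), "runtime")],
               rep2[, setdiff(names(rep2), "runtime")])
  # a failing method yields an NA row, not an aborted run
  bad <- datasets
  bad$d2$collection <- gene_set_collection(list(alien = c("x1", "x2")))
  rep3 <- suppressWarnings(
    run_benchmark(bad, methods = "ora", n_perm = 10, seed = 1,
                  n_random = 20))
  expect_identical(nrow(rep3), 2L)
  expect_true(any(is.na(rep3$X_bar)))
  expect_true(any(!is.na(rep3$X_bar)))
})

test_that("benchmark report serialization carries provenance", {
  sim <- simulate_expression(120, 4, de_fraction = 0.2, seed = 5)
  sc <- make_scenario(sim$dataset, sim$truth, n_sets = 8,
                      set_size_range = c(5, 12), seed = 5)
  rep <- suppressWarnings(run_benchmark(
    list(d = list(dataset = sim$dataset, collection = sc$collection,
                  relevance = sc$relevance)),
    methods = "camera", n_random = 20, seed = 5))
  dir <- withr::local_tempdir()
  write_benchmark_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.tsv")))
  js <- jsonlite::read_json(file.path(dir, "report.json"),
                            simplifyVector = TRUE)
  expect_identical(js$provenance$package, "eabench")
  expect_identical(js$provenance$seed, 5L)
  expect_identical(nrow(js$results), 1L)
})
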