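test_that("rank-to-weight transformation handles ties via the extremeness fraction", {
  # tie-free p-values: w = 1 - r_A/N
  expect_equal(ranks_to_weights(c(0.01, 0.1, 0.5, 0.9), "smaller"),
               c(0.75, 0.5, 0.25, 0))
  # one tie group
  expect_equal(ranks_to_weights(c(0.01, 0.2, 0.2, 0.9), "smaller"),
               c(0.75, 0.25, 0.25, 0))
  # all equal -> all weights 0
  expect_equal(ranks_to_weights(rep(0.3, 5), "smaller"), rep(0, 5))
  # orientation flips for score-like statistics
  expect_equal(ranks_to_weights(c(5, 4, 3, 2), "larger"),
               c(0.75, 0.5, 0.25, 0))
  expect_error(ranks_to_weights(numeric(0)), "non-empty")
  # weights always in [0,1]; tie-free weights sum to (N-1)/2
  set.seed(3)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    w <- ranks_to_weights(sample(seq_len(100), n), "larger")
    expect_true(all(w >= 0 & w <= 1))
    expect_equal(sum(w), (n - 1) / 2)
  }
})

test_that("relevance score is the weight-by-relevance dot product", {
  rel <- relevance_ranking(c(A = 10, B = 5, C = 0, D = 0))
  rk <- score_ranking(c(A = 4, B = 3, C = 2, D = 1), "larger")
  expect_equal(relevance_score(rk, rel), 0.75 * 10 + 0.5 * 5)  # X = 10
  res <- optimal_and_relative(rk, rel)
  expect_equal(res$O, 10)
  expect_equal(res$X_bar, 1)
  # fully reversed ranking
  rev_rk <- score_ranking(c(A = 1, B = 2, C = 3, D = 4), "larger")
  res_rev <- optimal_and_relative(rev_rk, rel)
  expect_equal(res_rev$X, 1.25)
  expect_equal(res_rev$X_bar, 0.125)
  # incremental vs brute-force dot product on random instances
  set.seed(8)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    s <- abs(rnorm(n)); names(s) <- paste0("S", seq_len(n))
    p <- runif(n); names(p) <- names(s)
    rkp <- score_ranking(p, "smaller")
    w <- 1 - vapply(p, function(x) mean(p <= x), 0)
    expect_equal(suppressMessages(relevance_score(rkp, relevance_ranking(s))),
                 sum(w * s), tolerance = 1e-12)
  }
})

test_that("top-fraction truncation zeroes weights below the cutoff", {
  rel <- relevance_ranking(c(A = 10, B = 5, C = 2, D = 1))
  rk <- score_ranking(c(A = 4, B = 3, C = 2, D = 1), "larger")
  # top 25% keeps only A's weight (0.75); the rest are zeroed
  expect_equal(relevance_score(rk, rel, top_fraction = 0.25), 0.75 * 10)
  expect_equal(relevance_score(rk, rel, top_fraction = 1),
               0.75 * 10 + 0.5 * 5 + 0.25 * 2)
  res <- optimal_and_relative(rk, rel, top_fraction = 0.25)
  expect_equal(res$X_bar, 1)  # ranking matches relevance order in its top
  expect_error(relevance_score(rk, rel, top_fraction = 0), "top_fraction")
})

test_that("sets absent from one side are dropped and weights recomputed", {
  rel <- relevance_ranking(c(A = 3, B = 1, Z = 7))
  rk <- score_ranking(c(A = 0.01, B = 0.5, Q = 0.2), "smaller")
  expect_message(x <- relevance_score(rk, rel), "dropped")
  # shared = {A, B}; weights recomputed on 2 sets: A -> 0.5, B -> 0
  expect_equal(x, 0.5 * 3)
  only <- score_ranking(c(Q = 0.1), "smaller")
  expect_error(suppressMessages(relevance_score(only, rel)), "share no")
})

test_that("X never exceeds the optimum and equals it only for matching order", {
  set.seed(9)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    s <- sort(stats::runif(n, 0, 10), decreasing = TRUE)  # tie-free a.s.
    names(s) <- paste0("S", seq_len(n))
    perm <- sample(n)
    rk <- score_ranking(stats::setNames(rank(-perm), names(s)), "larger")
    res <- suppressWarnings(optimal_and_relative(rk, relevance_ranking(s)))
    expect_lte(res$X, res$O + 1e-12)
    expect_true(res$X_bar >= 0 && res$X_bar <= 1 + 1e-12)
  }
})

test_that("random-ranking null matches exhaustive enumeration for small N", {
  rel <- relevance_ranking(c(A = 2, B = 1, C = 0))
  best <- score_ranking(c(A = 3, B = 2, C = 1), "larger")
  p <- random_ranking_pvalue(best, rel)
  expect_true(attr(p, "exhaustive"))
  expect_equal(as.numeric(p), 1 / 6)
  worst <- score_ranking(c(A = 1, B = 2, C = 3), "larger")
  expect_equal(as.numeric(random_ranking_pvalue(worst, rel)), 1)
  # mean of enumerated scores obeys the ((N-1)/(2N)) * sum(S) identity
  expect_equal(mean(attr(p, "null_scores")), (3 - 1) / (2 * 3) * 3)
  for (n in 3:6) {
    s <- stats::setNames(stats::runif(n, 0, 5), paste0("S", 1:n))
    s[1] <- s[1] + 1  # ensure positivity
    rk <- score_ranking(s, "larger")
    pv <- random_ranking_pvalue(rk, relevance_ranking(s))
    expect_equal(mean(attr(pv, "null_scores")),
                 (n - 1) / (2 * n) * sum(s), tolerance = 1e-12)
    expect_equal(mean(attr(pv, "null_scores")),
                 enumerate_mean_relevance(as.numeric(s)), tolerance = 1e-12)
  }
})

test_that("sampled random-ranking null uses the add-one convention and calibrates", {
  set.seed(10)
  s <- stats::setNames(runif(30, 0, 10), paste0("S", 1:30))
  rel <- relevance_ranking(s)
  rk <- score_ranking(stats::setNames(rnorm(30), names(s)), "larger")
  p <- random_ranking_pvalue(rk, rel, n_random = 99, seed = 5)
  expect_false(attr(p, "exhaustive"))
  expect_true(p > 0 && p <= 1)
  expect_equal((as.numeric(p) * 100) %% 1, 0, tolerance = 1e-9)  # p = (b+1)/100
})

test_that("label-permutation null is calibrated on null data and powered on signal", {
  # calibration: p approximately uniform over replicate null datasets
  ps <- vapply(1:30, function(i) {
    sim <- simulate_expression(150, 4, de_fraction = 0, seed = 700 + i)
    coll <- sample_random_sets(rownames(sim$dataset$matrix), 10, 8,
                               seed = 700 + i)
    rel <- relevance_ranking(stats::setNames(
      abs(rnorm(8)) + 0.01, names(coll)))
    as.numeric(label_permutation_pvalue("camera", sim$dataset, coll, rel,
                                        n_perm = 39, seed = 700 + i))
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  # power: strong embedded enrichment + noise-free relevance
  hits <- 0L
  for (i in 1:10) {
    sim <- simulate_expression(300, 8, de_fraction = 0.2, effect_size = 2,
                               seed = 800 + i)
    sc <- make_scenario(sim$dataset, sim$truth, n_sets = 20,
                        frac_enriched = 0.3, enrich_prop = 0.8,
                        relevance_noise = 0, seed = 800 + i)
    p <- label_permutation_pvalue("ora", sim$dataset, sc$collection,
                                  sc$relevance, n_perm = 19, seed = 800 + i)
    if (p <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
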