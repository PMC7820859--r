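test_that("ORA reproduces exact hypergeometric tails", {
  # universe 10, 5 DE, set of 2 genes both DE -> C(5,2)/C(10,2) = 10/45
  uni <- paste0("g", 1:10)
  de <- uni[1:5]
  coll <- gene_set_collection(list(bothde = uni[1:2],
                                   none = uni[9:10]))
  rk <- run_ora(de, uni, coll)
  expect_equal(rk$p_value[rk$set_id == "bothde"], 10 / 45,
               tolerance = 1e-12)
  expect_equal(rk$p_value[rk$set_id == "none"], 1)
  # universe 4, 2 DE, singleton DE set -> 0.5
  rk2 <- run_ora(paste0("g", 1:2), paste0("g", 1:4),
                 gene_set_collection(list(s = "g1")))
  expect_equal(rk2$p_value, 0.5)
  expect_error(run_ora(character(0), uni, coll), "fallback")
  expect_error(run_ora(de, character(0), coll), "universe")
})

test_that("adding non-DE background genes never raises an ORA overlap", {
  uni <- paste0("g", 1:20)
  de <- uni[1:6]
  coll <- toy_collection(uni, c(4, 6, 8), seed = 3)
  rk <- run_ora(de, uni, coll)
  rk_big <- run_ora(de, c(uni, paste0("extra", 1:20)), coll)
  ov <- rk$statistic[order(rk$set_id)]
  ov_big <- rk_big$statistic[order(rk_big$set_id)]
  expect_identical(ov, ov_big)       # overlap counts unchanged
  expect_true(all(rk_big$p_value[order(rk_big$set_id)] <=
                  rk$p_value[order(rk$set_id)] + 1e-12))
})

test_that("GSEA running-sum ES matches the brute-force oracle", {
  # perfect separation, unweighted
  stat <- c(4, 3, 2, 1)
  names(stat) <- paste0("g", 1:4)
  expect_equal(eabench:::.gsea_es(stat, 1:2, exponent = 0), 1)
  expect_equal(eabench:::.gsea_es(stat, 3:4, exponent = 0), -1)
  # random toys, both exponents
  set.seed(44)
  for (i in 1:100) {
    N <- sample(10:60, 1)
    s <- rnorm(N)
    m <- sample(2:(N - 2), 1)
    idx <- sample(N, m)
    expo <- sample(c(0, 1), 1)
    expect_equal(eabench:::.gsea_es(s, idx, expo),
                 brute_force_es(s, idx, expo), tolerance = 1e-12)
  }
})

test_that("SAFE Wilcoxon global statistic follows rank arithmetic", {
  set.seed(9)
  m <- matrix(rnorm(10 * 8, sd = 0.2), 10, 8,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  m[1:3, 5:8] <- m[1:3, 5:8] + 50  # three set genes get the largest |t|
  ds <- expression_dataset(m, rep(c("a", "b"), each = 4))
  coll <- gene_set_collection(list(top = paste0("g", 1:3)))
  rk <- run_safe(ds, coll, n_perm = 20, seed = 1)
  expect_equal(rk$statistic, 8 + 9 + 10)  # maximal attainable rank sum
  # set = universe leaves no background
  expect_error(run_safe(ds, gene_set_collection(list(all = paste0("g", 1:10))),
                        n_perm = 5),
               "background")
})

test_that("swapping the SAFE local statistic changes only the local layer", {
  ds <- toy_dataset(n_genes = 40, n_per_group = 4, seed = 23)
  coll <- toy_collection(rownames(ds$matrix), c(5, 8))
  r_t <- run_safe(ds, coll, local_stat = "ordinary_t", n_perm = 30, seed = 2)
  r_m <- run_safe(ds, coll, local_stat = "moderated_t", n_perm = 30, seed = 2)
  expect_identical(r_t$set_id[order(r_t$set_id)],
                   r_m$set_id[order(r_m$set_id)])
  expect_identical(attr(r_m, "method"), "safe")
  # the global layer is still a rank sum over the same set sizes
  expect_setequal(r_m$size, r_t$size)
})

test_that("PADOG gene weights follow the frequency formula", {
  # frequencies 1..5 across sets
  w <- eabench:::.padog_weights(list(1L, c(1L, 2L)), 2)  # f = c(2, 1)
  expect_equal(w, c(1, 2))
  # membership lists giving genes 1..3 frequencies 1, 3, 5
  f <- c(1, 3, 5)
  sets <- lapply(1:5, function(s) which(f >= s))
  w <- eabench:::.padog_weights(sets, 3)
  expect_equal(w[1], 2.0)
  expect_equal(w[3], 1.0)
  expect_equal(w[2], 1 + sqrt((5 - 3) / (5 - 1)), tolerance = 1e-12)
  # degenerate: all frequencies equal -> all weights 1
  expect_equal(eabench:::.padog_weights(list(1:3, 1:3), 3), rep(1, 3))
})

test_that("CAMERA variance inflation and limits behave as designed", {
  # VIF arithmetic: m = 101, rho = 0.01 -> 2.0
  expect_equal(1 + (101 - 1) * 0.01, 2)
  ds <- toy_dataset(n_genes = 120, n_per_group = 5, seed = 31)
  coll <- toy_collection(rownames(ds$matrix), c(10, 20, 101))
  rk <- run_camera(ds, coll, inter_gene_cor = 0.01)
  rk0 <- run_camera(ds, coll, inter_gene_cor = 0)
  # rho = 0 reduces to an ordinary two-sample t between set and
  # background z-scores
  i <- which(rk0$set_id == "ts01")
  prep <- eabench:::.prepare_method_data(ds, coll)
  gi <- eabench:::.group_indices(prep$groups)
  mom <- eabench:::.two_group_moments(prep$x, prep$x2, gi$i1, gi$i2)
  res <- eabench:::.stat_core_safe(mom, "moderated_t")
  z <- limma::zscoreT(res$stat, df = res$df, approx = FALSE)
  idx <- prep$set_idx[["ts01"]]
  tt <- t.test(z[idx], z[-idx], var.equal = TRUE)
  expect_equal(rk0$statistic[i], unname(tt$statistic), tolerance = 1e-9)
  # inflation can only weaken evidence
  expect_true(all(rk$p_value[order(rk$set_id)] >=
                  rk0$p_value[order(rk0$set_id)] - 1e-12))
  expect_error(run_camera(ds, gene_set_collection(
    list(all = rownames(ds$matrix)))), "background")
  # singleton set is still defined
  single <- gene_set_collection(list(one = rownames(ds$matrix)[1]))
  expect_s3_class(run_camera(ds, single), "EARanking")
})

test_that("estimating inter-gene correlation guards CAMERA against correlated nulls", {
  rejections <- function(igc) {
    rej <- 0; tot <- 0
    for (i in 1:8) {
      sim <- simulate_expression(400, 10, de_fraction = 0,
                                 within_set_cor = 0.1, cor_block_size = 20,
                                 seed = 500 + i)
      coll <- gene_set_collection(sim$truth$cor_blocks)
      rk <- run_camera(sim$dataset, coll, inter_gene_cor = igc)
      rej <- rej + sum(rk$p_value < 0.05); tot <- tot + nrow(rk)
    }
    rej / tot
  }
  expect_lte(rejections("estimate"), rejections(0))
})

test_that("SAMGS statistic is a sum of squared SAM t values, monotone in set size", {
  ds <- toy_dataset(n_genes = 80, n_per_group = 5, seed = 37)
  # nested random sets
  set.seed(2)
  genes <- sample(rownames(ds$matrix), 40)
  nested <- gene_set_collection(list(s10 = genes[1:10], s20 = genes[1:20],
                                     s40 = genes[1:40]))
  rk <- run_samgs(ds, nested, n_perm = 10, seed = 1)
  st <- rk$statistic[match(c("s10", "s20", "s40"), rk$set_id)]
  expect_true(all(diff(st) >= 0))
  # statistic equals the sum of squared sam_t over set genes
  sam <- gene_level_stats(ds, "sam_t")
  expect_equal(rk$statistic[rk$set_id == "s10"],
               sum(sam$stat[match(genes[1:10], sam$gene)]^2),
               tolerance = 1e-9)
})

test_that("every method returns a complete, valid ranking and drops foreign sets", {
  ds <- toy_dataset(n_genes = 60, n_per_group = 4, seed = 41)
  coll <- toy_collection(rownames(ds$matrix), c(5, 8, 12))
  foreign <- gene_set_collection(c(unclass(coll),
                                   list(alien = c("nope1", "nope2"))))
  for (m in ea_methods()$name) {
    expect_warning(rk <- run_method(m, ds, foreign, n_perm = 30, seed = 2),
                   "dropped|no genes")
    expect_equal(nrow(rk), 3L)
    expect_true(all(rk$p_value > 0 & rk$p_value <= 1))
    expect_setequal(rk$rank, 1:3)
  }
})

test_that("registry stubs raise not-implemented errors", {
  ds <- toy_dataset()
  coll <- toy_collection(rownames(ds$matrix), 5)
  expect_true(all(c("globaltest", "gsa", "roast", "gsva") %in%
                  ea_methods(implemented_only = FALSE)$name))
  expect_error(run_method("roast", ds, coll), "not implemented")
  expect_error(run_method("gsva", ds, coll), "not implemented")
  reg <- ea_methods()
  expect_identical(reg$hypothesis[reg$name == "samgs"], "self_contained")
  expect_true(all(reg$hypothesis[reg$name %in%
    c("ora", "gsea", "safe", "padog", "camera")] == "competitive"))
})
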