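test_that("a feature identical across groups gets fc 0, t 0, p 1", {
  withr::with_seed(31, {
    m <- matrix(rnorm(20 * 8), nrow = 20,
                dimnames = list(sprintf("f%02d", 1:20), sprintf("s%d", 1:8)))
    m[1, ] <- rep(c(5, 6, 7, 5), 2) # same values in both groups
    es <- expression_set(m, data.frame(sample_id = colnames(m),
                                       group = rep(c("a", "b"), each = 4)))
  })
  tab <- moderated_t_table(es, "a", "b")
  expect_equal(tab$log2fc[1], 0, tolerance = 1e-12)
  expect_equal(tab$t_stat[1], 0, tolerance = 1e-12)
  expect_equal(tab$p_raw[1], 1, tolerance = 1e-12)
  expect_error(moderated_t_table(es, "a", "missing"), "2 samples")
})

test_that("without shrinkage the moderated test reduces to the pooled t-test", {
  withr::with_seed(32, {
    m <- matrix(rnorm(50 * 10, mean = 8), nrow = 50,
                dimnames = list(sprintf("f%02d", 1:50), sprintf("s%d", 1:10)))
    es <- expression_set(m, data.frame(sample_id = colnames(m),
                                       group = rep(c("a", "b"), c(4, 6))))
  })
  tab <- moderated_t_table(es, "a", "b", shrink = FALSE)
  for (i in c(1, 17, 50)) {
    tt <- t.test(m[i, 5:10], m[i, 1:4], var.equal = TRUE)
    expect_equal(tab$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab$p_raw[i], tt$p.value, tolerance = 1e-10)
    expect_equal(tab$log2fc[i], mean(m[i, 5:10]) - mean(m[i, 1:4]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches its step-up definition", {
  # hand-enumerable case: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (s in 1:10) {
    p <- withr::with_seed(s, runif(sample(3:60, 1)))
    adj <- p.adjust(p, "BH")
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_identical(order(adj[order(p)]), seq_along(p)) # order preserved
  }
})

test_that("DEG selection applies strict FDR and fold-change bounds", {
  tab <- tiny_deg_table(
    feature_id = c("in_up", "out_fc", "in_down", "out_fdr"),
    log2fc = c(0.60, 0.58, -0.80, 2.0),
    p_raw = c(0.01, 0.01, 0.01, 0.9))
  tab$fdr <- c(0.04, 0.04, 0.04, 0.9)
  sig <- select_degs(tab, fdr_max = 0.05, fc_min = 1.5)
  expect_identical(sig$up, "in_up")      # 0.60 > log2(1.5) = 0.585
  expect_identical(sig$down, "in_down")  # 0.58 fails the fold-change bound

  # row order cannot matter
  shuf <- tab[c(3, 1, 4, 2), ]
  sig2 <- select_degs(shuf)
  expect_setequal(sig2$up, sig$up)
  expect_setequal(sig2$down, sig$down)

  empty <- select_degs(tiny_deg_table(character(0), numeric(0)))
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
  expect_error(select_degs(tab, fc_min = 1), "fc_min")
})

test_that("largest-changing query splits by fold-change sign", {
  # 1500 features; exactly 812 of the top 1000 |t| have positive fc
  n <- 1500
  ids <- sprintf("f%04d", seq_len(n))
  tvals <- seq(20, 2, length.out = n)
  sign_vec <- rep(1, n)
  sign_vec[withr::with_seed(7, sample.int(1000, 188))] <- -1 # among top 1000 by |t|
  tab <- tiny_deg_table(ids, log2fc = sign_vec * seq(3, 0.1, length.out = n),
                        t_stat = sign_vec * tvals)
  sig <- top_changing_probes(tab, 1000)
  expect_length(sig$up, 812)
  expect_length(sig$down, 188)

  all_sig <- top_changing_probes(tab, n)
  expect_setequal(c(all_sig$up, all_sig$down), ids)

  pos <- tiny_deg_table(ids[1:20], log2fc = 1:20 / 10, t_stat = 1:20)
  expect_length(top_changing_probes(pos, 5)$down, 0)
  expect_error(top_changing_probes(pos, 21), "21")
})

test_that("tie-breaks at the |t| cutoff are lexicographic and deterministic", {
  tab <- tiny_deg_table(c("z", "a", "m"), log2fc = c(1, 1, 2),
                        t_stat = c(5, 5, 9))
  sig <- top_changing_probes(tab, 2)
  expect_setequal(c(sig$up, sig$down), c("m", "a"))
})

test_that("ddCt arithmetic follows the closed form", {
  expect_equal(ddct_fold_change(5, 5), 1)
  expect_equal(ddct_fold_change(4, 5), 2)
  expect_equal(ddct_fold_change(8, 5), 0.125)
  expect_equal(ddct_fold_change(c(0, -1), c(0, 0)), c(1, 2))
})

test_that("planted signals are recovered at standard thresholds", {
  sim <- simulate_expression(500, n_up = 25, n_down = 15, effect_log2 = 2,
                             sd = 0.5, seed = 41)
  tab <- moderated_t_table(sim$expr, "early", "late")
  sig <- select_degs(tab)
  hit_up <- intersect(sig$up, sim$truth$planted_up)
  hit_down <- intersect(sig$down, sim$truth$planted_down)
  expect_gte(length(hit_up) + length(hit_down), 0.9 * 40)
  # wrong-direction calls: planted genes recovered on the wrong side
  wrong <- length(intersect(sig$down, sim$truth$planted_up)) +
    length(intersect(sig$up, sim$truth$planted_down))
  expect_lte(wrong, 0.05 * 40)
})
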