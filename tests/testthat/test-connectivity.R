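test_that("KS tag score matches hand-evaluated cases", {
  expect_equal(ks_tag_score(c(1, 2), 10), 0.8)
  # all items tagged: a = 0, b = 1/n
  expect_equal(ks_tag_score(1:10, 10), -0.1)
  expect_equal(ks_tag_score(1:7, 7), -1 / 7)
  expect_error(ks_tag_score(integer(0), 10), "empty")
  expect_error(ks_tag_score(c(3, 3), 10), "duplicate")
  expect_error(ks_tag_score(c(0, 2), 10), "1..n")
})

test_that("KS tag score equals the CDF-deviation oracle on all small subsets", {
  for (n in 4:8) {
    subsets <- unlist(lapply(seq_len(n), function(t) {
      utils::combn(n, t, simplify = FALSE)
    }), recursive = FALSE)
    for (v in subsets) {
      expect_equal(ks_tag_score(v, n), oracle_ks(v, n), tolerance = 1e-12)
    }
  }
})

test_that("reversing the ranked list negates the score up to discretization", {
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- sample(10:200, 1)
      t <- sample(seq_len(n - 1), 1)
      v <- sample.int(n, t)
    })
    fwd <- ks_tag_score(v, n)
    rev <- ks_tag_score(n + 1 - v, n)
    # decisive scores flip up to the 1/n discretization offset; near-ties
    # fall to the negative side in both orientations by the tie rule
    expect_true(abs(fwd + rev) <= 1 / n + 1e-12 || (fwd <= 0 && rev <= 0))
  }
})

test_that("raw score combination applies the opposite-sign rule", {
  expect_equal(combine_scores(-0.077, 0.223), -0.3)
  expect_equal(combine_scores(0.5, 0.5), 0)
  expect_equal(combine_scores(-0.4, -0.2), 0)
  expect_equal(combine_scores(0, 0), 0)
  # one-sided signals still score
  expect_equal(combine_scores(0, 0.3), -0.3)
  expect_equal(combine_scores(-0.3, 0), -0.3)
  # swapping the query's up and down sets negates the raw score
  for (s in 1:20) {
    ud <- withr::with_seed(s, runif(2, -1, 1))
    expect_equal(combine_scores(ud[1], ud[2]),
                 -combine_scores(ud[2], ud[1]), tolerance = 1e-12)
  }
})

test_that("connectivity normalization maps each side's extreme to +/-1", {
  expect_equal(normalize_connectivity(-0.3), -1)
  expect_equal(normalize_connectivity(c(0.2, -0.1)), c(1, -1))
  expect_equal(normalize_connectivity(c(0, 0)), c(0, 0))
  raw <- c(0.4, 0.1, 0, -0.2, -0.5)
  out <- normalize_connectivity(raw)
  expect_equal(out, c(1, 0.25, 0, -0.4, -1))
  # scale-free under positive rescaling
  expect_equal(normalize_connectivity(raw * 3.7), out, tolerance = 1e-12)
  expect_true(all(abs(out) <= 1))
})

test_that("a perfect planted reverser tops the KS screen at connectivity -1", {
  genes <- sprintf("g%05d", 1:120)
  sig <- signature_set(genes[1:10], genes[11:20], space = "gene")
  # strength chosen so the placement window equals the planted tag block
  sim <- simulate_rank_database(200, 6, probe_multiplicity = 1,
                                disease_signature = sig, n_reversers = 1,
                                strength = 10 / 200, seed = 13)
  psig <- signature_set(
    sim$map$probe_id[sim$map$gene_symbol %in% sig$up],
    sim$map$probe_id[sim$map$gene_symbol %in% sig$down], space = "probe")
  res <- run_ks_query(psig, sim$db)
  expect_identical(res$instance_id[1], sim$truth$reverser_instance_ids)
  expect_equal(res$connectivity[1], -1)
  expect_lt(res$raw_s[1], -1.8) # both tag sets pinned to opposite extremes
  # in a decoy-only screen the most negative instance still attains -1
  expect_equal(min(run_ks_query(psig, sim$db)$connectivity), -1)
})

test_that("query probes missing from the database are dropped, not fatal", {
  db <- tiny_db(c("p1", "p2", "p3", "p4"), list(i1 = c(1L, 2L, 3L, 4L),
                                                i2 = c(4L, 3L, 2L, 1L)))
  sig <- signature_set(c("p1", "absent"), c("p4"), space = "probe")
  withr::with_options(list(sigreverse.quiet = FALSE),
                      expect_message(res <- run_ks_query(sig, db), "dropped 1"))
  expect_equal(nrow(res), 2)
  none <- signature_set("nope1", "nope2", space = "probe")
  expect_error(run_ks_query(none, db), "no probes in common")
})
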