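test_that("median condensation follows the stated conventions", {
  map <- tibble::tibble(probe_id = c("a1", "a2", "a3", "b1", "c1", "c2"),
                        gene_symbol = c("A", "A", "A", "B", "C", "C"))
  r <- c(a1 = 10L, a2 = 20L, a3 = 30L, b1 = 7L, c1 = 5L, c2 = 15L)
  gr <- condense_probes_to_genes(r, map)
  expect_equal(gr$median_rank[gr$gene_symbol == "A"], 20) # odd count
  expect_equal(gr$median_rank[gr$gene_symbol == "B"], 7)  # single probe
  expect_equal(gr$median_rank[gr$gene_symbol == "C"], 10) # even count: mean
  expect_identical(gr$rank, 1:3)
  expect_identical(gr$gene_symbol[1], "B")

  # median ties break lexicographically in the dense order
  map2 <- tibble::tibble(probe_id = c("z1", "a1"), gene_symbol = c("Z", "A"))
  r2 <- c(z1 = 1L, a1 = 2L)
  r3 <- c(z1 = 5L, a1 = 5L) # impossible as a permutation, but tests the rule
  expect_identical(condense_probes_to_genes(r2, map2)$gene_symbol, c("Z", "A"))
  expect_identical(condense_probes_to_genes(r3, map2)$gene_symbol, c("A", "Z"))

  expect_error(condense_probes_to_genes(c(x = 1L), map), "no probes")
})

test_that("one-probe-per-gene condensation preserves the ranking order", {
  withr::with_seed(51, {
    n <- 40
    probes <- sprintf("p%02d", 1:n)
    map <- tibble::tibble(probe_id = probes,
                          gene_symbol = sprintf("G%02d", 1:n))
    r <- setNames(sample.int(n), probes)
  })
  gr <- condense_probes_to_genes(r, map)
  expect_identical(gr$gene_symbol, map$gene_symbol[order(r)])
  expect_identical(gr$rank, seq_len(n))
})

test_that("drug signatures take the k most extreme genes of the dense order", {
  map <- tibble::tibble(probe_id = c("a", "b", "c"),
                        gene_symbol = c("A", "B", "C"))
  gr <- condense_probes_to_genes(c(a = 1L, b = 2L, c = 3L), map)
  sig <- drug_signature(gr, k = 1)
  expect_identical(sig$up, "A")
  expect_identical(sig$down, "C")
  full <- drug_signature(gr, k = 1) # G = 3, k = 1 leaves the middle out
  expect_false("B" %in% c(full$up, full$down))
  both <- drug_signature(condense_probes_to_genes(c(a = 1L, b = 2L), map[1:2, ]),
                         k = 1)
  expect_setequal(c(both$up, both$down), c("A", "B")) # G = 2k covers all
  expect_error(drug_signature(gr, k = 2), "G = 3, k = 2")
})

test_that("reversing score counts opposing and matching overlaps", {
  # overlap cardinalities chosen freely; score must be their difference
  dis <- signature_set(sprintf("u%02d", 1:40), sprintf("d%02d", 1:20),
                       space = "gene")
  drug <- signature_set(
    up = c(sprintf("d%02d", 1:5), sprintf("u%02d", 1:7), "x1", "x2"),
    down = c(sprintf("u%02d", 8:20), sprintf("d%02d", 6:9), "y1"),
    space = "gene")
  rv <- reversing_score(dis, drug)
  expect_equal(length(rv$reversed), 13 + 5)
  expect_equal(length(rv$aggravated), 7 + 4)
  expect_equal(rv$score, 18 - 11)
  expect_length(intersect(rv$reversed, rv$aggravated), 0)

  none <- reversing_score(dis, signature_set("q1", "q2", space = "gene"))
  expect_equal(none$score, 0)
  expect_length(none$reversed, 0)

  perfect <- reversing_score(
    signature_set(sprintf("u%02d", 1:10), sprintf("d%02d", 1:5), space = "gene"),
    signature_set(sprintf("d%02d", 1:5), sprintf("u%02d", 1:10), space = "gene"))
  expect_equal(perfect$score, 15)
})

test_that("reversing score is antisymmetric and bounded by the signature size", {
  pool <- sprintf("g%03d", 1:60)
  for (s in 1:15) {
    withr::with_seed(s, {
      dis_up <- sample(pool, 8)
      dis_down <- sample(setdiff(pool, dis_up), 6)
      drug_up <- sample(pool, 10)
      drug_down <- sample(setdiff(pool, drug_up), 10)
    })
    dis <- signature_set(dis_up, dis_down, space = "gene")
    drug <- signature_set(drug_up, drug_down, space = "gene")
    rv <- reversing_score(dis, drug)
    expect_equal(rv$score, oracle_reversing(dis, drug))
    expect_lte(rv$score, 14)
    flipped <- reversing_score(signature_set(dis_down, dis_up, "gene"), drug)
    expect_equal(flipped$score, -rv$score)
    expect_setequal(flipped$reversed, rv$aggravated)
    expect_setequal(flipped$aggravated, rv$reversed)
  }
})

test_that("the matching screen ranks a perfect planted reverser first", {
  genes <- sprintf("g%05d", 1:100)
  sig <- signature_set(genes[1:8], genes[9:12], space = "gene")
  sim <- simulate_rank_database(100, 5, probe_multiplicity = 1,
                                disease_signature = sig, n_reversers = 1,
                                strength = 8 / 100, seed = 19)
  res <- run_matching_query(sig, sim$db, sim$map, k = 20)
  expect_identical(res$instance_id[1], sim$truth$reverser_instance_ids)
  expect_equal(res$score[1], 12)
  expect_equal(res$n_reversed[1], 12)
  expect_equal(res$n_aggravated[1], 0)
  expect_identical(res$rank, 1:5)
})
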