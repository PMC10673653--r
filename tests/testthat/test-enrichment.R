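test_that("hypergeometric p equals the brute-force tail sum", {
  # the printed-shape example: 30 of 100 in foreground, term annotates 20, 10 hit
  universe <- c(sprintf("f%02d", 1:30), sprintf("u%02d", 1:70))
  tm <- data.table(gene_id = c(sprintf("f%02d", 1:10), sprintf("u%02d", 1:10)),
                   term_id = "GO:0000001", term_name = "t")
  res <- term_enrichment(tm, foreground = sprintf("f%02d", 1:30), universe = universe)
  expect_equal(res$fg_with, 10L)
  expect_equal(res$bg_with, 20L)
  expect_equal(res$p, hyper_tail_oracle(10, 20, 100, 30), tolerance = 1e-12)

  set.seed(501)
  for (rep in 1:20) {
    bg_total <- sample(20:60, 1)
    universe <- sprintf("g%03d", seq_len(bg_total))
    fg <- sample(universe, sample(5:(bg_total - 5), 1))
    with_term <- sample(universe, sample(3:bg_total, 1))
    tm <- data.table(gene_id = with_term, term_id = "GO:0000002", term_name = "t2")
    res <- term_enrichment(tm, fg, universe, min_count = 1)
    oracle <- hyper_tail_oracle(res$fg_with, res$bg_with, bg_total, length(fg))
    expect_lt(abs(res$p - oracle), 1e-12)
  }
})

test_that("degenerate foregrounds behave as limits demand", {
  universe <- sprintf("g%02d", 1:40)
  tm <- data.table(gene_id = universe[1:10], term_id = "GO:0000003", term_name = "t3")
  # term absent from the foreground: upper tail from 0 is 1
  res <- term_enrichment(tm, foreground = universe[31:40], universe = universe)
  expect_equal(res$fg_with, 0L)
  expect_equal(res$p, 1)
  # foreground == universe: every term p = 1, odds ratio 1
  res2 <- term_enrichment(tm, foreground = universe, universe = universe)
  expect_equal(res2$p, 1)
  expect_equal(res2$odds_ratio, 1)
  expect_error(term_enrichment(tm, foreground = c("g01", "zz"), universe = universe),
               "outside the universe")
  # min_count filters sparse terms
  tm2 <- rbind(tm, data.table(gene_id = "g01", term_id = "GO:0000004", term_name = "rare"))
  expect_equal(nrow(term_enrichment(tm2, universe[1:5], universe, min_count = 3)), 1L)
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.05, 4)), rep(0.05, 4))
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_equal(order(q), order(p)) # monotone in p
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p[perm]), q[perm]) # permutation equivariance
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("orthogroup-level term lifting unions member annotations", {
  tbl <- orthogroup_table(
    data.table(og_id = c("OG1", "OG1", "OG2"),
               accession = c("A", "B", "A"),
               gene_id = c("g1", "h1", "g2")),
    accessions = c("A", "B")
  )
  tm <- data.table(gene_id = c("A|g1", "B|h1", "A|g2"),
                   term_id = c("GO:0000001", "GO:0000002", "GO:0000001"),
                   term_name = "t")
  og <- terms_by_orthogroup(tm, tbl)
  expect_equal(sort(og[gene_id == "OG1", term_id]), c("GO:0000001", "GO:0000002"))
  expect_equal(og[gene_id == "OG2", term_id], "GO:0000001")
})

test_that("a planted auxiliary-enriched term tops the ranking", {
  tr <- generate_truth(simulation_params(n_accessions = 6, n_orthogroups = 3000,
                                         core_fraction = 0.5, seed = 61))
  tm <- data.table(gene_id = tr$terms$og_id, term_id = tr$terms$term_id,
                   term_name = tr$terms$term_name)
  en <- term_enrichment(tm, foreground = tr$og[class == "auxiliary", og_id],
                        universe = tr$og$og_id)
  expect_equal(en$term_id[1], "GO:0009607")
  expect_lt(en$fdr_q[1], 1e-6)
})
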