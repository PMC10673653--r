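test_that("feature rows satisfy the gene-model arithmetic", {
  ann <- make_ann("A",
    data.table(gene_id = c("g1", "g2", "g3"), seq_id = "chr1",
               start = c(101L, 1101L, 5101L), end = c(200L, 1200L, 5200L),
               strand = c("+", "+", "-")),
    data.table(gene_id = c("g1", "g2", "g2", "g3", "g3"),
               start = c(101L, 1101L, 1171L, 5101L, 5171L),
               end = c(200L, 1150L, 1200L, 5150L, 5200L)))
  lab <- make_labels("A", c("g1", "g2", "g3"), c("core", "auxiliary", "auxiliary"))
  ft <- compute_features(ann, lab)
  g1 <- ft[gene_id == "g1"]
  expect_equal(g1$gene_length, 100L)
  expect_equal(g1$cds_length, 100L)
  expect_equal(g1$cds_count, 1L)
  expect_equal(g1$intron_count, 0L)
  expect_equal(g1$intron_length_total, 0L)
  g2 <- ft[gene_id == "g2"]
  expect_equal(g2$cds_length, 80L)
  expect_equal(g2$cds_count, 2L)
  expect_equal(g2$intron_count, 1L)
  expect_equal(g2$intron_length_total, 20L)
  # minus-strand gene with the same segment layout: identical lengths
  g3 <- ft[gene_id == "g3"]
  expect_equal(g3[, .(gene_length, cds_length, cds_count, intron_count, intron_length_total)],
               g2[, .(gene_length, cds_length, cds_count, intron_count, intron_length_total)])
  expect_true(all(is.na(ft$tpm)))
  # unlabeled gene is an error
  lab2 <- make_labels("A", c("g1", "g2"), c("core", "auxiliary"))
  expect_error(compute_features(ann, lab2), "no core/auxiliary label")
})

test_that("feature invariants hold on generated annotations", {
  tr <- generate_truth(small_params())
  anns <- emit_annotations(tr)
  lab <- classify_pav(emit_orthogroups(tr, 0), anns, emit_anchors(tr, 0, 0), W = 5000)
  ft <- compute_features(anns, lab, emit_expression(tr))
  g <- rbindlist(lapply(anns, `[[`, "genes"))
  expect_equal(nrow(ft), nrow(g))
  expect_true(all(ft$gene_length == ft$cds_length + ft$intron_length_total))
  expect_true(all(ft$intron_count == ft$cds_count - 1L))
  expect_true(all(!is.na(ft$tpm) & ft$tpm >= 0))
})

test_that("rank-sum contrast matches exact enumeration on tiny samples", {
  rows <- data.table(label = rep(c("core", "auxiliary"), each = 3),
                     gene_length = c(1, 2, 3, 4, 5, 6))
  cmp <- compare_groups(rows, "gene_length")
  expect_equal(cmp$U, 0)
  # oracle: of the C(6,3)=20 equally likely core-rank assignments, exactly one
  # puts the core ranks at {1,2,3}; one-sided p = 1/20, two-sided doubles it
  ranks <- combn(6, 3)
  obs <- sum(1:3)
  p_one <- mean(colSums(ranks) <= obs)
  expect_equal(p_one, 0.05)
  expect_equal(cmp$p, 2 * p_one)
  expect_equal(cmp$direction, -1)
  # identical multisets: no difference
  rows2 <- data.table(label = rep(c("core", "auxiliary"), each = 3),
                      gene_length = c(7, 8, 9, 7, 8, 9))
  cmp2 <- compare_groups(rows2, "gene_length")
  expect_equal(cmp2$p, 1)
  expect_equal(cmp2$direction, 0)
  expect_error(compare_groups(rows[label == "core"], "gene_length"), "both classes")
})

test_that("normal approximation tracks the exact rank-sum p at n = 8 vs 8", {
  set.seed(77)
  for (rep in 1:5) {
    x <- sample(100, 8); y <- sample(100, 8) + 20
    p_exact <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
    p_norm <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_norm), 0.02)
    rows <- data.table(label = rep(c("core", "auxiliary"), each = 8),
                       gene_length = c(x, y))
    expect_equal(compare_groups(rows, "gene_length")$p, p_exact)
  }
})

test_that("genes lacking TPM are excluded from the expression contrast only", {
  rows <- data.table(label = rep(c("core", "auxiliary"), each = 5),
                     gene_length = 1:10,
                     tpm = c(5, 6, 7, NA, NA, 1, 2, NA, NA, NA))
  cmp <- compare_groups(rows, "tpm")
  expect_equal(cmp$n_core, 3L)
  expect_equal(cmp$n_aux, 2L)
  all_cmp <- compare_all_features(rows, features = c("gene_length", "tpm"))
  expect_equal(all_cmp$n_core, c(5L, 3L))
})
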