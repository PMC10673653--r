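mk_gene <- function(accession, seq_id, start, end) {
  list(accession = accession, seq_id = seq_id, start = start, end = end)
}

test_that("anchor distance is max-of-sides, minimised over anchors", {
  ga <- mk_gene("A", "chr1", 20000, 21000)
  gb <- mk_gene("B", "chr1", 20000, 21000)
  # overlapping both sides -> 0
  an <- anchor_set(data.frame(acc_a = "A", seq_a = "chr1", start_a = 19500, end_a = 20500,
                              acc_b = "B", seq_b = "chr1", start_b = 20900, end_b = 21500))
  expect_equal(anchor_distance(ga, gb, an), 0)
  # anchor ending 6000 bp before gene_a, overlapping gene_b -> 6000
  an2 <- anchor_set(data.frame(acc_a = "A", seq_a = "chr1", start_a = 13000, end_a = 14000,
                               acc_b = "B", seq_b = "chr1", start_b = 20000, end_b = 21000))
  expect_equal(anchor_distance(ga, gb, an2), 6000)
  # two anchors at distances 7000 and 3200 -> 3200
  an3 <- anchor_set(rbind(
    data.frame(acc_a = "A", seq_a = "chr1", start_a = 12000, end_a = 13000,
               acc_b = "B", seq_b = "chr1", start_b = 20100, end_b = 20500),
    data.frame(acc_a = "A", seq_a = "chr1", start_a = 16000, end_a = 16800,
               acc_b = "B", seq_b = "chr1", start_b = 20000, end_b = 20900)
  ))
  expect_equal(anchor_distance(ga, gb, an3), 3200)
  # wrong chromosome or no anchor at all -> Inf
  expect_equal(anchor_distance(mk_gene("A", "chr2", 1, 10), gb, an), Inf)
  # direction-free: swapped arguments give the same distance
  expect_equal(anchor_distance(gb, ga, an3), 3200)
})

two_gene_fixture <- function(gap_a) {
  # one orthogroup, one gene in each of A and B; anchor sits gap_a bp left of
  # the A gene and overlaps the B gene
  anns <- list(
    make_ann("A", data.table(gene_id = "g1", seq_id = "chr1",
                             start = 20000L, end = 21000L, strand = "+"),
             data.table(gene_id = "g1", start = 20000L, end = 21000L)),
    make_ann("B", data.table(gene_id = "h1", seq_id = "chr1",
                             start = 20000L, end = 21000L, strand = "+"),
             data.table(gene_id = "h1", start = 20000L, end = 21000L))
  )
  tbl <- orthogroup_table(
    data.table(og_id = "OG1", accession = c("A", "B"), gene_id = c("g1", "h1")),
    accessions = c("A", "B")
  )
  an <- anchor_set(data.frame(acc_a = "A", seq_a = "chr1",
                              start_a = 20000 - gap_a - 500, end_a = 20000 - gap_a,
                              acc_b = "B", seq_b = "chr1",
                              start_b = 20200, end_b = 20800))
  list(anns = anns, tbl = tbl, an = an)
}

test_that("the proximity boundary is inclusive at exactly W", {
  fx <- two_gene_fixture(gap_a = 5000)
  fc <- filter_ortholog_calls(fx$tbl, fx$anns, fx$an, W = 5000)
  expect_equal(fc$min_anchor_distance, 5000)
  expect_true(fc$retained)
  fc2 <- filter_ortholog_calls(fx$tbl, fx$anns, fx$an, W = 4999)
  expect_false(fc2$retained)
})

test_that("unresolvable member genes are named in the error", {
  fx <- two_gene_fixture(0)
  tbl <- orthogroup_table(
    data.table(og_id = "OG1", accession = c("A", "B"), gene_id = c("g1", "ghost")),
    accessions = c("A", "B")
  )
  expect_error(filter_ortholog_calls(tbl, fx$anns, fx$an, W = 5000), "B\\|ghost")
})

test_that("noiseless synthetic classification recovers the truth exactly", {
  tr <- generate_truth(small_params())
  anns <- emit_annotations(tr)
  tbl <- emit_orthogroups(tr, og_error_rate = 0)
  an <- emit_anchors(tr, dropout = 0, jitter_sd = 0)
  lab <- classify_pav(tbl, anns, an, W = 5000)
  expect_equal(gene_label_accuracy(lab, tr), 1)
  expect_equal(mean(lab$units$label == "core"), mean(tr$og$class == "core"))
  # partition: core + auxiliary genes = total genes, overall and per accession
  gl <- lab$gene_labels
  expect_equal(gl[, sum(label == "core") + sum(label == "auxiliary")], nrow(tr$genes))
  per <- gl[, .(tot = .N, parts = sum(label %in% c("core", "auxiliary"))), by = accession]
  expect_true(all(per$tot == per$parts))
})

test_that("mis-merged members are dropped by the filter and occupancy decremented", {
  p <- small_params(og_error_rate = 0.2)
  tr <- generate_truth(p)
  anns <- emit_annotations(tr)
  tbl <- emit_orthogroups(tr)
  mm <- attr(tbl, "mismerged")
  expect_gt(nrow(mm), 0)
  an <- emit_anchors(tr)
  fc <- filter_ortholog_calls(tbl, anns, an, W = 5000)
  injected <- fc[gene_a %in% mm$global | gene_b %in% mm$global]
  expect_true(all(!injected$retained))
  lab <- classify(tbl, fc)
  # mis-merged genes revert to auxiliary singleton units
  back <- lab$gene_labels[global %in% mm$global]
  expect_true(all(back$label == "auxiliary" & !back$retained))
  expect_equal(gene_label_accuracy(lab, tr), 1)
})

test_that("W = Inf reduces to occupancy classification and W < 0 voids all calls", {
  tr <- generate_truth(small_params())
  anns <- emit_annotations(tr)
  tbl <- emit_orthogroups(tr, og_error_rate = 0)
  inf_lab <- classify_pav(tbl, anns, NULL, mode = "orthogroup")
  expect_equal(
    sum(inf_lab$units$label == "core"),
    tbl$og[n_acc == length(tbl$accessions), .N]
  )
  neg <- classify(tbl, filter_ortholog_calls(tbl, anns, NULL, W = -1))
  expect_true(all(neg$units$label == "auxiliary"))
  expect_true(all(neg$units$occupancy == 1))
})

test_that("reference projection applies the span-coverage threshold", {
  ref <- make_ann("REF",
    data.table(gene_id = c("r1", "r2", "r3"), seq_id = "chr1",
               start = c(1000L, 5000L, 9000L), end = c(1999L, 5999L, 9999L),
               strand = "+"),
    data.table(gene_id = c("r1", "r2", "r3"),
               start = c(1000L, 5000L, 9000L), end = c(1999L, 5999L, 9999L)))
  an <- anchor_set(rbind(
    # X covers r1 fully (two abutting blocks) and r2 at 40%; r3 untouched
    data.frame(acc_a = "REF", seq_a = "chr1", start_a = 900, end_a = 1500,
               acc_b = "X", seq_b = "chr1", start_b = 900, end_b = 1500),
    data.frame(acc_a = "REF", seq_a = "chr1", start_a = 1400, end_a = 2100,
               acc_b = "X", seq_b = "chr1", start_b = 1400, end_b = 2100),
    data.frame(acc_a = "REF", seq_a = "chr1", start_a = 5000, end_a = 5399,
               acc_b = "X", seq_b = "chr1", start_b = 5000, end_b = 5399),
    # Y covers everything
    data.frame(acc_a = "REF", seq_a = "chr1", start_a = 1, end_a = 20000,
               acc_b = "Y", seq_b = "chr1", start_b = 1, end_b = 20000)
  ))
  m <- project_to_reference(ref, an, accessions = c("X", "Y"))
  expect_true(m["r1", "X"] && m["r1", "Y"])
  expect_false(m["r2", "X"]) # 40% < 50%
  expect_false(m["r3", "X"])
  m2 <- project_to_reference(ref, an, accessions = c("X", "Y"), coverage_threshold = 0.4)
  expect_true(m2["r2", "X"]) # inclusive at the threshold
  expect_equal(reference_core(m), "r1")
  expect_error(project_to_reference(ref, an, accessions = c("X", "Z")), "Z")
})

test_that("summaries reproduce printed-style percentages under half-up rounding", {
  expect_equal(pav_percent(14553, 27463, 0), 53)
  expect_equal(pav_percent(70073, 104552, 2), 67.02)
  expect_equal(pav_percent(10, 10, 0), 100)
  tr <- generate_truth(small_params())
  lab <- classify_pav(emit_orthogroups(tr, 0), emit_annotations(tr),
                      emit_anchors(tr, 0, 0), W = 5000)
  s <- summarize_pav(lab, digits = 2)
  per <- lab$gene_labels[, .(n_core = sum(label == "core"), n_total = .N), by = accession]
  expect_equal(s$per_accession$n_core, per[order(accession)]$n_core)
  expect_equal(s$units$n_core, sum(lab$units$label == "core"))
  expect_equal(s$overall$pct_core,
               pav_percent(mean(per$n_core), mean(per$n_total), 2))
})
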