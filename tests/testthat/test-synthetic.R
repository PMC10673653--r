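test_that("identical parameters give byte-identical emitted files", {
  p <- simulation_params(n_accessions = 4, n_orthogroups = 150,
                         og_error_rate = 0.05, anchor_dropout = 0.05,
                         anchor_jitter_sd = 25, position_jitter_sd = 50, seed = 5)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  simulate_pangenome(p, d1)
  simulate_pangenome(p, d2)
  fs <- sort(list.files(d1))
  expect_identical(fs, sort(list.files(d2)))
  expect_identical(unname(tools::md5sum(file.path(d1, fs))),
                   unname(tools::md5sum(file.path(d2, fs))))
})

test_that("core fraction and occupancy ranges follow the parameters", {
  tr <- generate_truth(small_params(core_fraction = 1))
  expect_true(all(tr$og$occupancy == tr$params$n_accessions))
  tr2 <- generate_truth(small_params(core_fraction = 0.53))
  expect_equal(sum(tr2$og$class == "core"), floor(0.53 * 200))
  aux <- tr2$og[class == "auxiliary"]
  expect_true(all(aux$occupancy >= 1 & aux$occupancy <= tr2$params$n_accessions - 1))
  # occupancy N <=> core, and labels are per-orthogroup
  expect_identical(tr2$og$occupancy == tr2$params$n_accessions,
                   tr2$og$class == "core")
})

test_that("a gene appears in an accession's annotation iff truth places it there", {
  tr <- generate_truth(small_params())
  anns <- emit_annotations(tr)
  emitted <- rbindlist(lapply(anns, function(a) {
    data.table(accession = a$accession_id, gene_id = a$genes$gene_id)
  }))
  expect_equal(
    emitted[order(accession, gene_id)],
    tr$genes[order(accession, gene_id), .(accession, gene_id)]
  )
  # with zero position jitter, copies of one orthogroup share coordinates
  g <- tr$genes[, .(n_start = uniqueN(start), n_end = uniqueN(end)), by = og_id]
  expect_true(all(g$n_start == 1 & g$n_end == 1))
})

test_that("class feature distributions are recovered at the sample level", {
  tr <- generate_truth(simulation_params(n_accessions = 5, n_orthogroups = 5000,
                                         core_fraction = 0.5, seed = 17))
  fp <- tr$params$feature_params
  for (cl in c("core", "auxiliary")) {
    pars <- if (cl == "core") fp$core else fp$aux
    lens <- tr$og[class == cl, len]
    se <- sd(lens) / sqrt(length(lens))
    expect_lt(abs(mean(lens) - pars$mean_length), 3 * se + 1)
  }
})

test_that("mis-merge and anchor-dropout counts are binomial around their rates", {
  p <- simulation_params(n_accessions = 6, n_orthogroups = 4000,
                         core_fraction = 0.4, og_error_rate = 0.1,
                         anchor_dropout = 0.05, seed = 23)
  tr <- generate_truth(p)
  n_single <- sum(tr$og$class == "auxiliary" & tr$og$occupancy == 1)
  mm <- attr(emit_orthogroups(tr), "mismerged")
  se <- sqrt(n_single * 0.1 * 0.9)
  expect_lt(abs(nrow(mm) - 0.1 * n_single), 3 * se)
  # every mis-merged gene sits >= 50 kbp from its adoptive family's locus
  pos <- tr$og[, .(og_id, chrom, anc_start)]
  chk <- merge(merge(mm, tr$genes[, .(global, og_id)], by = "global"),
               pos, by.x = "to_og", by.y = "og_id")
  chk <- merge(chk, pos, by.x = "og_id", by.y = "og_id", suffixes = c("_fam", "_self"))
  expect_true(all(chk$chrom_fam != chk$chrom_self |
                  abs(chk$anc_start_fam - chk$anc_start_self) >= 50000))

  g <- tr$genes[, .(og_id, accession)]
  n_pairs <- merge(g, g, by = "og_id", allow.cartesian = TRUE)[
    accession.x < accession.y, .N]
  kept <- nrow(emit_anchors(tr)) / 2 # closure doubles records
  se2 <- sqrt(n_pairs * 0.05 * 0.95)
  expect_lt(abs(kept - 0.95 * n_pairs), 3 * se2)
  expect_equal(nrow(emit_anchors(tr, dropout = 1)), 0L)
})

test_that("expression and terms respect their class parameters", {
  tr <- generate_truth(small_params())
  expect_true(all(tr$genes$tpm >= 0))
  tmap <- emit_terms(tr)
  expect_true(all(grepl("^GO:[0-9]{7}$", tmap$term_id)))
  expect_true(all(tmap$gene_id %in% tr$genes$global))
})

test_that("undersized chromosomes are rejected with advice", {
  expect_error(
    simulation_params(n_accessions = 3, n_orthogroups = 1000,
                      chrom_count = 2, chrom_length = 60000, seed = 1) |>
      generate_truth(),
    "chrom_length"
  )
})
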