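# Ground-truthed synthetic pangenome generator. Orthogroups ("ancestral
# genes") are laid out on fixed-width chromosome slots shared by all
# accessions, so a gene present in several accessions sits at the same
# ancestral position (+- jitter) in each -- the positional structure the
# synteny-anchor filter relies on.

SLOT_BP <- 15000L      # per-orthogroup chromosome slot
SLOT_HEAD <- 1000L     # head margin inside a slot (jitter room)
LEN_MIN <- 300L        # gene length clamp
LEN_MAX <- 12000L

#' Simulation parameters for the synthetic pangenome
#'
#' Defaults emulate a cranberry-sized cultivar panel: 11 accessions, 20000
#' orthogroups of which 53\% are core, auxiliary occupancy uniform on
#' 1..N-1, core genes longer (mean 3000 bp vs 1200 bp), more introns and
#' higher expression than auxiliary genes, and one term
#' ("response to biotic stimulus") planted as auxiliary-enriched.
#'
#' @param n_accessions number of accessions N (>= 2).
#' @param n_orthogroups number of orthogroups G.
#' @param core_fraction fraction of orthogroups with occupancy N.
#' @param occupancy_model `"uniform"` or `"beta"` over 1..N-1 for auxiliary
#'   orthogroups.
#' @param occupancy_shape length-2 (alpha, beta) used when
#'   `occupancy_model = "beta"` (U-shaped spectra for alpha, beta < 1).
#' @param genes_per_group genes per orthogroup per carrying accession.
#' @param chrom_count chromosomes per genome.
#' @param chrom_length chromosome length in bp; `NULL` sizes it to fit
#'   `n_orthogroups` slots.
#' @param anchor_dropout probability an alignment anchor is lost.
#' @param anchor_jitter_sd SD (bp) of anchor endpoint jitter.
#' @param position_jitter_sd SD (bp) of per-copy gene position jitter.
#' @param og_error_rate probability an auxiliary singleton is mis-merged
#'   into a random gene family (emulating family-level over-grouping).
#' @param feature_params per-class gene structure distributions: lists
#'   `core`/`aux` with `mean_length` (bp), `sdlog` (log-normal), `intron_rate`
#'   (Poisson mean intron count) and `cds_fraction`.
#' @param expr_params per-class log-normal TPM parameters (`meanlog`, `sdlog`).
#' @param enrich_params data.frame (term_id, term_name, p_core, p_aux) of
#'   per-class term assignment probabilities.
#' @param seed integer seed; the sole entry point for randomness.
#' @return a `simulation_params` list.
#' @export
simulation_params <- function(n_accessions = 11L,
                              n_orthogroups = 20000L,
                              core_fraction = 0.53,
                              occupancy_model = c("uniform", "beta"),
                              occupancy_shape = c(0.5, 0.5),
                              genes_per_group = 1L,
                              chrom_count = 12L,
                              chrom_length = NULL,
                              anchor_dropout = 0,
                              anchor_jitter_sd = 0,
                              position_jitter_sd = 0,
                              og_error_rate = 0,
                              feature_params = list(
                                core = list(mean_length = 3000, sdlog = 0.4, intron_rate = 3, cds_fraction = 0.6),
                                aux  = list(mean_length = 1200, sdlog = 0.4, intron_rate = 1, cds_fraction = 0.6)
                              ),
                              expr_params = list(
                                core = list(meanlog = log(10), sdlog = 1),
                                aux  = list(meanlog = log(3),  sdlog = 1)
                              ),
                              enrich_params = default_enrich_params(),
                              seed = 1L) {
  occupancy_model <- match.arg(occupancy_model)
  p <- list(
    n_accessions = as.integer(n_accessions),
    n_orthogroups = as.integer(n_orthogroups),
    core_fraction = core_fraction,
    occupancy_model = occupancy_model,
    occupancy_shape = occupancy_shape,
    genes_per_group = as.integer(genes_per_group),
    chrom_count = as.integer(chrom_count),
    chrom_length = chrom_length,
    anchor_dropout = anchor_dropout,
    anchor_jitter_sd = anchor_jitter_sd,
    position_jitter_sd = position_jitter_sd,
    og_error_rate = og_error_rate,
    feature_params = feature_params,
    expr_params = expr_params,
    enrich_params = as.data.frame(enrich_params),
    seed = as.integer(seed)
  )
  if (p$n_accessions < 2) stopf("n_accessions must be >= 2")
  probs <- c(p$core_fraction, p$anchor_dropout, p$og_error_rate,
             p$enrich_params$p_core, p$enrich_params$p_aux)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  slots_per_chrom_needed <- ceiling(p$n_orthogroups / p$chrom_count)
  if (is.null(p$chrom_length)) {
    p$chrom_length <- (slots_per_chrom_needed + 1L) * SLOT_BP
  }
  p$chrom_length <- as.integer(p$chrom_length)
  class(p) <- "simulation_params"
  p
}

#' Default term-enrichment structure for the generator
#'
#' One planted auxiliary-enriched term (defense-type, 0.20 vs 0.05) plus
#' background terms assigned at equal class probabilities.
#'
#' @return data.frame (term_id, term_name, p_core, p_aux).
#' @export
default_enrich_params <- function() {
  data.frame(
    term_id = c("GO:0009607", "GO:0008152", "GO:0006355", "GO:0016020"),
    term_name = c("response to biotic stimulus", "metabolic process",
                  "regulation of transcription", "membrane"),
    p_core = c(0.05, 0.10, 0.10, 0.10),
    p_aux  = c(0.20, 0.10, 0.10, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Generate the synthetic ground truth
#'
#' Draws, deterministically from `params$seed`: per-orthogroup occupancy
#' (floor(core_fraction * G) groups at occupancy N, the rest from the
#' occupancy model over 1..N-1), carrier accessions (uniform without
#' replacement), ancestral chromosome slots, per-orthogroup gene structure
#' (length, intron count, CDS split) from the class-specific feature
#' distributions, per-copy TPM, per-orthogroup term assignments, and the
#' pre-draws used by the mis-merge and anchor emitters.
#'
#' @param params a [simulation_params()] object.
#' @return a `synthetic_truth`: list with `params`, `og` (per-orthogroup
#'   table incl. class/occupancy/position/structure), `genes` (per-copy
#'   table), `terms` (og_id, term_id, term_name) and internal stage seeds.
#' @export
generate_truth <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(params$seed, {
    N <- params$n_accessions
    G <- params$n_orthogroups
    accs <- sprintf("ACC%02d", seq_len(N))
    n_core <- as.integer(floor(params$core_fraction * G))
    n_aux <- G - n_core

    occ_aux <- if (n_aux == 0) integer(0) else switch(params$occupancy_model,
      uniform = sample.int(N - 1L, n_aux, replace = TRUE),
      beta = {
        a <- params$occupancy_shape[1]; b <- params$occupancy_shape[2]
        pmin(N - 1L, 1L + as.integer(floor(rbeta(n_aux, a, b) * (N - 1L))))
      })
    og <- data.table(
      og_id = sprintf("OG%07d", seq_len(G)),
      class = rep(c("core", "auxiliary"), c(n_core, n_aux)),
      occupancy = c(rep(N, n_core), occ_aux)
    )

    # ancestral slot layout, shared across accessions
    spc <- params$chrom_length %/% SLOT_BP
    if (params$chrom_count * spc < G) {
      stopf("chromosome capacity exceeded (%d slots for %d orthogroups); increase chrom_length",
            params$chrom_count * spc, G)
    }
    slot_idx <- sample.int(params$chrom_count * spc, G)
    og[, chrom := (slot_idx - 1L) %/% spc + 1L]
    og[, seq_id := sprintf("chr%02d", chrom)]
    og[, anc_start := ((slot_idx - 1L) %% spc) * SLOT_BP + SLOT_HEAD + 1L]
    og[, strand := sample(c("+", "-"), G, replace = TRUE)]

    # per-orthogroup gene structure from class feature distributions
    fp <- params$feature_params
    pick <- function(field) {
      ifelse(og$class == "core", fp$core[[field]], fp$aux[[field]])
    }
    mlen <- pick("mean_length"); sdl <- pick("sdlog")
    og[, len := as.integer(pmin(pmax(round(rlnorm(G, log(mlen) - sdl^2 / 2, sdl)), LEN_MIN), LEN_MAX))]
    og[, intron_count := pmin(rpois(G, pick("intron_rate")), (len - 20L) %/% 40L)]
    og[, cds_total := pmin(pmax(as.integer(round(pick("cds_fraction") * len)),
                                20L * (intron_count + 1L)),
                           len - 20L * intron_count)]
    og[intron_count == 0L, cds_total := len]

    # carrier accessions: uniform without replacement
    dd <- CJ(idx = seq_len(G), acc = seq_len(N))
    dd[, key2 := runif(.N)]
    dd[, rk := frank(key2, ties.method = "first"), by = idx]
    dd <- dd[rk <= og$occupancy[idx]]

    genes <- og[dd$idx, .(og_id, class, seq_id, anc_start, len, strand)]
    genes[, accession := accs[dd$acc]]
    jit <- if (params$position_jitter_sd > 0) {
      as.integer(pmin(pmax(round(rnorm(nrow(genes), 0, params$position_jitter_sd)),
                           -(SLOT_HEAD - 100L)), SLOT_HEAD - 100L))
    } else 0L
    genes[, start := anc_start + jit]
    genes[, end := start + len - 1L]
    ep <- params$expr_params
    genes[, tpm := rlnorm(.N,
                          ifelse(class == "core", ep$core$meanlog, ep$aux$meanlog),
                          ifelse(class == "core", ep$core$sdlog, ep$aux$sdlog))]
    genes[, tpm := round(tpm, 3)]
    setorder(genes, accession, seq_id, start, og_id)
    genes[, gene_id := sprintf("g%06d", seq_len(.N)), by = accession]
    genes[, global := global_gene_id(accession, gene_id)]

    # per-orthogroup term assignment
    en <- params$enrich_params
    terms <- rbindlist(lapply(seq_len(nrow(en)), function(i) {
      pr <- ifelse(og$class == "core", en$p_core[i], en$p_aux[i])
      hit <- runif(G) < pr
      data.table(og_id = og$og_id[hit], term_id = en$term_id[i], term_name = en$term_name[i])
    }))

    # pre-draws for the orthogroup-error emitter: per-orthogroup uniform and
    # a mis-merge target family >= 50 kbp from the singleton's own locus
    og[, u_mm := runif(G)]
    fam_idx <- which(og$occupancy >= 2L)
    og[, target_og := NA_character_]
    if (length(fam_idx)) {
      cand <- fam_idx[pmin(length(fam_idx), 1L + as.integer(floor(runif(G) * length(fam_idx))))]
      too_close <- og$chrom[cand] == og$chrom &
        abs(og$anc_start[cand] - og$anc_start) < 50000L
      for (i in which(too_close)) {
        j <- match(cand[i], fam_idx)
        repeat {
          j <- j %% length(fam_idx) + 1L
          k <- fam_idx[j]
          if (og$chrom[k] != og$chrom[i] || abs(og$anc_start[k] - og$anc_start[i]) >= 50000L) {
            cand[i] <- k
            break
          }
        }
      }
      og[, target_og := og_id[cand]]
    }

    truth <- list(
      params = params,
      accessions = accs,
      og = og[],
      genes = genes[, .(og_id, class, accession, gene_id, global, seq_id, start, end, strand, tpm)],
      terms = terms,
      stage_seeds = sample.int(.Machine$integer.max - 1L, 4L)
    )
    class(truth) <- "synthetic_truth"
    truth
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: N=%d accessions, %d orthogroups (%.1f%% core), %d gene copies\n",
              x$params$n_accessions, nrow(x$og),
              100 * mean(x$og$class == "core"), nrow(x$genes)))
  invisible(x)
}

#' Emit per-accession genome annotations from a synthetic truth
#'
#' Each gene copy is placed at its orthogroup's ancestral slot (plus any
#' position jitter); CDS segments are derived from the orthogroup's stored
#' structure (identical across copies). Genes never overlap within an
#' accession because slots are disjoint.
#'
#' @param truth a `synthetic_truth`.
#' @return named list of `genome_annotation`, one per accession.
#' @export
emit_annotations <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  g <- truth$genes[truth$og[, .(og_id, len, intron_count, cds_total)], on = "og_id", nomatch = NULL]
  cds <- expand_cds(g)
  anns <- lapply(truth$accessions, function(a) {
    ga <- g[accession == a]
    setorder(ga, seq_id, start)
    if (nrow(ga) > 1) {
      ov <- ga[, any(start[-1] <= cummax(end[-.N])), by = seq_id][V1 == TRUE]
      if (nrow(ov)) stopf("overlapping genes on %s of %s; increase chrom_length", ov$seq_id[1], a)
    }
    out <- list(
      accession_id = a,
      genes = ga[, .(gene_id, seq_id, start, end, strand)],
      cds = cds[accession == a, .(gene_id, start, end)]
    )
    class(out) <- "genome_annotation"
    out
  })
  names(anns) <- truth$accessions
  anns
}

# derive CDS segments from (len, intron_count, cds_total): exons split as
# evenly as integers allow (remainder on the first exon), introns likewise
expand_cds <- function(g) {
  ne <- g$intron_count + 1L
  ebase <- g$cds_total %/% ne
  erem <- g$cds_total %% ne
  ibase <- ifelse(g$intron_count > 0L, (g$len - g$cds_total) %/% g$intron_count, 0L)
  irem <- ifelse(g$intron_count > 0L, (g$len - g$cds_total) %% g$intron_count, 0L)
  idx <- rep(seq_len(nrow(g)), ne)
  j <- sequence(ne)
  off <- (j - 1L) * (ebase[idx] + ibase[idx]) + (j > 1L) * (erem[idx] + irem[idx])
  cs <- g$start[idx] + off
  ce <- cs + ebase[idx] + (j == 1L) * erem[idx] - 1L
  data.table(accession = g$accession[idx], gene_id = g$gene_id[idx],
             start = as.integer(cs), end = as.integer(ce))
}

#' Emit an orthogroup table, optionally with mis-merge errors
#'
#' With `og_error_rate = 0` the table equals the truth partition. With rate
#' epsilon > 0, a fraction epsilon of auxiliary singletons are merged into a
#' pre-drawn random family whose ancestral locus lies >= 50 kbp away --
#' the false "present" calls the synteny filter is designed to remove.
#'
#' @param truth a `synthetic_truth`.
#' @param og_error_rate mis-merge probability; defaults to the value in
#'   `truth$params`.
#' @return an `orthogroup_table`; attribute `"mismerged"` records the
#'   injected calls (global, from_og, to_og).
#' @export
emit_orthogroups <- function(truth, og_error_rate = truth$params$og_error_rate) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mem <- truth$genes[, .(og_id, accession, gene_id, global)]
  mm <- truth$og[class == "auxiliary" & occupancy == 1L & u_mm < og_error_rate & !is.na(target_og),
                 .(og_id, target_og)]
  if (nrow(mm)) {
    mem[mm, on = "og_id", og_id := i.target_og]
  }
  tbl <- orthogroup_table(mem, truth$accessions)
  mmg <- truth$genes[mm$og_id, on = "og_id", nomatch = NULL][, .(global, from_og = og_id)]
  mmg[mm, on = c(from_og = "og_id"), to_og := i.target_og]
  attr(tbl, "mismerged") <- mmg
  tbl
}

#' Emit synteny anchors from a synthetic truth
#'
#' For every pair of accessions and every orthogroup present in both, one
#' anchor covering the two gene copies (endpoints shifted by Gaussian
#' jitter) is emitted with probability `1 - dropout`, then closed
#' symmetrically.
#'
#' @param truth a `synthetic_truth`.
#' @param dropout,jitter_sd override the values stored in `truth$params`.
#' @return an `anchor_set` (may be empty when `dropout = 1`).
#' @export
emit_anchors <- function(truth,
                         dropout = truth$params$anchor_dropout,
                         jitter_sd = truth$params$anchor_jitter_sd) {
  stopifnot(inherits(truth, "synthetic_truth"))
  g <- truth$genes[, .(og_id, accession, seq_id, start, end)]
  pairs <- merge(g, g, by = "og_id", allow.cartesian = TRUE,
                 suffixes = c("_a", "_b"))[accession_a < accession_b]
  with_seed(truth$stage_seeds[2], {
    n <- nrow(pairs)
    keep_row <- if (dropout >= 1) rep(FALSE, n) else runif(n) >= dropout
    sha <- if (jitter_sd > 0) as.integer(round(rnorm(n, 0, jitter_sd))) else integer(n)
    shb <- if (jitter_sd > 0) as.integer(round(rnorm(n, 0, jitter_sd))) else integer(n)
    pairs <- pairs[keep_row]
    sha <- sha[keep_row]; shb <- shb[keep_row]
    rec <- pairs[, .(acc_a = accession_a, seq_a = seq_id_a,
                     start_a = pmax(1L, start_a + sha), end_a = pmax(1L, end_a + sha),
                     acc_b = accession_b, seq_b = seq_id_b,
                     start_b = pmax(1L, start_b + shb), end_b = pmax(1L, end_b + shb))]
    if (nrow(rec) == 0) {
      rec <- data.table(acc_a = character(0), seq_a = character(0),
                        start_a = integer(0), end_a = integer(0),
                        acc_b = character(0), seq_b = character(0),
                        start_b = integer(0), end_b = integer(0))
    }
    anchor_set(rec, truth$accessions)
  })
}

#' Emit a per-gene expression table
#'
#' @param truth a `synthetic_truth`.
#' @return data.table (accession, gene_id, tpm, global); TPM values are the
#'   truth's class-specific log-normal draws.
#' @export
emit_expression <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  truth$genes[, .(accession, gene_id, tpm, global)]
}

#' Emit a gene-to-term map
#'
#' Terms were assigned per orthogroup (all member genes share them); the
#' emitted map is gene-level, keyed by global gene ID.
#'
#' @param truth a `synthetic_truth`.
#' @return data.table (gene_id, term_id, term_name) with global gene IDs.
#' @export
emit_terms <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  m <- merge(truth$genes[, .(og_id, global)], truth$terms,
             by = "og_id", allow.cartesian = TRUE)
  out <- m[, .(gene_id = global, term_id, term_name)]
  setorder(out, gene_id, term_id)
  out[]
}

#' Simulate a pangenome and write every pipeline input to disk
#'
#' One call emits, under `out_dir`: per-accession GFF3 files, the
#' orthogroups + unassigned-genes tables, the anchors TSV, expression and
#' term TSVs, truth tables for recovery checks, and `params.json`. Output
#' bytes are a deterministic function of `params` (including its seed).
#'
#' @param params a [simulation_params()] object.
#' @param out_dir output directory (created if needed).
#' @return the `synthetic_truth`, invisibly.
#' @export
simulate_pangenome <- function(params, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(params)
  anns <- emit_annotations(truth)
  for (a in names(anns)) write_gff3(anns[[a]], file.path(out_dir, paste0(a, ".gff3")))
  tbl <- emit_orthogroups(truth)
  write_orthogroups(tbl, file.path(out_dir, "Orthogroups.tsv"),
                    file.path(out_dir, "Orthogroups_UnassignedGenes.tsv"))
  anch <- emit_anchors(truth)
  write_table(as.data.table(anch)[order(acc_a, seq_a, start_a, acc_b, seq_b, start_b)],
              file.path(out_dir, "anchors.tsv"))
  write_table(emit_expression(truth)[, .(accession, gene_id, tpm)],
              file.path(out_dir, "expression.tsv"))
  write_table(emit_terms(truth), file.path(out_dir, "terms.tsv"))
  write_table(truth$og[, .(og_id, class, occupancy, seq_id, anc_start, len, intron_count, cds_total)],
              file.path(out_dir, "truth_orthogroups.tsv"))
  write_table(truth$genes, file.path(out_dir, "truth_genes.tsv"))
  pj <- truth$params
  pj$enrich_params <- as.data.frame(pj$enrich_params)
  jsonlite::write_json(unclass(pj), file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
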