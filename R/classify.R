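# Dual-evidence core/auxiliary designation: orthogroup membership is only
# trusted where a whole-genome-alignment anchor lies within W bp (default
# 5000) of both genes of a cross-accession member pair. Genes whose every
# ortholog call fails the filter revert to singletons, so gene-family
# over-grouping cannot inflate occupancy.

# one undirected record per anchor (drops the symmetric-closure twins)
canonical_anchors <- function(anchors) {
  dt <- as.data.table(anchors)
  keyfwd <- paste(dt$acc_a, dt$seq_a, dt$start_a, dt$end_a,
                  dt$acc_b, dt$seq_b, dt$start_b, dt$end_b, sep = "\r")
  keyrev <- paste(dt$acc_b, dt$seq_b, dt$start_b, dt$end_b,
                  dt$acc_a, dt$seq_a, dt$start_a, dt$end_a, sep = "\r")
  dt[keyfwd <= keyrev]
}

#' Anchor distance between two genes
#'
#' For each anchor joining the two genes' accessions (matching each gene's
#' chromosome on its side), the per-side distance is 0 if the anchor
#' interval overlaps the gene span, else the bp gap between them; the
#' anchor's distance is the max of its two sides. Returns the minimum over
#' anchors, or `Inf` when no anchor qualifies.
#'
#' @param gene_a,gene_b lists (or one-row data.frames) with fields
#'   `accession`, `seq_id`, `start`, `end`.
#' @param anchors an [anchor_set()].
#' @return distance in bp (0 for overlap), or `Inf`.
#' @export
anchor_distance <- function(gene_a, gene_b, anchors) {
  a <- as.list(gene_a); b <- as.list(gene_b)
  dt <- as.data.table(anchors)
  hits <- dt[acc_a == a$accession & seq_a == a$seq_id &
             acc_b == b$accession & seq_b == b$seq_id]
  if (nrow(hits) == 0) return(Inf)
  da <- interval_gap(hits$start_a, hits$end_a, a$start, a$end)
  db <- interval_gap(hits$start_b, hits$end_b, b$start, b$end)
  min(pmax(da, db))
}

# long gene table (global, accession, seq_id, start, end) from one
# annotation, a list of annotations, or an already-long data.frame
gene_table <- function(annotations) {
  if (inherits(annotations, "genome_annotation")) annotations <- list(annotations)
  if (is.data.frame(annotations)) {
    g <- as.data.table(annotations)
    if (!"global" %in% names(g)) g[, global := global_gene_id(accession, gene_id)]
    return(g[, .(global, accession, gene_id, seq_id, start, end)])
  }
  rbindlist(lapply(annotations, function(a) {
    data.table(global = global_gene_id(a$accession_id, a$genes$gene_id),
               accession = a$accession_id, gene_id = a$genes$gene_id,
               seq_id = a$genes$seq_id, start = a$genes$start, end = a$genes$end)
  }))
}

#' Filter ortholog calls by alignment proximity
#'
#' Builds every cross-accession member pair of every orthogroup and marks a
#' pair retained iff some anchor lies within `W` bp of both genes
#' (inclusive boundary; [anchor_distance()] semantics). `W = Inf` retains
#' all pairs (pure orthogroup evidence); a negative `W` retains none.
#'
#' @param table an `orthogroup_table`.
#' @param annotations annotation(s) resolving every member gene (a
#'   `genome_annotation`, list of them, or a long gene data.frame).
#' @param anchors an [anchor_set()]; may be `NULL` when `W` is infinite or
#'   negative.
#' @param W proximity window in bp (default 5000).
#' @return `filtered_calls` data.table (og_id, gene_a, gene_b, acc_a, acc_b,
#'   min_anchor_distance, retained) with attribute `W`; `min_anchor_distance`
#'   is exact within `[0, W]` and `Inf` beyond the window.
#' @export
filter_ortholog_calls <- function(table, annotations, anchors, W = 5000) {
  stopifnot(inherits(table, "orthogroup_table"))
  genes <- gene_table(annotations)
  mem <- merge(table$members, genes[, .(global, seq_id, start, end)],
               by = "global", all.x = TRUE)
  if (anyNA(mem$seq_id)) {
    stopf("gene %s not resolvable in the annotations", mem[is.na(seq_id)]$global[1])
  }

  m <- merge(mem, mem, by = "og_id", allow.cartesian = TRUE, suffixes = c("_a", "_b"))
  m <- m[global_a < global_b & accession_a != accession_b]
  calls <- m[, .(og_id, gene_a = global_a, gene_b = global_b,
                 acc_a = accession_a, acc_b = accession_b)]

  if (is.infinite(W) && W > 0) {
    calls[, min_anchor_distance := NA_real_]
    calls[, retained := TRUE]
  } else if (W < 0 || is.null(anchors) || nrow(as.data.table(anchors)) == 0) {
    calls[, min_anchor_distance := Inf]
    calls[, retained := FALSE]
  } else {
    anch <- canonical_anchors(anchors)
    anch[, uid := .I]
    Wi <- as.integer(W)
    gk <- genes[, .(global, accession, seq_id, start, end)]
    setkey(gk, accession, seq_id, start, end)
    side_hits <- function(acc_col, seq_col, s_col, e_col) {
      q <- anch[, .(uid,
                    accession = get(acc_col), seq_id = get(seq_col),
                    as_ = get(s_col), ae_ = get(e_col))]
      q[, `:=`(qs = pmax(1L, as_ - Wi), qe = ae_ + Wi)]
      h <- foverlaps(q, gk, by.x = c("accession", "seq_id", "qs", "qe"),
                     by.y = c("accession", "seq_id", "start", "end"),
                     type = "any", nomatch = NULL)
      h[, .(uid, g = global, gap = interval_gap(as_, ae_, start, end))]
    }
    ha <- side_hits("acc_a", "seq_a", "start_a", "end_a")
    hb <- side_hits("acc_b", "seq_b", "start_b", "end_b")
    sup <- merge(ha, hb, by = "uid", allow.cartesian = TRUE,
                 suffixes = c("_a", "_b"))[g_a != g_b]
    calls[, min_anchor_distance := Inf]
    if (nrow(sup)) {
      sup <- sup[, .(d = min(pmax(gap_a, gap_b))),
                 by = .(gene_a = pmin(g_a, g_b), gene_b = pmax(g_a, g_b))]
      calls[sup, on = c("gene_a", "gene_b"), min_anchor_distance := i.d]
    }
    calls[, retained := min_anchor_distance <= W]
  }
  setattr(calls, "W", W)
  setattr(calls, "class", c("filtered_calls", class(calls)))
  calls[]
}

#' Core/auxiliary classification from filtered ortholog calls
#'
#' Genes keeping at least one retained call stay in their orthogroup;
#' genes whose every call was filtered out (and original singletons) become
#' their own occupancy-1 units. A unit is core iff its retained members
#' span all `N` accessions; gene labels are inherited from their unit.
#'
#' @param table the `orthogroup_table` the calls were computed from.
#' @param filtered output of [filter_ortholog_calls()].
#' @param N accession count (defaults to `length(table$accessions)`).
#' @return a `pav_labels`: list with `units` (unit_id, og_id, occupancy,
#'   size, label), `gene_labels` (accession, gene_id, global, og_id,
#'   unit_id, retained, label), `N`, `W`.
#' @export
classify <- function(table, filtered, N = length(table$accessions)) {
  stopifnot(inherits(table, "orthogroup_table"))
  ret <- as.data.table(filtered)[retained == TRUE]
  kept_genes <- unique(c(ret$gene_a, ret$gene_b))

  gl <- copy(table$members)
  gl[, retained := global %chin% kept_genes]
  gl[, unit_id := fifelse(retained, og_id, global)]

  units <- gl[, .(og_id = og_id[1], occupancy = uniqueN(accession), size = .N),
              by = unit_id]
  units[, label := fifelse(occupancy == N, "core", "auxiliary")]

  gl[units, on = "unit_id", label := i.label]
  out <- list(units = units[], gene_labels = gl[], N = N, W = attr(filtered, "W"))
  class(out) <- "pav_labels"
  out
}

#' One-call dual-evidence classification
#'
#' Convenience wrapper running [filter_ortholog_calls()] then [classify()].
#' `mode = "orthogroup"` skips the anchor filter (`W = Inf`).
#'
#' @param table an `orthogroup_table`.
#' @param annotations annotation(s) resolving every member gene.
#' @param anchors an [anchor_set()] (ignored for `mode = "orthogroup"`).
#' @param W proximity window in bp.
#' @param mode `"dual"` (default) or `"orthogroup"`.
#' @return a `pav_labels`.
#' @export
classify_pav <- function(table, annotations, anchors = NULL, W = 5000,
                         mode = c("dual", "orthogroup")) {
  mode <- match.arg(mode)
  if (mode == "orthogroup") W <- Inf
  fc <- filter_ortholog_calls(table, annotations, anchors, W)
  classify(table, fc)
}

#' @export
print.pav_labels <- function(x, ...) {
  cat(sprintf("pav_labels: N=%d, W=%s; %d units (%d core), %d genes (%d core)\n",
              x$N, format(x$W), nrow(x$units), sum(x$units$label == "core"),
              nrow(x$gene_labels), sum(x$gene_labels$label == "core")))
  invisible(x)
}

#' Reference-projected synteny presence matrix
#'
#' Marks a reference gene present in accession X iff at least
#' `coverage_threshold` of its span is covered by the union of anchor
#' intervals aligning the reference to X. A gene is reference-core iff
#' present in every queried accession.
#'
#' @param ref reference `genome_annotation`.
#' @param anchors an [anchor_set()] connecting the reference to each
#'   accession.
#' @param accessions accessions to project onto (reference excluded).
#' @param coverage_threshold minimum covered fraction of the gene span.
#' @return logical `presence_matrix` (genes x accessions) with attributes
#'   `provenance = "synteny"` and `coverage_threshold`.
#' @export
project_to_reference <- function(ref, anchors, accessions, coverage_threshold = 0.5) {
  stopifnot(inherits(ref, "genome_annotation"))
  dt <- as.data.table(anchors)
  ref_acc <- ref$accession_id
  accessions <- setdiff(accessions, ref_acc)
  have <- unique(dt[acc_a == ref_acc, acc_b])
  missing <- setdiff(accessions, have)
  if (length(missing)) {
    stopf("accession(s) absent from the anchor set: %s", paste(missing, collapse = ", "))
  }
  g <- ref$genes
  # fold (seq_id, pos) into one axis so a single IRanges handles all chromosomes
  seqs <- sort(unique(c(g$seq_id, dt[acc_a == ref_acc, seq_a])))
  span <- max(c(g$end, dt[acc_a == ref_acc, end_a], 1L)) + 1L
  offs <- setNames((seq_along(seqs) - 1) * as.numeric(span), seqs)
  gr <- IRanges::IRanges(start = g$start + offs[g$seq_id], end = g$end + offs[g$seq_id])
  mat <- matrix(FALSE, nrow = nrow(g), ncol = length(accessions),
                dimnames = list(g$gene_id, accessions))
  for (x in accessions) {
    a <- dt[acc_a == ref_acc & acc_b == x]
    if (nrow(a) == 0) next
    ar <- IRanges::reduce(IRanges::IRanges(start = a$start_a + offs[a$seq_a],
                                           end = a$end_a + offs[a$seq_a]))
    hits <- IRanges::findOverlaps(gr, ar)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    pi_ <- IRanges::pintersect(gr[qi], ar[S4Vectors::subjectHits(hits)])
    cov <- rowsum(IRanges::width(pi_), qi)
    frac <- as.vector(cov) / IRanges::width(gr)[as.integer(rownames(cov))]
    mat[as.integer(rownames(cov)), x] <- frac >= coverage_threshold
  }
  structure(mat, provenance = "synteny", coverage_threshold = coverage_threshold,
            class = c("presence_matrix", class(mat)))
}

#' Reference-core gene IDs from a presence matrix
#'
#' @param mat a `presence_matrix` (or any logical matrix, genes x accessions).
#' @return character vector of genes present in every accession.
#' @export
reference_core <- function(mat) {
  rownames(mat)[rowSums(mat) == ncol(mat)]
}

#' Summarise a classification
#'
#' Per-accession and overall core/auxiliary gene counts, plus unit-level
#' counts, with percentages `100 * core / total` rounded half-up to
#' `digits` decimals (matching how such tables are printed).
#'
#' @param labels a `pav_labels`.
#' @param digits decimals kept in percentages (0 for integer percent).
#' @return a `pav_summary`: list with `per_accession` (accession, n_core,
#'   n_total, pct_core), `overall` (mean per-accession counts and percent)
#'   and `units`.
#' @export
summarize_pav <- function(labels, digits = 0) {
  stopifnot(inherits(labels, "pav_labels"))
  gl <- labels$gene_labels
  per <- gl[, .(n_core = sum(label == "core"), n_total = .N), by = accession]
  per[, pct_core := pav_percent(n_core, n_total, digits)]
  setorder(per, accession)
  mc <- mean(per$n_core); mt <- mean(per$n_total)
  un <- labels$units
  out <- list(
    per_accession = per[],
    overall = list(mean_core = mc, mean_total = mt,
                   pct_core = pav_percent(mc, mt, digits),
                   pct_aux = pav_percent(mt - mc, mt, digits)),
    units = list(n_core = sum(un$label == "core"), n_total = nrow(un),
                 pct_core = pav_percent(sum(un$label == "core"), nrow(un), digits))
  )
  class(out) <- "pav_summary"
  out
}

#' @export
print.pav_summary <- function(x, ...) {
  cat(sprintf("mean per-accession: %.1f core / %.1f total genes (%s%% core)\n",
              x$overall$mean_core, x$overall$mean_total, format(x$overall$pct_core)))
  cat(sprintf("units: %d core / %d total (%s%% core)\n",
              x$units$n_core, x$units$n_total, format(x$units$pct_core)))
  invisible(x)
}

#' Percentage under the printed-report rounding rule
#'
#' `100 * core / total`, rounded half-up to `digits` decimals.
#'
#' @param core,total counts.
#' @param digits decimals kept.
#' @return numeric percentage.
#' @export
pav_percent <- function(core, total, digits = 0) {
  round_half_up(100 * core / total, digits)
}
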