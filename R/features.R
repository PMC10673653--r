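# Per-gene structural/expression statistics and the core-vs-auxiliary
# contrast (rank-sum). On the collapsed one-isoform gene model,
# intron_count = cds_count - 1 and the total intron length is the coding
# footprint (first CDS start .. last CDS end) minus the CDS length.

#' Per-gene feature rows
#'
#' Computes, for every gene of the annotation(s): gene length (span),
#' CDS length and segment count, intron count and total intron length, and
#' (when supplied) TPM. Genes lacking a TPM record carry `NA`, not 0.
#'
#' @param annotations a `genome_annotation` or list of them.
#' @param labels a `pav_labels` covering every gene (classification is an
#'   error-out prerequisite, not optional).
#' @param expr optional expression table (accession, gene_id, tpm), as from
#'   [read_expression()] or [emit_expression()].
#' @return a `feature_table` data.table: global, accession, gene_id, label,
#'   gene_length, cds_length, cds_count, intron_count, intron_length_total,
#'   tpm.
#' @export
compute_features <- function(annotations, labels, expr = NULL) {
  stopifnot(inherits(labels, "pav_labels"))
  if (inherits(annotations, "genome_annotation")) annotations <- list(annotations)
  rows <- rbindlist(lapply(annotations, function(ann) {
    agg <- ann$cds[, .(cds_length = sum(end - start + 1L), cds_count = .N,
                       first_cds = min(start), last_cds = max(end)), by = gene_id]
    g <- merge(ann$genes, agg, by = "gene_id", all.x = TRUE)
    g[, accession := ann$accession_id]
    g
  }))
  rows[, global := global_gene_id(accession, gene_id)]
  rows[, gene_length := end - start + 1L]
  rows[, intron_count := cds_count - 1L]
  rows[, intron_length_total := (last_cds - first_cds + 1L) - cds_length]

  lab <- labels$gene_labels[, .(global, label)]
  rows <- merge(rows, lab, by = "global", all.x = TRUE)
  if (anyNA(rows$label)) {
    stopf("gene %s has no core/auxiliary label", rows[is.na(label)]$global[1])
  }
  if (!is.null(expr)) {
    e <- as.data.table(expr)
    if (!"global" %in% names(e)) e[, global := global_gene_id(accession, gene_id)]
    rows[e, on = "global", tpm := i.tpm]
  } else {
    rows[, tpm := NA_real_]
  }
  out <- rows[, .(global, accession, gene_id, label, gene_length, cds_length,
                  cds_count, intron_count, intron_length_total, tpm)]
  setattr(out, "class", c("feature_table", class(out)))
  out[]
}

#' Core-vs-auxiliary contrast of one feature
#'
#' Wilcoxon rank-sum comparison of the feature between core and auxiliary
#' genes: exact two-sided p when both groups have n <= 8, otherwise the
#' normal approximation with continuity correction (via
#' [stats::wilcox.test()]). Medians and quartiles are the primary output;
#' `direction` is `sign(median_core - median_aux)`.
#'
#' @param rows a [compute_features()] table.
#' @param feature feature column to compare (e.g. `"gene_length"`,
#'   `"tpm"`); `NA` values (missing TPM) are dropped from the comparison.
#' @return one-row data.table: feature, n_core, n_aux, mean/median/q1/q3
#'   per class, U, p, direction.
#' @export
compare_groups <- function(rows, feature) {
  rows <- as.data.table(rows)
  if (!feature %in% names(rows)) stopf("unknown feature '%s'", feature)
  x <- rows[label == "core"][[feature]]
  y <- rows[label == "auxiliary"][[feature]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stopf("both classes must be represented for feature '%s'", feature)
  }
  exact <- length(x) <= 8 && length(y) <= 8
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  qx <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  qy <- quantile(y, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.table(
    feature = feature,
    n_core = length(x), n_aux = length(y),
    mean_core = mean(x), mean_aux = mean(y),
    median_core = qx[2], median_aux = qy[2],
    q1_core = qx[1], q3_core = qx[3],
    q1_aux = qy[1], q3_aux = qy[3],
    U = unname(wt$statistic),
    p = wt$p.value,
    direction = sign(qx[2] - qy[2])
  )
}

#' Contrast every standard feature at once
#'
#' @param rows a [compute_features()] table.
#' @param features feature columns to compare; TPM is included only when
#'   any value is present.
#' @return data.table, one row per feature (see [compare_groups()]).
#' @export
compare_all_features <- function(rows,
                                 features = c("gene_length", "cds_length", "cds_count",
                                              "intron_count", "intron_length_total", "tpm")) {
  rows <- as.data.table(rows)
  if ("tpm" %in% features && all(is.na(rows$tpm))) features <- setdiff(features, "tpm")
  rbindlist(lapply(features, function(f) compare_groups(rows, f)))
}
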