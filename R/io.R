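# Readers and writers for the external formats the pipeline touches:
# GFF3 gene annotations, OrthoFinder-dialect orthogroup tables, synteny
# anchor tables, expression (TPM) tables and gene->term maps. All tabular
# readers skip lines starting with "#".

read_lines_nocomment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

fread_nocomment <- function(path, sep = "\t", header = TRUE, colClasses = NULL) {
  lines <- read_lines_nocomment(path)
  if (length(lines) == 0) stopf("no data lines in %s", path)
  data.table::fread(
    text = paste0(paste(lines, collapse = "\n"), "\n"),
    sep = sep, header = header, colClasses = colClasses, quote = "\""
  )
}

#' Read a GFF3 gene annotation
#'
#' Parses gene/mRNA/CDS features (via [rtracklayer::import]) into a
#' `genome_annotation`: one model per gene, multi-isoform genes collapsed to
#' the isoform with the largest total CDS length (ties broken by transcript
#' ID). Coordinates are 1-based inclusive throughout.
#'
#' @param path path to a GFF3 file.
#' @param accession accession identifier; defaults to the file name without
#'   its `.gff`/`.gff3` extension.
#' @return a `genome_annotation`: list with `accession_id`, `genes`
#'   (data.table: gene_id, seq_id, start, end, strand) and `cds`
#'   (data.table: gene_id, start, end; segments sorted, non-overlapping).
#' @export
read_gff3 <- function(path, accession = NULL) {
  if (is.null(accession)) accession <- sub("\\.gff3?$", "", basename(path))

  # pre-scan: reject malformed coordinates with the offending line number
  raw <- readLines(path, warn = FALSE)
  feat <- which(!startsWith(raw, "#") & nzchar(raw))
  if (length(feat)) {
    parts <- strsplit(raw[feat], "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 8)) stopf("malformed GFF3 record at line %d of %s", feat[which(nf < 8)[1]], path)
    st <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 4L)))
    en <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 5L)))
    bad <- which(is.na(st) | is.na(en))
    if (length(bad)) stopf("non-integer coordinates at line %d of %s", feat[bad[1]], path)
    bad <- which(en < st)
    if (length(bad)) {
      stopf("coordinate error at line %d of %s: end (%d) < start (%d)",
            feat[bad[1]], path, en[bad[1]], st[bad[1]])
    }
  }

  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  dt <- data.table(
    type = type,
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = as.character(gr$ID)
  )
  parents <- gr$Parent # CharacterList

  genes <- dt[type == "gene"]
  if (nrow(genes) == 0) stopf("no gene features in %s", path)
  if (anyDuplicated(genes$id)) {
    stopf("duplicated gene ID in %s: %s", path, genes$id[duplicated(genes$id)][1])
  }

  is_tx <- type %in% c("mRNA", "transcript")
  tx <- dt[is_tx]
  tx[, parent := vapply(as.list(parents[is_tx]), function(p) if (length(p)) p[1] else NA_character_, "")]

  is_cds <- type == "CDS"
  if (!any(is_cds)) {
    stopf("gene(s) without CDS in %s: %s", path,
          paste(utils::head(genes$id, 5), collapse = ", "))
  }
  cds_par <- as.list(parents[is_cds])
  cds <- dt[is_cds][rep(seq_len(sum(is_cds)), lengths(cds_par))]
  cds[, parent := unlist(cds_par)]

  # CDS may hang off a transcript or (rarely) directly off the gene
  tx_of_gene <- setNames(tx$parent, tx$id)
  cds[, tx_id := parent]
  cds[, gene_of := fifelse(parent %chin% genes$id, parent, tx_of_gene[parent])]
  if (anyNA(cds$gene_of)) {
    stopf("CDS with unresolvable Parent '%s' in %s", cds$parent[is.na(cds$gene_of)][1], path)
  }

  # collapse to the longest-CDS isoform per gene
  iso <- cds[, .(cds_len = sum(end - start + 1L)), by = .(gene_of, tx_id)]
  setorder(iso, gene_of, -cds_len, tx_id)
  pick <- iso[, .SD[1], by = gene_of]
  missing_cds <- setdiff(genes$id, pick$gene_of)
  if (length(missing_cds)) {
    stopf("gene(s) without CDS in %s: %s", path,
          paste(utils::head(missing_cds, 5), collapse = ", "))
  }

  keep <- cds[pick[, .(gene_of, tx_id)], on = c("gene_of", "tx_id")]
  cds_out <- keep[, .(gene_id = gene_of, start, end)]
  setorder(cds_out, gene_id, start)

  # validate containment and non-overlap of CDS segments
  gidx <- genes[, .(gene_id = id, gstart = start, gend = end)]
  chk <- cds_out[gidx, on = "gene_id"]
  if (chk[, any(start < gstart | end > gend)]) {
    stopf("CDS segment outside gene span in %s", path)
  }
  ov <- cds_out[, .(bad = any(start[-1] <= cummax(end[-.N])) && .N > 1), by = gene_id]
  if (any(ov$bad)) stopf("overlapping CDS segments for gene %s in %s", ov[bad == TRUE]$gene_id[1], path)

  out <- list(
    accession_id = accession,
    genes = genes[, .(gene_id = id, seq_id, start, end, strand)],
    cds = cds_out
  )
  class(out) <- "genome_annotation"
  out
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_gff3()] for the collapsed one-isoform-per-gene model;
#' each gene gets a single mRNA (`<gene>.t1`) carrying its CDS segments.
#'
#' @param ann a `genome_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- copy(ann$genes)
  setorder(g, seq_id, start, gene_id)
  cds <- ann$cds
  gl <- sprintf("%s\tvpav\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$seq_id, g$start, g$end, g$strand, g$gene_id)
  ml <- sprintf("%s\tvpav\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                g$seq_id, g$start, g$end, g$strand, g$gene_id, g$gene_id)
  cd <- cds[g[, .(gene_id, seq_id, strand)], on = "gene_id"]
  setorder(cd, seq_id, start, gene_id)
  cl <- sprintf("%s\tvpav\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.t1.cds;Parent=%s.t1",
                cd$seq_id, cd$start, cd$end, cd$strand, cd$gene_id, cd$gene_id)
  # interleave per gene: gene, mRNA, then its CDS lines
  ord <- order(match(cd$gene_id, g$gene_id), cd$start)
  blocks <- split(cl[ord], match(cd$gene_id[ord], g$gene_id))
  lines <- character(0)
  body <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    body[[i]] <- c(gl[i], ml[i], blocks[[as.character(i)]])
  }
  writeLines(c("##gff-version 3", unlist(body)), path)
  invisible(path)
}

#' Read OrthoFinder-dialect orthogroup tables
#'
#' Parses an `Orthogroups` table plus (optionally) an
#' `Orthogroups_UnassignedGenes` table. Both are one orthogroup per row,
#' first column the orthogroup ID, one column per accession, cells holding
#' `", "`-separated gene lists. Tab- and comma-delimited exports are both
#' accepted (sniffed from the header line). Unassigned genes become
#' singleton orthogroups.
#'
#' @param groups_path path to the orthogroups table.
#' @param unassigned_path optional path to the unassigned-genes table.
#' @param accessions optional character vector of expected accession
#'   columns; any other column is rejected.
#' @return an `orthogroup_table`: list with `accessions`, `members`
#'   (data.table: og_id, accession, gene_id, global) and `og` (data.table:
#'   og_id, size, n_acc, singleton).
#' @export
read_orthogroups <- function(groups_path, unassigned_path = NULL, accessions = NULL) {
  parse_one <- function(path) {
    first <- read_lines_nocomment(path)[1]
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
    dt <- fread_nocomment(path, sep = sep, colClasses = "character")
    og_col <- names(dt)[1]
    acc_cols <- names(dt)[-1]
    if (!is.null(accessions)) {
      unknown <- setdiff(acc_cols, accessions)
      if (length(unknown)) stopf("unknown accession column(s) in %s: %s",
                                 path, paste(unknown, collapse = ", "))
    }
    long <- melt(dt, id.vars = og_col, variable.name = "accession",
                 value.name = "cell", variable.factor = FALSE)
    setnames(long, og_col, "og_id")
    long <- long[!is.na(cell) & nzchar(trimws(cell))]
    genes <- strsplit(long$cell, ",[ ]?")
    out <- long[rep(seq_len(.N), lengths(genes))]
    out[, gene_id := trimws(unlist(genes))]
    out[, cell := NULL]
    list(members = out[nzchar(gene_id)], accessions = acc_cols)
  }

  gp <- parse_one(groups_path)
  members <- gp$members
  acc <- if (is.null(accessions)) gp$accessions else accessions

  if (!is.null(unassigned_path)) {
    up <- parse_one(unassigned_path)
    bad <- up$members[, .N, by = og_id][N > 1]
    if (nrow(bad)) stopf("unassigned-genes row %s lists more than one gene", bad$og_id[1])
    clash <- intersect(up$members$og_id, members$og_id)
    if (length(clash)) stopf("orthogroup ID %s appears in both tables", clash[1])
    members <- rbind(members, up$members)
  }

  members[, global := global_gene_id(accession, gene_id)]
  dup <- members[duplicated(global) | duplicated(global, fromLast = TRUE)]
  if (nrow(dup)) {
    two <- unique(dup[, .(global, og_id)])
    multi <- two[, .N, by = global][N > 1]
    if (nrow(multi)) {
      stopf("gene %s is listed in more than one orthogroup", multi$global[1])
    }
    members <- unique(members)
  }
  orthogroup_table(members, acc)
}

#' Construct an orthogroup table from long-format membership
#'
#' @param members data.table/data.frame with columns og_id, accession,
#'   gene_id (and optionally global).
#' @param accessions accession identifiers (declares N).
#' @return an `orthogroup_table`.
#' @export
orthogroup_table <- function(members, accessions) {
  members <- as.data.table(members)
  if (!"global" %in% names(members)) {
    members[, global := global_gene_id(accession, gene_id)]
  }
  bad <- setdiff(unique(members$accession), accessions)
  if (length(bad)) stopf("member accession(s) not declared: %s", paste(bad, collapse = ", "))
  og <- members[, .(size = .N, n_acc = uniqueN(accession)), by = og_id]
  og[, singleton := size == 1L]
  out <- list(accessions = accessions,
              members = members[, .(og_id, accession, gene_id, global)],
              og = og)
  class(out) <- "orthogroup_table"
  out
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat(sprintf("orthogroup_table: %d orthogroups (%d singletons), %d genes, %d accessions\n",
              nrow(x$og), sum(x$og$singleton), nrow(x$members), length(x$accessions)))
  invisible(x)
}

#' Write an orthogroup table in the OrthoFinder dialect
#'
#' Multi-member orthogroups go to `groups_path`; singletons go to
#' `unassigned_path` (mirroring the `Orthogroups` /
#' `Orthogroups_UnassignedGenes` pair).
#'
#' @param tbl an `orthogroup_table`.
#' @param groups_path,unassigned_path output paths.
#' @return invisibly, the two paths.
#' @export
write_orthogroups <- function(tbl, groups_path, unassigned_path) {
  stopifnot(inherits(tbl, "orthogroup_table"))
  emit <- function(mem, path) {
    wide <- dcast(mem, og_id ~ factor(accession, levels = tbl$accessions),
                  value.var = "gene_id",
                  fun.aggregate = function(x) paste(sort(x), collapse = ", "),
                  drop = FALSE, fill = "")
    setnames(wide, "og_id", "Orthogroup")
    setorder(wide, Orthogroup)
    write_table(wide, path)
  }
  singles <- tbl$og[singleton == TRUE, og_id]
  emit(tbl$members[!og_id %in% singles], groups_path)
  emit(tbl$members[og_id %in% singles], unassigned_path)
  invisible(c(groups_path, unassigned_path))
}

ANCHOR_COLS <- c("acc_a", "seq_a", "start_a", "end_a", "acc_b", "seq_b", "start_b", "end_b")

#' Construct an anchor set (pairwise aligned intervals)
#'
#' Applies the symmetric closure: every record implies its side-swapped
#' twin, so queries are direction-free. Records are deduplicated.
#'
#' @param records data.frame with columns acc_a, seq_a, start_a, end_a,
#'   acc_b, seq_b, start_b, end_b (1-based inclusive bp).
#' @param accessions optional declared accession list.
#' @return an `anchor_set` (a data.table with the symmetric closure applied).
#' @export
anchor_set <- function(records, accessions = NULL) {
  dt <- as.data.table(records)[, ..ANCHOR_COLS]
  for (col in c("start_a", "end_a", "start_b", "end_b")) {
    set(dt, j = col, value = as.integer(dt[[col]]))
  }
  if (dt[, any(end_a < start_a | end_b < start_b)]) {
    stopf("anchor with end < start")
  }
  swapped <- dt[, .(acc_a = acc_b, seq_a = seq_b, start_a = start_b, end_a = end_b,
                    acc_b = acc_a, seq_b = seq_a, start_b = start_a, end_b = end_a)]
  out <- unique(rbind(dt, swapped))
  if (is.null(accessions)) accessions <- sort(unique(c(out$acc_a, out$acc_b)))
  bad <- setdiff(unique(c(out$acc_a, out$acc_b)), accessions)
  if (length(bad)) stopf("anchor accession(s) not declared: %s", paste(bad, collapse = ", "))
  setattr(out, "accessions", accessions)
  setattr(out, "class", c("anchor_set", class(out)))
  out[]
}

#' Read a synteny anchor table
#'
#' Eight-column TSV (`acc_a, seq_a, start_a, end_a, acc_b, seq_b, start_b,
#' end_b`); a leading `#`-prefixed header line is skipped, an unprefixed
#' header row is recognised and dropped. Non-integer coordinates are
#' rejected. The symmetric closure is applied.
#'
#' @param path path to the anchors TSV.
#' @param accessions optional declared accession list.
#' @return an `anchor_set`.
#' @export
read_anchors <- function(path, accessions = NULL) {
  lines <- read_lines_nocomment(path)
  if (length(lines) == 0) stopf("no anchor records in %s", path)
  dt <- data.table::fread(text = paste0(paste(lines, collapse = "\n"), "\n"),
                          sep = "\t", header = FALSE, colClasses = "character")
  if (ncol(dt) != 8) stopf("expected 8 columns in %s, found %d", path, ncol(dt))
  if (identical(unname(unlist(dt[1])), ANCHOR_COLS)) dt <- dt[-1]
  setnames(dt, ANCHOR_COLS)
  for (col in c("start_a", "end_a", "start_b", "end_b")) {
    v <- dt[[col]]
    bad <- !grepl("^-?[0-9]+$", v)
    if (any(bad)) stopf("non-integer coordinate '%s' in column %s of %s", v[bad][1], col, path)
  }
  anchor_set(dt, accessions)
}

#' Read a per-gene expression (TPM) table
#'
#' TSV with columns `accession`, `gene_id`, `tpm`; TPM must be non-negative.
#'
#' @param path path to the expression TSV.
#' @return data.table (accession, gene_id, tpm, global).
#' @export
read_expression <- function(path) {
  dt <- fread_nocomment(path)
  need <- c("accession", "gene_id", "tpm")
  if (!all(need %in% names(dt))) stopf("expression table must have columns %s", paste(need, collapse = ", "))
  dt[, tpm := as.numeric(tpm)]
  if (dt[, any(is.na(tpm) | tpm < 0)]) stopf("TPM values must be non-negative numbers")
  dt[, global := global_gene_id(accession, gene_id)]
  dt[]
}

#' Read a gene-to-term annotation map
#'
#' TSV with columns `gene_id`, `term_id`, `term_name`. Term IDs that start
#' with `GO:` must match the `GO:NNNNNNN` pattern.
#'
#' @param path path to the term map TSV.
#' @return data.table (gene_id, term_id, term_name).
#' @export
read_term_map <- function(path) {
  dt <- fread_nocomment(path)
  need <- c("gene_id", "term_id", "term_name")
  if (!all(need %in% names(dt))) stopf("term map must have columns %s", paste(need, collapse = ", "))
  go <- startsWith(dt$term_id, "GO:")
  bad <- go & !grepl("^GO:[0-9]{7}$", dt$term_id)
  if (any(bad)) stopf("malformed GO term ID: %s", dt$term_id[bad][1])
  unique(dt[, .(gene_id, term_id, term_name)])
}

#' Write a table as TSV
#'
#' UTF-8, header row, newline-terminated; double columns are formatted at
#' 6 significant digits. Optional `#`-prefixed comment lines (e.g. the run
#' seed) are written above the header and skipped by all package readers.
#'
#' @param x data.frame with uniquely named columns.
#' @param path output path.
#' @param comments optional character vector written as `# <line>` headers.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, comments = NULL) {
  x <- as.data.table(x)
  if (anyDuplicated(names(x))) stopf("column names must be unique")
  cols <- lapply(x, function(col) {
    if (is.double(col) && !inherits(col, "integer64")) {
      ifelse(is.na(col), "NA", formatC(col, digits = 6, format = "g"))
    } else {
      as.character(col)
    }
  })
  header <- paste(names(x), collapse = "\t")
  body <- if (nrow(x)) do.call(paste, c(cols, sep = "\t")) else character(0)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  pre <- if (length(comments)) paste0("# ", comments) else character(0)
  writeLines(c(pre, header, body), con, sep = "\n")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path input path.
#' @return data.table.
#' @export
read_table <- function(path) fread_nocomment(path)
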