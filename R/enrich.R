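# Term (GO) over-representation of one gene class against the full gene
# universe: one-sided hypergeometric upper-tail p per term, odds ratio from
# the foreground-vs-universe 2x2 rates, Benjamini-Hochberg FDR across terms.

#' Benjamini-Hochberg step-up q-values
#'
#' Thin validated wrapper over `p.adjust(method = "BH")`: order-preserving,
#' monotone, q >= p.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return q-values, same order as input.
#' @export
bh_fdr <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stopf("p-values must be numbers in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Term over-representation in a gene set
#'
#' For each term annotating at least `min_count` universe genes, tests
#' over-representation in the foreground with the one-sided hypergeometric
#' upper tail: `p = P(X >= fg_with)` for X hypergeometric(bg_with,
#' bg_total - bg_with, fg_total). The odds ratio contrasts the foreground
#' rate with the universe rate (Haldane 0.5 correction when any cell is 0),
#' so `foreground == universe` gives p = 1 and odds ratio 1 for every term.
#'
#' @param term_map data.frame (gene_id, term_id, term_name) as from
#'   [read_term_map()]; genes without terms are allowed.
#' @param foreground gene IDs tested for enrichment; must be a subset of
#'   `universe`.
#' @param universe background gene IDs.
#' @param min_count drop terms annotating fewer universe genes than this.
#' @return an `enrichment_table` data.table, sorted by p: term_id,
#'   term_name, fg_with, fg_total, bg_with, bg_total, odds_ratio, p, fdr_q.
#' @export
term_enrichment <- function(term_map, foreground, universe, min_count = 3) {
  tm <- as.data.table(term_map)
  if (!all(c("gene_id", "term_id") %in% names(tm))) {
    stopf("term_map needs gene_id and term_id columns")
  }
  if (!"term_name" %in% names(tm)) tm[, term_name := term_id]
  foreground <- unique(foreground)
  universe <- unique(universe)
  if (!all(foreground %in% universe)) {
    stopf("foreground gene(s) outside the universe: %s",
          setdiff(foreground, universe)[1])
  }
  tm <- unique(tm[gene_id %in% universe, .(gene_id, term_id, term_name)])
  bg_total <- length(universe)
  fg_total <- length(foreground)
  tab <- tm[, .(term_name = term_name[1], bg_with = .N,
                fg_with = sum(gene_id %in% foreground)), by = term_id]
  tab <- tab[bg_with >= min_count]
  if (nrow(tab) == 0) {
    out <- data.table(term_id = character(0), term_name = character(0),
                      fg_with = integer(0), fg_total = integer(0),
                      bg_with = integer(0), bg_total = integer(0),
                      odds_ratio = numeric(0), p = numeric(0), fdr_q = numeric(0))
    setattr(out, "class", c("enrichment_table", class(out)))
    return(out[])
  }
  tab[, `:=`(fg_total = fg_total, bg_total = bg_total)]
  tab[, p := phyper(fg_with - 1, bg_with, bg_total - bg_with, fg_total, lower.tail = FALSE)]
  a <- tab$fg_with; b <- fg_total - tab$fg_with
  cc <- tab$bg_with; dd <- bg_total - tab$bg_with
  corr <- (a == 0 | b == 0 | cc == 0 | dd == 0) * 0.5
  tab[, odds_ratio := ((a + corr) / (b + corr)) / ((cc + corr) / (dd + corr))]
  tab[, fdr_q := bh_fdr(p)]
  setorder(tab, p, term_id)
  out <- tab[, .(term_id, term_name, fg_with, fg_total, bg_with, bg_total,
                 odds_ratio, p, fdr_q)]
  setattr(out, "class", c("enrichment_table", class(out)))
  out[]
}

#' Lift a gene-level term map to orthogroup level
#'
#' An orthogroup carries the union of its member genes' terms, so
#' enrichment can be run with orthogroups as the unit (one observation per
#' family rather than per gene copy).
#'
#' @param term_map data.frame (gene_id, term_id, term_name) keyed by global
#'   gene IDs.
#' @param table an `orthogroup_table`.
#' @return data.table (gene_id = og_id, term_id, term_name).
#' @export
terms_by_orthogroup <- function(term_map, table) {
  stopifnot(inherits(table, "orthogroup_table"))
  tm <- as.data.table(term_map)
  m <- merge(table$members[, .(og_id, global)], tm,
             by.x = "global", by.y = "gene_id")
  unique(m[, .(gene_id = og_id, term_id, term_name)])
}
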