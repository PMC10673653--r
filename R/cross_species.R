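# Cross-species intersection of positionally conserved core sets and
# conservation scoring of the shared ("BC") core in outgroup genomes.

#' Intersect two species' core gene sets
#'
#' Greedy reciprocal-best 1:1 matching over the supplied cross-species
#' links, restricted to `core_a` x `core_b`: links are taken in order of
#' (score descending, then the lexicographically smaller gene pair), each
#' gene used at most once. Links touching genes outside the core sets are
#' ignored. Unmatched core genes are counted species-specific.
#'
#' @param core_a,core_b character vectors of core gene IDs per species.
#' @param links data.frame (gene_a, gene_b\[, score\]) of orthology/synteny
#'   evidence; `score` defaults to 1.
#' @return a `cross_core_result`: list with `pairs` (gene_a, gene_b, score),
#'   `size`, `a_specific`, `b_specific`.
#' @export
intersect_core <- function(core_a, core_b, links) {
  core_a <- unique(core_a); core_b <- unique(core_b)
  l <- as.data.table(links)
  if (!all(c("gene_a", "gene_b") %in% names(l))) {
    stopf("links need gene_a and gene_b columns")
  }
  if (!"score" %in% names(l)) l[, score := 1]
  l <- l[gene_a %chin% core_a & gene_b %chin% core_b]
  # orientation-free tie-break so intersect_core(A, B) == intersect_core(B, A)
  setorder(l, -score)
  l <- l[order(-score, pmin(gene_a, gene_b), pmax(gene_a, gene_b))]
  used_a <- new.env(hash = TRUE, parent = emptyenv())
  used_b <- new.env(hash = TRUE, parent = emptyenv())
  take <- logical(nrow(l))
  ga <- l$gene_a; gb <- l$gene_b
  for (i in seq_len(nrow(l))) {
    if (is.null(used_a[[ga[i]]]) && is.null(used_b[[gb[i]]])) {
      used_a[[ga[i]]] <- TRUE
      used_b[[gb[i]]] <- TRUE
      take[i] <- TRUE
    }
  }
  pairs <- l[take]
  out <- list(
    pairs = pairs[, .(gene_a, gene_b, score)],
    size = nrow(pairs),
    a_specific = length(core_a) - nrow(pairs),
    b_specific = length(core_b) - nrow(pairs)
  )
  class(out) <- "cross_core_result"
  out
}

#' @export
print.cross_core_result <- function(x, ...) {
  cat(sprintf("cross-species core: %d matched pairs; %d A-specific, %d B-specific\n",
              x$size, x$a_specific, x$b_specific))
  invisible(x)
}

#' Conservation of the shared core in an outgroup genome
#'
#' Given per-pair presence of the shared core in an outgroup (e.g. from
#' [project_to_reference()] coverage of the pair's reference genes), counts
#' how many are found and reports the percentage rounded half-up to one
#' decimal.
#'
#' @param cross_core a [intersect_core()] result.
#' @param presence logical vector, one entry per matched pair.
#' @param outgroup_id label for the outgroup genome.
#' @return a `conservation_report` one-row data.table: outgroup_id, found,
#'   total, percent.
#' @export
conservation_in_outgroup <- function(cross_core, presence, outgroup_id = "outgroup") {
  stopifnot(inherits(cross_core, "cross_core_result"))
  if (length(presence) != cross_core$size) {
    stopf("presence vector length (%d) != cross-core size (%d)",
          length(presence), cross_core$size)
  }
  found <- sum(as.logical(presence))
  out <- data.table(outgroup_id = outgroup_id, found = found,
                    total = cross_core$size,
                    percent = round_half_up(100 * found / cross_core$size, 1))
  setattr(out, "class", c("conservation_report", class(out)))
  out[]
}
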