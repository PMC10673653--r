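#' Round half away from zero
#'
#' Deterministic half-up rounding, the rule used when reporting printed
#' percentages (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Globally disambiguated gene identifier
#'
#' Different accessions may reuse local gene IDs, so genes are addressed
#' internally as `"accession|gene_id"`.
#'
#' @param accession accession identifier(s).
#' @param gene_id local gene identifier(s).
#' @return character vector of global IDs.
#' @export
global_gene_id <- function(accession, gene_id) paste(accession, gene_id, sep = "|")

# evaluate expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# gap in bp between two closed intervals; 0 if they overlap or touch
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1 - e2, s2 - e1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
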