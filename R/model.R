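# Pangenome accumulation curves. The average core/pan counts over every
# combination of k accessions reduce to a hypergeometric closed form over
# the occupancy histogram:
#   E[core(k)] = sum_m counts[m] * C(m, k) / C(N, k)
#   E[pan(k)]  = sum_m counts[m] * (1 - C(N - m, k) / C(N, k))
# (with C(a, b) = 0 for a < b), which the test suite proves equal to
# exhaustive subset enumeration.

#' Occupancy histogram of a presence structure
#'
#' Counts, for each m in 1..N, the units present in exactly m accessions.
#' For a `pav_labels` the post-filter units are used.
#'
#' @param x a `pav_labels`, a logical presence matrix (units x accessions),
#'   an `orthogroup_table`, or an integer occupancy vector.
#' @param N accession count (required for an occupancy vector).
#' @param weights optional per-unit weights (same order as units/rows);
#'   defaults to 1 per unit.
#' @return an `occupancy_histogram`: list with `N` and `counts` (length N,
#'   `counts[m]` = weight of units with occupancy m).
#' @export
occupancy_histogram <- function(x, N = NULL, weights = NULL) {
  if (inherits(x, "pav_labels")) {
    occ <- x$units$occupancy
    N <- x$N
  } else if (is.matrix(x)) {
    occ <- as.integer(rowSums(x != 0 & !is.na(x)))
    N <- ncol(x)
  } else if (inherits(x, "orthogroup_table")) {
    occ <- x$og$n_acc
    N <- length(x$accessions)
  } else {
    occ <- as.integer(x)
    if (is.null(N)) stopf("N is required for a raw occupancy vector")
  }
  if (length(occ) && any(occ < 0 | occ > N)) stopf("occupancy outside 0..N")
  if (is.null(weights)) weights <- rep(1, length(occ))
  keep <- occ >= 1L
  counts <- as.vector(rowsum(c(weights[keep], rep(0, N)), c(occ[keep], seq_len(N))))
  out <- list(N = as.integer(N), counts = counts)
  class(out) <- "occupancy_histogram"
  out
}

check_k <- function(h, k) {
  if (any(k < 1 | k > h$N)) stopf("k must lie in 1..N (N = %d)", h$N)
}

#' Expected core count for subsets of size k
#'
#' Exact average, over all C(N, k) accession subsets, of the number of
#' units present in every chosen accession.
#'
#' @param h an [occupancy_histogram()].
#' @param k subset size(s), 1 <= k <= N.
#' @return numeric vector along `k`.
#' @export
expected_core <- function(h, k) {
  check_k(h, k)
  m <- seq_len(h$N)
  vapply(k, function(kk) sum(h$counts * choose(m, kk)) / choose(h$N, kk), 0)
}

#' Expected pangenome size for subsets of size k
#'
#' Exact average number of units present in at least one of the k chosen
#' accessions.
#'
#' @inheritParams expected_core
#' @return numeric vector along `k`.
#' @export
expected_pan <- function(h, k) {
  check_k(h, k)
  m <- seq_len(h$N)
  # single division keeps the numerator an exact (integer-weight) sum
  vapply(k, function(kk) {
    cnk <- choose(h$N, kk)
    (sum(h$counts) * cnk - sum(h$counts * choose(h$N - m, kk))) / cnk
  }, 0)
}

#' Expected auxiliary count for subsets of size k
#'
#' `expected_pan(h, k) - expected_core(h, k)`.
#'
#' @inheritParams expected_core
#' @return numeric vector along `k`.
#' @export
expected_aux <- function(h, k) expected_pan(h, k) - expected_core(h, k)

#' Brute-force accumulation averages by subset enumeration
#'
#' Enumerates every size-k accession subset of a presence matrix and
#' averages core and pan counts; the oracle the closed form is checked
#' against.
#'
#' @param mat logical presence matrix (units x accessions).
#' @param k subset size.
#' @param cap refuse to enumerate more than this many subsets.
#' @return named numeric: `core_avg`, `pan_avg`.
#' @export
enumerate_curve <- function(mat, k, cap = 1e5) {
  N <- ncol(mat)
  if (k < 1 || k > N) stopf("k must lie in 1..N (N = %d)", N)
  if (choose(N, k) > cap) {
    stopf("C(%d, %d) subsets exceed the enumeration cap (%g); use the closed form", N, k, cap)
  }
  mat <- mat != 0
  subsets <- combn(N, k)
  core <- numeric(ncol(subsets)); pan <- numeric(ncol(subsets))
  for (i in seq_len(ncol(subsets))) {
    sub <- mat[, subsets[, i], drop = FALSE]
    rs <- rowSums(sub)
    core[i] <- sum(rs == k)
    pan[i] <- sum(rs > 0)
  }
  c(core_avg = mean(core), pan_avg = mean(pan))
}

#' Model the core/pan accumulation curve
#'
#' Closed-form points for k = 1..N plus the marginal pangenome gain
#' `gain(k) = pan(k) - pan(k-1)` (`gain(1) = pan(1)`). The pangenome is
#' flagged open when `gain(N)` exceeds `closedness_threshold`.
#'
#' @param x a `pav_labels`, presence matrix, `orthogroup_table` or
#'   [occupancy_histogram()].
#' @param unit `"orthogroup"` (each unit weight 1) or `"gene"` (each unit
#'   weighted by its mean member count per carrying accession); `"gene"`
#'   requires a `pav_labels`.
#' @param closedness_threshold open/closed cutoff on `gain(N)` (units).
#' @return a `pangenome_curve` data.table (k, core_avg, pan_avg, aux_avg,
#'   gain_avg) with attributes `method`, `unit`, `open`.
#' @export
model_curve <- function(x, unit = c("orthogroup", "gene"), closedness_threshold = 0) {
  unit <- match.arg(unit)
  if (inherits(x, "occupancy_histogram")) {
    h <- x
    if (unit == "gene") stopf("gene-weighted curves need a pav_labels input")
  } else if (unit == "gene") {
    if (!inherits(x, "pav_labels")) stopf("gene-weighted curves need a pav_labels input")
    w <- x$units$size / x$units$occupancy
    h <- occupancy_histogram(x$units$occupancy, N = x$N, weights = w)
  } else {
    h <- occupancy_histogram(x)
  }
  if (h$N < 2) stopf("need at least 2 accessions")
  k <- seq_len(h$N)
  core <- expected_core(h, k)
  pan <- expected_pan(h, k)
  curve <- data.table(k = k, core_avg = core, pan_avg = pan,
                      aux_avg = pan - core,
                      gain_avg = c(pan[1], diff(pan)))
  setattr(curve, "method", "closed_form")
  setattr(curve, "unit", unit)
  setattr(curve, "open", curve$gain_avg[h$N] > closedness_threshold)
  setattr(curve, "class", c("pangenome_curve", class(curve)))
  curve[]
}
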