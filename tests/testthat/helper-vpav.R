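library(data.table)

# toy occupancy structure: N = 3 accessions, occupancies {3, 2, 1, 2, 1}
toy_hist <- function() occupancy_histogram(c(3L, 2L, 1L, 2L, 1L), N = 3)

toy_matrix <- function() {
  matrix(c(TRUE, TRUE, TRUE,
           TRUE, TRUE, FALSE,
           TRUE, FALSE, FALSE,
           FALSE, TRUE, TRUE,
           FALSE, FALSE, TRUE),
         ncol = 3, byrow = TRUE,
         dimnames = list(paste0("OG", 1:5), c("A", "B", "C")))
}

small_params <- function(...) {
  simulation_params(n_accessions = 5, n_orthogroups = 200, seed = 99, ...)
}

# hand-built one-accession annotation
make_ann <- function(accession, genes, cds) {
  out <- list(accession_id = accession,
              genes = as.data.table(genes),
              cds = as.data.table(cds))
  class(out) <- "genome_annotation"
  out
}

# minimal pav_labels for feature tests
make_labels <- function(accession, gene_id, label, N = 2, W = 5000) {
  gl <- data.table(accession = accession, gene_id = gene_id,
                   global = global_gene_id(accession, gene_id),
                   og_id = paste0("OG", seq_along(gene_id)),
                   unit_id = paste0("OG", seq_along(gene_id)),
                   retained = TRUE, label = label)
  out <- list(units = gl[, .(unit_id, og_id, occupancy = fifelse(label == "core", N, 1L),
                             size = 1L, label)],
              gene_labels = gl, N = N, W = W)
  class(out) <- "pav_labels"
  out
}

# random presence matrix with no all-absent rows
random_presence <- function(G, N, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.2, 0.9)
  m <- matrix(runif(G * N) < p, nrow = G)
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample(N, sum(empty), replace = TRUE))] <- TRUE
  m
}

# brute-force hypergeometric upper tail from binomial coefficients only
hyper_tail_oracle <- function(fg_with, bg_with, bg_total, fg_total) {
  xs <- fg_with:min(bg_with, fg_total)
  sum(choose(bg_with, xs) * choose(bg_total - bg_with, fg_total - xs)) /
    choose(bg_total, fg_total)
}

gene_label_accuracy <- function(labels, truth) {
  tl <- merge(labels$gene_labels[, .(global, label)],
              truth$genes[, .(global, class)], by = "global")
  mean(tl$label == tl$class)
}
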