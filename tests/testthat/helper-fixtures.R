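# Shared fixtures: small parameter sets and hand-built tables.

# Deep, noise-free single-cell regime: every expressed gene is informative
# in every cell and allelic fractions are essentially exact.
deep_params <- function(n_genes = 200L, n_cells = 100L, seed = 1L, ...) {
  sim_params(n_genes = n_genes, n_cells = n_cells, dropout = 0, leak = 0,
             mean_expression = c(log(200), 0.25), seed = seed, ...)
}

# allele_counts built from explicit matrices with one population label.
make_counts <- function(mat, pat, population = "pop", modality = "single_cell",
                        genes = NULL, samples = NULL) {
  mat <- as.matrix(mat); pat <- as.matrix(pat)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(mat)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(mat)))
  meta <- data.frame(sample = samples, population = population,
                     modality = modality, stringsAsFactors = FALSE)
  allele_counts(mat, pat, gene_ids = genes, sample_ids = samples, meta = meta)
}

# gene_classes table from gene -> class pairs.
make_classes <- function(classes, population = "pop") {
  df <- data.frame(gene = names(classes), population = population,
                   class = unname(classes),
                   n_mono_mat = 0L, n_mono_pat = 0L, n_biallelic = 0L,
                   n_expressed = 0L, stringsAsFactors = FALSE)
  class(df) <- c("gene_classes", "data.frame")
  df
}

# Independent textbook BH: sort, step-up minimum, cap, restore order.
bh_textbook <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent exhaustive hypergeometric upper tail: enumerate every
# possible query of size n from a universe of size N and count those
# overlapping the K-set in at least k elements.
hyper_tail_enum <- function(k, K, N, n) {
  hits <- 0L
  total <- 0L
  for (sub in utils::combn(N, n, simplify = FALSE)) {
    total <- total + 1L
    if (sum(sub <= K) >= k) hits <- hits + 1L
  }
  hits / total
}
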