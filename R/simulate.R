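#' Simulation parameters
#'
#' Defines the generative model for allele-resolved counts. Per gene an
#' expected total expression is drawn log-normally; per sample the total
#' is negative-binomial around it; the maternal/paternal split depends on
#' the gene's true class:
#' \itemize{
#'   \item biallelic: maternal share Binomial(total, 0.5);
#'   \item DeMA: the predetermined active allele carries the reads except
#'     a leak fraction `leak` Binomial-misassigned to the silent allele
#'     (SNP-misassignment noise; the "solely expressed from one allele"
#'     regime is the `leak = 0` limit);
#'   \item RaMA: in single cells the active allele is an independent
#'     Bernoulli(0.5) draw per cell (each allele has an equal chance of
#'     being active); in bulk clonal replicates the allele is fixed once
#'     per clone, which is exactly why bulk data cannot separate RaMA
#'     from DeMA;
#'   \item not_expressed: structural zeros.
#' }
#' In single cells each expressed allele is independently zeroed with
#' probability `dropout` before counts are drawn (allelic dropout).
#' Class counts are assigned by largest-remainder quota so realized class
#' sizes match `class_proportions` exactly, which makes recovery tests
#' exact.
#'
#' @param n_genes number of genes to simulate.
#' @param class_proportions named fractions over `biallelic`, `DeMA_mat`,
#'   `DeMA_pat`, `RaMA`, `not_expressed`; must sum to 1. The implied
#'   DeMA_mat:DeMA_pat gene-count ratio is the maternal:paternal
#'   imbalance the data will carry.
#' @param mean_expression `c(log_mean, log_sd)` of the log-normal law for
#'   per-gene expected total counts per sample.
#' @param nb_dispersion negative-binomial dispersion (NB size is its
#'   reciprocal).
#' @param n_replicates bulk clonal replicate count (default 3).
#' @param n_cells cells per simulated single-cell population.
#' @param dropout probability an expressed allele yields zero counts in a
#'   given cell (single-cell only).
#' @param leak expected fraction of a monoallelic gene's reads assigned
#'   to the silent allele.
#' @param nascent_only_frac,mature_only_frac fractions of expressed genes
#'   in the active-only / mature-only transcript states (remainder is
#'   active_and_mature). Defaults jointly reproduce a regime where 88.2%
#'   of genes with mature transcripts lack nascent signal and 79.5% of
#'   actively transcribing genes lack mature transcripts.
#' @param seed integer RNG seed; every gene gets a counter-based
#'   substream derived from it, so adding genes does not perturb earlier
#'   genes' draws.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_genes = 2000L,
                       class_proportions = c(biallelic = 0.72,
                                             DeMA_mat = 0.055,
                                             DeMA_pat = 0.01,
                                             RaMA = 0.015,
                                             not_expressed = 0.20),
                       mean_expression = c(log_mean = log(100), log_sd = 1),
                       nb_dispersion = 0.1,
                       n_replicates = 3L,
                       n_cells = 200L,
                       dropout = 0.3,
                       leak = 0.005,
                       nascent_only_frac = 0.314,
                       mature_only_frac = 0.605,
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            class_proportions = class_proportions,
            mean_expression = unname(mean_expression),
            nb_dispersion = nb_dispersion,
            n_replicates = as.integer(n_replicates),
            n_cells = as.integer(n_cells),
            dropout = dropout, leak = leak,
            nascent_only_frac = nascent_only_frac,
            mature_only_frac = mature_only_frac,
            seed = as.integer(seed))
  classes <- c("biallelic", "DeMA_mat", "DeMA_pat", "RaMA", "not_expressed")
  miss <- setdiff(classes, names(p$class_proportions))
  if (length(miss)) stop("class_proportions missing: ", paste(miss, collapse = ", "))
  p$class_proportions <- p$class_proportions[classes]
  if (any(p$class_proportions < 0) || any(p$class_proportions > 1))
    stop("class proportions must lie in [0, 1]")
  if (abs(sum(p$class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  probs <- c(p$dropout, p$leak, p$nascent_only_frac, p$mature_only_frac)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  if (p$nascent_only_frac + p$mature_only_frac > 1)
    stop("nascent_only_frac + mature_only_frac must not exceed 1")
  if (p$dropout >= 1) stop("dropout must be < 1")
  if (p$n_genes < 1L) stop("n_genes must be >= 1")
  if (p$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (p$mean_expression[2L] < 0) stop("log_sd must be >= 0")
  n_dema <- quota_counts(p$n_genes, p$class_proportions)[c("DeMA_mat", "DeMA_pat")]
  p$imbalance_ratio <- if (n_dema[2L] > 0) unname(n_dema[1L] / n_dema[2L]) else NA_real_
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("sim_params: %d genes, %d cells, %d bulk replicates, seed %d\n",
              x$n_genes, x$n_cells, x$n_replicates, x$seed))
  cat("class quota:", paste(sprintf("%s=%d", names(x$class_proportions),
                                    quota_counts(x$n_genes, x$class_proportions)),
                            collapse = " "), "\n")
  cat(sprintf("dropout=%.3g leak=%.3g dispersion=%.3g mat:pat ratio=%.3g\n",
              x$dropout, x$leak, x$nb_dispersion, x$imbalance_ratio))
  invisible(x)
}

# Largest-remainder quota: integer counts summing to n, proportional to p;
# ties broken by position.
quota_counts <- function(n, p) {
  exact <- n * p / sum(p)
  base <- floor(exact)
  rem <- exact - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

# Counter-based per-gene substream: deterministic in (seed, stream, i),
# independent of how many genes are simulated.
gene_seed <- function(seed, stream, i) {
  s0 <- (abs(as.numeric(seed)) %% 2147483647) + 1
  as.integer((s0 + stream * 1000003 + i * 48271) %% 2147483647)
}

sim_gene_classes <- function(params) {
  counts <- quota_counts(params$n_genes, params$class_proportions)
  rep(names(counts), counts)
}

# Zero-truncated NB via inverse CDF: used where a channel must be detected.
rztnb <- function(n, mu, size) {
  p0 <- stats::dnbinom(0, mu = mu, size = size)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(u, mu = mu, size = size)
}

#' Simulate allele-resolved bulk RNA-seq replicates
#'
#' Emulates a three-clonal-replicate bulk design: per gene and replicate a
#' negative-binomial total, split between alleles by the gene's true
#' class (see [sim_params()]). RaMA genes have their active allele fixed
#' once per clonal replicate (clonal expansion), so in bulk they are
#' indistinguishable from DeMA whenever all clones happened to pick the
#' same allele.
#'
#' @param params a [sim_params()] object.
#' @param population population label for the replicates.
#' @return list with `counts` (an [allele_counts] with
#'   `n_replicates` samples) and `truth` (a `sim_truth` object).
#' @export
simulate_bulk <- function(params, population = "bulk") {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_replicates < 1L) stop("n_replicates must be >= 1")
  G <- params$n_genes
  R <- params$n_replicates
  classes <- sim_gene_classes(params)
  genes <- sprintf("gene_%05d", seq_len(G))
  size <- 1 / params$nb_dispersion
  lm <- params$mean_expression[1L]; ls <- params$mean_expression[2L]
  mat <- matrix(0L, G, R); pat <- matrix(0L, G, R)
  active <- rep(NA_character_, G)
  rama_bulk <- vector("list", G)
  for (i in seq_len(G)) {
    cl <- classes[i]
    if (cl == "not_expressed") next
    set.seed(gene_seed(params$seed, 1L, i))
    mu <- stats::rlnorm(1L, meanlog = lm, sdlog = ls)
    total <- stats::rnbinom(R, mu = mu, size = size)
    if (cl == "biallelic") {
      m <- stats::rbinom(R, total, 0.5)
      mat[i, ] <- m; pat[i, ] <- total - m
    } else {
      if (cl == "RaMA") {
        act <- ifelse(stats::runif(R) < 0.5, "mat", "pat")
        rama_bulk[[i]] <- act
      } else {
        act <- rep(if (cl == "DeMA_mat") "mat" else "pat", R)
        active[i] <- act[1L]
      }
      silent <- stats::rbinom(R, total, params$leak)
      on_active <- total - silent
      mat[i, ] <- ifelse(act == "mat", on_active, silent)
      pat[i, ] <- ifelse(act == "mat", silent, on_active)
    }
  }
  samples <- sprintf("%s_rep%d", population, seq_len(R))
  meta <- data.frame(sample = samples, population = population,
                     modality = "bulk", stringsAsFactors = FALSE)
  counts <- allele_counts(mat, pat, gene_ids = genes, sample_ids = samples,
                          meta = meta)
  truth <- new_sim_truth(genes, classes, active, params,
                         rama_assign = rama_bulk, sample_ids = samples)
  list(counts = counts, truth = truth)
}

#' Simulate allele-resolved single cells
#'
#' Per cell and gene: RaMA genes draw their active allele independently
#' per cell (Bernoulli(0.5)); DeMA genes keep one fixed allele; biallelic
#' genes express both. Each expressed allele is independently zeroed with
#' probability `dropout` before its negative-binomial count is drawn —
#' the technical confound that makes biallelic genes look monoallelic in
#' single cells.
#'
#' @param params a [sim_params()] object.
#' @param population population (cell-type) label.
#' @return list with `counts` ([allele_counts] with `n_cells` samples)
#'   and `truth` (`sim_truth`, including per-cell RaMA allele choices).
#' @export
simulate_cells <- function(params, population = "cells") {
  stopifnot(inherits(params, "sim_params"))
  if (params$dropout >= 1) stop("dropout must be < 1")
  if (params$n_cells < 1L) stop("n_cells must be >= 1")
  G <- params$n_genes
  C <- params$n_cells
  classes <- sim_gene_classes(params)
  genes <- sprintf("gene_%05d", seq_len(G))
  size <- 1 / params$nb_dispersion
  lm <- params$mean_expression[1L]; ls <- params$mean_expression[2L]
  d <- params$dropout; eps <- params$leak
  mat <- matrix(0L, G, C); pat <- matrix(0L, G, C)
  active <- rep(NA_character_, G)
  rama_cells <- vector("list", G)
  for (i in seq_len(G)) {
    cl <- classes[i]
    if (cl == "not_expressed") next
    set.seed(gene_seed(params$seed, 2L, i))
    mu <- stats::rlnorm(1L, meanlog = lm, sdlog = ls)
    if (cl == "biallelic") {
      keep_m <- stats::runif(C) >= d
      keep_p <- stats::runif(C) >= d
      m <- stats::rnbinom(C, mu = mu / 2, size = size) * keep_m
      p <- stats::rnbinom(C, mu = mu / 2, size = size) * keep_p
      mat[i, ] <- m; pat[i, ] <- p
    } else {
      if (cl == "RaMA") {
        act <- ifelse(stats::runif(C) < 0.5, "mat", "pat")
        rama_cells[[i]] <- act
      } else {
        act <- rep(if (cl == "DeMA_mat") "mat" else "pat", C)
        active[i] <- act[1L]
      }
      keep <- stats::runif(C) >= d
      total <- stats::rnbinom(C, mu = mu, size = size) * keep
      silent <- stats::rbinom(C, total, eps)
      on_active <- total - silent
      mat[i, ] <- ifelse(act == "mat", on_active, silent)
      pat[i, ] <- ifelse(act == "mat", silent, on_active)
    }
  }
  cells <- sprintf("%s_cell%03d", population, seq_len(C))
  meta <- data.frame(sample = cells, population = population,
                     modality = "single_cell", stringsAsFactors = FALSE)
  counts <- allele_counts(mat, pat, gene_ids = genes, sample_ids = cells,
                          meta = meta)
  truth <- new_sim_truth(genes, classes, active, params,
                         rama_assign = rama_cells, sample_ids = cells)
  list(counts = counts, truth = truth)
}

new_sim_truth <- function(genes, classes, active, params,
                          rama_assign = NULL, sample_ids = NULL) {
  names(rama_assign) <- genes
  rama_assign <- rama_assign[classes == "RaMA"]
  tbl <- data.frame(gene = genes, class = classes,
                    active_allele = active, stringsAsFactors = FALSE)
  structure(list(table = tbl, rama_assignment = rama_assign,
                 sample_ids = sample_ids, params = params),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$table), "genes\n")
  print(table(x$table$class))
  invisible(x)
}

#' Ground truth as a gene-class table
#'
#' Converts a simulator truth object into the `gene_classes` shape so it
#' can be compared with, or used in place of, classifier output
#' (truth-faithful classification). Evidence counts are not defined by
#' truth and are set to `NA`.
#'
#' @param truth a `sim_truth` object.
#' @param population population label for the rows.
#' @return A `gene_classes` data.frame.
#' @export
truth_classes <- function(truth, population = "truth") {
  stopifnot(inherits(truth, "sim_truth"))
  df <- data.frame(gene = truth$table$gene, population = population,
                   class = truth$table$class,
                   n_mono_mat = NA_integer_, n_mono_pat = NA_integer_,
                   n_biallelic = NA_integer_, n_expressed = NA_integer_,
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_classes", "data.frame")
  df
}

#' Simulate nascent/mature transcript states
#'
#' Expressed genes are assigned to active_only / mature_only /
#' active_and_mature by largest-remainder quota on
#' (`nascent_only_frac`, `mature_only_frac`, remainder); genes whose true
#' class is not_expressed are silent. Present channels are drawn from a
#' zero-truncated negative binomial so a gene's realized state equals the
#' assigned one at detection threshold 1; absent channels are exact zeros.
#'
#' @param params a [sim_params()] object.
#' @param truth `sim_truth` from [simulate_bulk()] or [simulate_cells()];
#'   the returned copy carries the per-gene transcript state.
#' @return list with `states` (a `transcript_states` data.frame: gene,
#'   nascent_count, mature_count, state) and the updated `truth`.
#' @export
simulate_transcript_states <- function(params, truth) {
  stopifnot(inherits(params, "sim_params"), inherits(truth, "sim_truth"))
  if (params$nascent_only_frac + params$mature_only_frac > 1)
    stop("nascent_only_frac + mature_only_frac must not exceed 1")
  tbl <- truth$table
  G <- nrow(tbl)
  expressed <- which(tbl$class != "not_expressed")
  state <- rep("silent", G)
  fr <- c(active_only = params$nascent_only_frac,
          mature_only = params$mature_only_frac,
          active_and_mature = 1 - params$nascent_only_frac -
            params$mature_only_frac)
  q <- quota_counts(length(expressed), fr)
  state[expressed] <- rep(names(q), q)
  size <- 1 / params$nb_dispersion
  lm <- params$mean_expression[1L]; ls <- params$mean_expression[2L]
  nasc <- integer(G); matc <- integer(G)
  for (i in seq_len(G)) {
    if (state[i] == "silent") next
    set.seed(gene_seed(params$seed, 3L, i))
    mu <- stats::rlnorm(1L, meanlog = lm, sdlog = ls)
    if (state[i] != "mature_only") nasc[i] <- rztnb(1L, mu, size)
    if (state[i] != "active_only") matc[i] <- rztnb(1L, mu, size)
  }
  states <- data.frame(gene = tbl$gene, nascent_count = nasc,
                       mature_count = matc, state = state,
                       stringsAsFactors = FALSE)
  class(states) <- c("transcript_states", "data.frame")
  truth$table$transcript_state <- state
  list(states = states, truth = truth)
}
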