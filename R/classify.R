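#' Classification thresholds
#'
#' Decision parameters of the allele-specific filtering algorithm.
#' A (gene, sample) pair is informative when its total allele-assigned
#' count reaches `min_total`; an informative pair is monoallelic when the
#' allelic fraction f = mat/(mat+pat) satisfies f >= `mono_fraction`
#' (maternal) or f <= 1 - `mono_fraction` (paternal), biallelic otherwise.
#' Ties at exactly `mono_fraction` resolve to the monoallelic call.
#' Population-level calls additionally require `min_cells` informative
#' samples, at least `rama_min_cells` cells on EACH allele for RaMA, at
#' most a `max_biallelic_frac` share of biallelic cells for any
#' monoallelic verdict, and an informative-sample fraction of at least
#' `min_expressed_frac` for a gene to count as expressed.
#'
#' Defaults (`min_total` 5 counts, `mono_fraction` 0.98, `min_cells` 5,
#' `rama_min_cells` 3, `max_biallelic_frac` 0.10, `min_expressed_frac`
#' 0.05) are chosen so that in noise-free data a monoallelic gene is one
#' expressed solely from a single parental background.
#'
#' @param min_total minimum mat+pat counts for an informative sample.
#' @param mono_fraction allelic-fraction cutoff in (0.5, 1].
#' @param min_cells minimum informative samples for a population call.
#' @param rama_min_cells minimum cells required on each allele for RaMA.
#' @param max_biallelic_frac maximum biallelic share of informative cells
#'   compatible with a monoallelic or RaMA verdict, in [0, 1).
#' @param min_expressed_frac minimum informative fraction of samples for
#'   a gene to be expressed in a population.
#' @return A `call_thresholds` list.
#' @export
call_thresholds <- function(min_total = 5L, mono_fraction = 0.98,
                            min_cells = 5L, rama_min_cells = 3L,
                            max_biallelic_frac = 0.10,
                            min_expressed_frac = 0.05) {
  th <- list(min_total = as.integer(min_total),
             mono_fraction = mono_fraction,
             min_cells = as.integer(min_cells),
             rama_min_cells = as.integer(rama_min_cells),
             max_biallelic_frac = max_biallelic_frac,
             min_expressed_frac = min_expressed_frac)
  if (th$mono_fraction <= 0.5 || th$mono_fraction > 1)
    stop("mono_fraction must lie in (0.5, 1]")
  if (th$min_total < 1L) stop("min_total must be >= 1")
  if (th$rama_min_cells < 1L) stop("rama_min_cells must be >= 1")
  if (th$max_biallelic_frac < 0 || th$max_biallelic_frac >= 1)
    stop("max_biallelic_frac must lie in [0, 1)")
  if (th$min_expressed_frac < 0 || th$min_expressed_frac > 1)
    stop("min_expressed_frac must lie in [0, 1]")
  class(th) <- "call_thresholds"
  th
}

#' @export
print.call_thresholds <- function(x, ...) {
  cat(sprintf(paste0("call_thresholds: min_total=%d mono_fraction=%.3g ",
                     "min_cells=%d rama_min_cells=%d max_biallelic_frac=%.3g ",
                     "min_expressed_frac=%.3g\n"),
              x$min_total, x$mono_fraction, x$min_cells, x$rama_min_cells,
              x$max_biallelic_frac, x$min_expressed_frac))
  invisible(x)
}

# Vectorized per-(gene, sample) state codes:
# "not_expressed", "mono_mat", "mono_pat", "biallelic".
allele_state <- function(mat, pat, th) {
  total <- mat + pat
  f <- ifelse(total > 0, mat / total, NA_real_)
  state <- rep("biallelic", length(total))
  state[total < th$min_total] <- "not_expressed"
  inf <- total >= th$min_total
  state[inf & f >= th$mono_fraction] <- "mono_mat"
  state[inf & f <= 1 - th$mono_fraction] <- "mono_pat"
  list(state = state, f = f)
}

#' Call the expression state of one allele-count pair
#'
#' The atomic per-sample call under the filtering algorithm: computes the
#' allelic fraction f = mat/(mat+pat) and classifies the pair as
#' `not_expressed` (total below `min_total`), `mono_mat`
#' (f >= `mono_fraction`), `mono_pat` (f <= 1 - `mono_fraction`) or
#' `biallelic`.
#'
#' @param mat,pat non-negative maternal/paternal counts (vectorized).
#' @param thresholds a [call_thresholds()] object.
#' @return data.frame with columns `mat`, `pat`, `f` (NA when total is 0)
#'   and `state`.
#' @export
call_allele <- function(mat, pat, thresholds = call_thresholds()) {
  if (any(mat < 0) || any(pat < 0)) stop("counts must be non-negative")
  s <- allele_state(mat, pat, thresholds)
  data.frame(mat = mat, pat = pat, f = s$f, state = s$state,
             stringsAsFactors = FALSE)
}

state_counts <- function(counts, samples, th) {
  mat <- counts$mat[, samples, drop = FALSE]
  pat <- counts$pat[, samples, drop = FALSE]
  total <- mat + pat
  informative <- total >= th$min_total
  f <- mat / total
  mono_mat <- informative & f >= th$mono_fraction
  mono_pat <- informative & f <= 1 - th$mono_fraction
  biallelic <- informative & !mono_mat & !mono_pat
  list(n_inf = rowSums(informative),
       n_mm = rowSums(mono_mat),
       n_mp = rowSums(mono_pat),
       n_bi = rowSums(biallelic),
       n_samples = ncol(mat))
}

new_gene_classes <- function(genes, population, class, sc) {
  df <- data.frame(gene = genes, population = population, class = class,
                   n_mono_mat = as.integer(sc$n_mm),
                   n_mono_pat = as.integer(sc$n_mp),
                   n_biallelic = as.integer(sc$n_bi),
                   n_expressed = as.integer(sc$n_inf),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_classes", "data.frame")
  df
}

#' Classify genes from bulk clonal replicates
#'
#' The deterministic-monoallelic (DeMA) filter: a gene is DeMA only when
#' it is expressed exclusively from one parental background in every
#' clonal replicate. A gene is expressed when informative in all
#' replicates; unanimous maternal (paternal) monoallelic calls give
#' `DeMA_mat` (`DeMA_pat`); unanimous biallelic calls give `biallelic`.
#' Replicate patterns violating unanimity — mixed monoallelic directions,
#' mono/biallelic mixtures, or expression in only some replicates — are
#' `inconclusive` under `mode = "strict"` (default); `mode = "lenient"`
#' instead calls any expressed non-DeMA gene `biallelic`. Bulk data never
#' yields `RaMA`: clonal expansion fixes the active allele within a
#' clone, so a random-monoallelic gene is indistinguishable from a
#' deterministic one in bulk.
#'
#' @param counts an [allele_counts] object whose samples are bulk
#'   replicates of one population (>= 2 replicates).
#' @param thresholds a [call_thresholds()] object.
#' @param mode `"strict"` or `"lenient"` handling of unanimity violations.
#' @param population population to classify (default: the single label
#'   present).
#' @return A `gene_classes` data.frame.
#' @export
classify_bulk <- function(counts, thresholds = call_thresholds(),
                          mode = c("strict", "lenient"),
                          population = NULL) {
  stopifnot(inherits(counts, "allele_counts"))
  mode <- match.arg(mode)
  th <- thresholds
  if (is.null(population)) {
    population <- unique(counts$meta$population)
    if (length(population) != 1L)
      stop("multiple populations present; pass `population`")
  }
  samples <- counts$meta$sample[counts$meta$population == population]
  if (length(samples) < 2L)
    stop("bulk classification requires >= 2 replicates")
  sc <- state_counts(counts, samples, th)
  R <- sc$n_samples
  cls <- rep("inconclusive", length(counts$gene_ids))
  cls[sc$n_inf == 0] <- "not_expressed"
  expressed <- sc$n_inf == R
  cls[expressed & sc$n_mm == R] <- "DeMA_mat"
  cls[expressed & sc$n_mp == R] <- "DeMA_pat"
  if (mode == "strict") {
    cls[expressed & sc$n_bi == R] <- "biallelic"
  } else {
    cls[expressed & sc$n_mm < R & sc$n_mp < R] <- "biallelic"
  }
  new_gene_classes(counts$gene_ids, population, cls, sc)
}

#' Classify genes from single cells of one population
#'
#' The RaMA-capable filter. Using informative cells only, a gene is:
#' `not_expressed` when informative in fewer than `min_cells` cells or
#' less than `min_expressed_frac` of cells; `DeMA_mat` when at least
#' `min_cells` cells are maternal-monoallelic, no cell is
#' paternal-monoallelic and the biallelic share is at most
#' `max_biallelic_frac` (`DeMA_pat` symmetric); `RaMA` when at least
#' `rama_min_cells` cells are monoallelic for EACH parental allele and
#' the biallelic share is at most `max_biallelic_frac` — different cells
#' of the same type expressing different parental alleles; `biallelic`
#' when the biallelic share exceeds `max_biallelic_frac`; otherwise
#' `inconclusive`.
#'
#' @param counts an [allele_counts] object of single cells.
#' @param thresholds a [call_thresholds()] object.
#' @param population population(s) to classify; default all present.
#' @return A `gene_classes` data.frame (one block of rows per population).
#' @export
classify_population <- function(counts, thresholds = call_thresholds(),
                                population = NULL) {
  stopifnot(inherits(counts, "allele_counts"))
  th <- thresholds
  if (is.null(population)) population <- unique(counts$meta$population)
  out <- vector("list", length(population))
  for (pidx in seq_along(population)) {
    pop <- population[pidx]
    samples <- counts$meta$sample[counts$meta$population == pop]
    if (!length(samples)) stop("empty population: ", pop)
    sc <- state_counts(counts, samples, th)
    n_inf <- sc$n_inf
    bia_frac <- ifelse(n_inf > 0, sc$n_bi / n_inf, 0)
    cls <- rep("inconclusive", length(counts$gene_ids))
    low <- n_inf < th$min_cells | n_inf / sc$n_samples < th$min_expressed_frac
    ok_bia <- bia_frac <= th$max_biallelic_frac
    dema_mat <- sc$n_mm >= th$min_cells & sc$n_mp == 0 & ok_bia
    dema_pat <- sc$n_mp >= th$min_cells & sc$n_mm == 0 & ok_bia
    rama <- sc$n_mm >= th$rama_min_cells & sc$n_mp >= th$rama_min_cells & ok_bia
    cls[bia_frac > th$max_biallelic_frac] <- "biallelic"
    cls[rama] <- "RaMA"
    cls[dema_mat] <- "DeMA_mat"
    cls[dema_pat] <- "DeMA_pat"
    cls[low] <- "not_expressed"
    out[[pidx]] <- new_gene_classes(counts$gene_ids, pop, cls, sc)
  }
  res <- do.call(rbind, out)
  class(res) <- c("gene_classes", "data.frame")
  res
}

#' Per-allele counts-per-million normalization
#'
#' Plain CPM on the combined per-sample library (maternal + paternal
#' totals): `cpm(g, s, allele) = count / library(s) * 1e6`, so the
#' maternal and paternal CPM matrices of a sample sum to 1e6 over genes.
#' Used for reporting only; expression gating is done on raw counts.
#'
#' @param counts an [allele_counts] object with no zero-total sample.
#' @return list with matrices `mat` and `pat`.
#' @export
cpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "allele_counts"))
  lib <- colSums(counts$mat) + colSums(counts$pat)
  if (any(lib == 0))
    stop("zero-total sample(s): ",
         paste(counts$sample_ids[lib == 0], collapse = ", "))
  list(mat = sweep(counts$mat, 2L, lib, "/") * 1e6,
       pat = sweep(counts$pat, 2L, lib, "/") * 1e6)
}
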