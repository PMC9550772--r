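#' One-sided Fisher exact (hypergeometric) gene-set enrichment
#'
#' For each term the overlap k between the query and the term's members
#' (both restricted to the universe) is tested against the upper-tail
#' hypergeometric law: p = P(X >= k | N, K, n) with N the universe size,
#' K the term size and n the query size — the Fisher exact test under
#' independence of set membership. P-values are Benjamini-Hochberg
#' adjusted across all tested terms; results are sorted by p, then term.
#'
#' @param query character vector of query gene ids (subset of the
#'   universe).
#' @param sets a [gene_sets] collection.
#' @param universe background gene ids; defaults (with a warning) to the
#'   union of all term sets.
#' @return An `enrich_result` data.frame: `term`, `k`, `K`, `n`, `N`,
#'   `p`, `adj_p`, and placeholder `z`/`combined` columns filled by
#'   [combined_score()]. Carries the restricted sets and universe as
#'   attributes for the background-rank step.
#' @export
fisher_enrich <- function(query, sets, universe = NULL) {
  stopifnot(inherits(sets, "gene_sets"))
  if (is.null(universe)) universe <- sets$universe
  if (is.null(universe)) {
    warning("no universe supplied; using the union of all term sets")
    universe <- unique(unlist(sets$sets))
  }
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ", outside[1L])
  restricted <- lapply(sets$sets, intersect, universe)
  empty <- lengths(restricted) == 0L
  if (any(empty)) {
    message(sum(empty), " term(s) empty after universe restriction skipped: ",
            paste(names(restricted)[empty], collapse = ", "))
    restricted <- restricted[!empty]
  }
  if (!length(restricted)) stop("no testable terms")
  N <- length(universe)
  n <- length(query)
  K <- lengths(restricted)
  k <- vapply(restricted, function(s) length(intersect(s, query)), 1L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term = names(restricted), k = as.integer(k),
                    K = as.integer(K), n = n, N = N, p = p,
                    adj_p = bh_adjust(p), z = NA_real_,
                    combined = NA_real_, stringsAsFactors = FALSE)
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  attr(res, "universe") <- universe
  attr(res, "sets") <- restricted
  class(res) <- c("enrich_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: adj_(i) is the minimum over
#' ranks j >= i of p_(j) * m / j, capped at 1, returned in the input
#' order. Input p-values must lie in (0, 1].
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Rank-deviation combined enrichment score
#'
#' Enrichr-style combined score: for each term, the rank its p-value
#' attains in the observed analysis is compared with the ranks the same
#' term attains across `n_background_draws` random queries of the
#' observed query's size drawn uniformly from the universe. With mu and
#' sigma the mean and standard deviation of the background ranks,
#' z = (mu - observed_rank) / sigma (positive when the term ranks better
#' than expected) and combined = -ln(p) * z, so stronger enrichment gives
#' larger positive scores. Terms whose background rank never varies get
#' z = 0.
#'
#' @param results an `enrich_result` from [fisher_enrich()].
#' @param n_background_draws number of random background queries (>= 2;
#'   default 1000).
#' @param seed RNG seed for the background draws.
#' @return `results` with `z` and `combined` filled; ordering unchanged.
#' @export
combined_score <- function(results, n_background_draws = 1000L, seed = 1L) {
  stopifnot(inherits(results, "enrich_result"))
  if (n_background_draws < 2L) stop("n_background_draws must be >= 2")
  universe <- attr(results, "universe")
  sets <- attr(results, "sets")
  if (is.null(universe) || is.null(sets))
    stop("results must carry the universe/sets attributes from fisher_enrich()")
  sets <- sets[results$term]
  N <- length(universe)
  n <- results$n[1L]
  K <- results$K
  B <- as.integer(n_background_draws)
  member <- vapply(sets, function(s) universe %in% s, logical(N))
  # terms x universe
  member <- t(member)
  set.seed(seed)
  rank_sum <- numeric(nrow(results))
  rank_sq <- numeric(nrow(results))
  for (b in seq_len(B)) {
    idx <- sample.int(N, n)
    kb <- as.integer(rowSums(member[, idx, drop = FALSE]))
    pb <- stats::phyper(kb - 1L, K, N - K, n, lower.tail = FALSE)
    rb <- rank(pb, ties.method = "average")
    rank_sum <- rank_sum + rb
    rank_sq <- rank_sq + rb^2
  }
  mu <- rank_sum / B
  sigma <- sqrt(pmax(0, (rank_sq - B * mu^2) / (B - 1)))
  obs_rank <- rank(results$p, ties.method = "average")
  z <- ifelse(sigma > 1e-12, (mu - obs_rank) / sigma, 0)
  results$z <- z
  results$combined <- -log(results$p) * z
  results
}

#' @export
print.enrich_result <- function(x, ...) {
  cat(sprintf("enrich_result: %d terms, query n=%d, universe N=%d\n",
              nrow(x), x$n[1L], x$N[1L]))
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more terms\n")
  invisible(x)
}

#' Write an enrichment table to TSV
#' @param results an `enrich_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrich_result <- function(results, path) {
  stopifnot(inherits(results, "enrich_result"))
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
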