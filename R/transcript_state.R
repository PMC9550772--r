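#' Classify a gene's nascent/mature transcript state
#'
#' Count-level census of active transcription versus mature-transcript
#' presence: a gene with nascent (intron-assigned or metabolically
#' labeled proxy) signal at or above `min_detect` but mature (spliced)
#' signal below it is `active_only`; the converse is `mature_only`; both
#' detected gives `active_and_mature`; neither gives `silent`.
#'
#' @param nascent,mature non-negative counts (vectorized).
#' @param min_detect detection threshold (>= 1; default 1 =
#'   presence/absence).
#' @return character vector of states.
#' @export
classify_transcript_state <- function(nascent, mature, min_detect = 1L) {
  if (min_detect < 1) stop("min_detect must be >= 1")
  if (any(nascent < 0) || any(mature < 0)) stop("counts must be non-negative")
  has_n <- nascent >= min_detect
  has_m <- mature >= min_detect
  out <- rep("silent", length(has_n))
  out[has_n & !has_m] <- "active_only"
  out[!has_n & has_m] <- "mature_only"
  out[has_n & has_m] <- "active_and_mature"
  out
}

#' Build a transcript-state table from counts
#'
#' @param gene gene identifiers.
#' @param nascent,mature counts per gene.
#' @param min_detect detection threshold passed to
#'   [classify_transcript_state()].
#' @return A `transcript_states` data.frame.
#' @export
transcript_states <- function(gene, nascent, mature, min_detect = 1L) {
  if (anyDuplicated(gene)) stop("duplicate gene ids")
  df <- data.frame(gene = as.character(gene),
                   nascent_count = as.integer(nascent),
                   mature_count = as.integer(mature),
                   state = classify_transcript_state(nascent, mature,
                                                     min_detect),
                   stringsAsFactors = FALSE)
  class(df) <- c("transcript_states", "data.frame")
  df
}

#' @export
print.transcript_states <- function(x, ...) {
  cat("transcript_states:", nrow(x), "genes\n")
  print(table(x$state))
  invisible(x)
}

#' Census of transcript states over a gene subset
#'
#' Two deliberately different denominators mirror the two census
#' questions: the mature-only fraction is taken over all genes with
#' detected mature transcripts ("of the total RNAs" — mature-bearing
#' genes lacking nascent signal), while the active-only fraction is taken
#' over all genes with detected nascent signal ("of the total active
#' RNAs" — actively transcribing genes lacking mature transcripts). Each
#' fraction comes with an exact (Clopper-Pearson) binomial 95% CI.
#'
#' @param states a `transcript_states` data.frame (state already derived
#'   at the chosen detection threshold).
#' @param gene_subset optional gene ids to restrict to (e.g. the mat-mono
#'   cohort).
#' @return A `state_census` list: per-state counts, the two denominators,
#'   fractions with CIs, and the fraction of each state among non-silent
#'   genes.
#' @export
state_census <- function(states, gene_subset = NULL) {
  stopifnot(inherits(states, "transcript_states"))
  if (!is.null(gene_subset)) states <- states[states$gene %in% gene_subset, ]
  st <- states$state
  n_active_only <- sum(st == "active_only")
  n_mature_only <- sum(st == "mature_only")
  n_both <- sum(st == "active_and_mature")
  n_nonsilent <- n_active_only + n_mature_only + n_both
  if (n_nonsilent == 0L) stop("no non-silent genes in the subset")
  mature_denom <- n_mature_only + n_both
  active_denom <- n_active_only + n_both
  if (mature_denom == 0L) stop("empty mature denominator")
  if (active_denom == 0L) stop("empty active denominator")
  ci <- function(k, n) as.numeric(stats::binom.test(k, n)$conf.int)
  out <- list(
    counts = c(active_only = n_active_only, mature_only = n_mature_only,
               active_and_mature = n_both, silent = sum(st == "silent")),
    mature_denom = mature_denom,
    active_denom = active_denom,
    mature_only_frac = n_mature_only / mature_denom,
    mature_only_ci = ci(n_mature_only, mature_denom),
    active_only_frac = n_active_only / active_denom,
    active_only_ci = ci(n_active_only, active_denom),
    frac_of_nonsilent = c(active_only = n_active_only,
                          mature_only = n_mature_only,
                          active_and_mature = n_both) / n_nonsilent)
  class(out) <- "state_census"
  out
}

#' @export
print.state_census <- function(x, ...) {
  cat(sprintf("state_census: %d non-silent genes (%d silent)\n",
              sum(x$counts[1:3]), x$counts[["silent"]]))
  cat(sprintf("mature-only: %.1f%% of %d mature-bearing genes (95%% CI %.1f-%.1f%%)\n",
              100 * x$mature_only_frac, x$mature_denom,
              100 * x$mature_only_ci[1], 100 * x$mature_only_ci[2]))
  cat(sprintf("active-only: %.1f%% of %d actively transcribing genes (95%% CI %.1f-%.1f%%)\n",
              100 * x$active_only_frac, x$active_denom,
              100 * x$active_only_ci[1], 100 * x$active_only_ci[2]))
  invisible(x)
}
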