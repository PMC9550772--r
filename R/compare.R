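#' Maternal:paternal imbalance of deterministic monoallelic genes
#'
#' The gene-level census statistic: the number of maternal-exclusive
#' (DeMA_mat) genes divided by the number of paternal-exclusive
#' (DeMA_pat) genes in one population, with a bootstrap 95% percentile
#' interval obtained by resampling the classified gene list (genes, not
#' cells — the ratio is a gene-census quantity).
#'
#' @param classes a `gene_classes` table.
#' @param population population to measure.
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return An `imbalance_stat` list: `n_mat`, `n_pat`, `ratio` (NA when
#'   `n_pat` is 0 — reported with counts, not an error), `ci`, `n_genes`.
#' @export
imbalance_ratio <- function(classes, population = NULL, n_boot = 2000L,
                            seed = 1L, conf = 0.95) {
  classes <- validate_gene_classes(classes)
  if (is.null(population)) {
    population <- unique(classes$population)
    if (length(population) != 1L)
      stop("multiple populations present; pass `population`")
  }
  cls <- classes$class[classes$population == population]
  if (!length(cls)) stop("population not present: ", population)
  n_mat <- sum(cls == "DeMA_mat")
  n_pat <- sum(cls == "DeMA_pat")
  G <- length(cls)
  if (n_pat == 0L) {
    out <- list(population = population, n_mat = n_mat, n_pat = 0L,
                ratio = NA_real_, ci = c(NA_real_, NA_real_),
                n_genes = G, n_boot = as.integer(n_boot))
    class(out) <- "imbalance_stat"
    return(out)
  }
  ratio <- n_mat / n_pat
  # Bootstrap: resampling G genes with replacement makes the category
  # counts multinomial; draw them directly.
  set.seed(seed)
  probs <- c(n_mat, n_pat, G - n_mat - n_pat) / G
  draws <- stats::rmultinom(n_boot, G, probs)
  ratios <- draws[1L, ] / draws[2L, ]
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(ratios, c(alpha, 1 - alpha), names = FALSE,
                               type = 7))
  out <- list(population = population, n_mat = n_mat, n_pat = n_pat,
              ratio = ratio, ci = ci, n_genes = G,
              n_boot = as.integer(n_boot))
  class(out) <- "imbalance_stat"
  out
}

#' @export
print.imbalance_stat <- function(x, ...) {
  if (is.na(x$ratio)) {
    cat(sprintf("imbalance_stat [%s]: %d mat-mono, 0 pat-mono; ratio undefined\n",
                x$population, x$n_mat))
  } else {
    cat(sprintf("imbalance_stat [%s]: %d mat-mono / %d pat-mono = %.2f-fold (95%% CI %.2f-%.2f)\n",
                x$population, x$n_mat, x$n_pat, x$ratio, x$ci[1], x$ci[2]))
  }
  invisible(x)
}

#' Expression-status changes between two populations
#'
#' Buckets every gene classified as monoallelic (DeMA_mat/DeMA_pat) or
#' biallelic in BOTH tables into exactly one transition:
#' `mono_to_biallelic`, `biallelic_to_mono`, `mono_same_allele`,
#' `mono_switched_allele` (the allele-switch outliers, enumerated
#' explicitly) or `biallelic_stable`. Genes that are RaMA, inconclusive
#' or not expressed in either table are excluded and counted in
#' `n_excluded` — status change is defined over the classified cohorts.
#'
#' @param classes_a,classes_b `gene_classes` tables sharing a gene
#'   universe (e.g. two cell types).
#' @return A `status_change` list with per-bucket counts and gene lists.
#' @export
status_change <- function(classes_a, classes_b) {
  a <- validate_gene_classes(classes_a)
  b <- validate_gene_classes(classes_b)
  shared <- intersect(a$gene, b$gene)
  if (!length(shared)) stop("disjoint gene universes")
  a <- a[match(shared, a$gene), ]
  b <- b[match(shared, b$gene), ]
  grp <- function(cl) ifelse(cl %in% c("DeMA_mat", "DeMA_pat"), "mono",
                             ifelse(cl == "biallelic", "biallelic", "other"))
  ga <- grp(a$class); gb <- grp(b$class)
  keep <- ga != "other" & gb != "other"
  bucket <- rep(NA_character_, length(shared))
  bucket[keep & ga == "mono" & gb == "biallelic"] <- "mono_to_biallelic"
  bucket[keep & ga == "biallelic" & gb == "mono"] <- "biallelic_to_mono"
  bucket[keep & ga == "biallelic" & gb == "biallelic"] <- "biallelic_stable"
  mono_both <- keep & ga == "mono" & gb == "mono"
  bucket[mono_both & a$class == b$class] <- "mono_same_allele"
  bucket[mono_both & a$class != b$class] <- "mono_switched_allele"
  lists <- split(shared[!is.na(bucket)], bucket[!is.na(bucket)])
  buckets <- c("mono_to_biallelic", "biallelic_to_mono", "mono_same_allele",
               "mono_switched_allele", "biallelic_stable")
  counts <- stats::setNames(integer(length(buckets)), buckets)
  for (bk in names(lists)) counts[bk] <- length(lists[[bk]])
  out <- list(counts = counts,
              genes = lists,
              switched_alleles = lists[["mono_switched_allele"]] %||% character(0),
              n_shared = length(shared),
              n_excluded = sum(!keep))
  class(out) <- "status_change"
  out
}

#' @export
print.status_change <- function(x, ...) {
  cat(sprintf("status_change over %d shared genes (%d excluded as unclassified):\n",
              x$n_shared, x$n_excluded))
  for (b in names(x$counts)) cat(sprintf("  %-22s %d\n", b, x$counts[[b]]))
  if (length(x$switched_alleles))
    cat("  allele-switch outliers:",
        paste(x$switched_alleles, collapse = ", "), "\n")
  invisible(x)
}

#' Exclusive (UpSet-style) intersections of class-filtered gene sets
#'
#' For each population the genes holding one of the `class_filter`
#' labels form a set; every gene of the union is then assigned to exactly
#' one membership combination, so the exclusive-intersection counts sum
#' to the union size. Combinations are ordered by descending count, then
#' lexicographically.
#'
#' @param tables a `gene_classes` table covering >= 2 populations, or a
#'   list of such tables (rbind-ed).
#' @param class_filter class label(s) defining membership, e.g.
#'   `c("DeMA_mat", "DeMA_pat")`.
#' @return An `intersection_report`: `populations`, `combos` (data.frame
#'   with `combo`, `degree`, `count`), `genes` (per-combo gene lists) and
#'   the logical membership matrix.
#' @export
intersect_classes <- function(tables, class_filter) {
  if (is.data.frame(tables)) tables <- list(tables)
  tables <- lapply(tables, validate_gene_classes)
  all_cls <- do.call(rbind, tables)
  bad <- setdiff(class_filter, GENE_CLASSES)
  if (length(bad)) stop("unknown class in filter: ", bad[1L])
  pops <- unique(all_cls$population)
  if (length(pops) < 2L) stop("need >= 2 populations to intersect")
  sets <- lapply(pops, function(p)
    unique(all_cls$gene[all_cls$population == p &
                          all_cls$class %in% class_filter]))
  names(sets) <- pops
  union_genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) union_genes %in% s,
                   logical(length(union_genes)))
  if (length(union_genes) == 1L)
    member <- matrix(member, nrow = 1L, dimnames = list(NULL, pops))
  rownames(member) <- union_genes
  sig <- apply(member, 1L, function(r) paste(pops[r], collapse = "&"))
  lists <- split(union_genes, sig)
  combos <- data.frame(combo = names(lists),
                       degree = lengths(strsplit(names(lists), "&", fixed = TRUE)),
                       count = lengths(lists),
                       stringsAsFactors = FALSE)
  ord <- order(-combos$count, combos$combo)
  combos <- combos[ord, ]
  rownames(combos) <- NULL
  out <- list(populations = pops, combos = combos,
              genes = lists[combos$combo], membership = member,
              class_filter = class_filter)
  class(out) <- "intersection_report"
  out
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("intersection_report: %d populations, classes {%s}, union %d genes\n",
              length(x$populations), paste(x$class_filter, collapse = ", "),
              nrow(x$membership)))
  print(x$combos)
  invisible(x)
}

#' Transcripts-per-gene summary by expression class
#'
#' Tabulates annotated transcripts (optionally restricted to
#' protein-coding records) per gene, grouped by the gene's expression
#' class, and tests each group's mean against a supplied reference with
#' a one-sample t-test. Genes missing from the annotation are excluded
#' and their number reported.
#'
#' @param classes a `gene_classes` table (one population).
#' @param annotation data.frame with columns `gene`, `transcript_id` and
#'   logical `coding`.
#' @param reference_mean null mean for the one-sample t-test.
#' @param coding_only count only transcripts flagged `coding`.
#' @return data.frame with per-class `n_genes`, `mean_tx`, `sd_tx`,
#'   `t`, `p`, plus attribute `n_missing_annotation`.
#' @export
transcripts_per_gene_summary <- function(classes, annotation,
                                         reference_mean,
                                         coding_only = FALSE) {
  classes <- validate_gene_classes(classes)
  need <- c("gene", "transcript_id", "coding")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop("annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  ann <- annotation
  if (coding_only) ann <- ann[ann$coding, ]
  tx_per_gene <- table(ann$gene)
  present <- classes$gene %in% names(tx_per_gene)
  n_missing <- sum(!present)
  if (n_missing) message(n_missing, " gene(s) absent from annotation excluded")
  cl <- classes[present, ]
  groups <- split(as.integer(tx_per_gene[cl$gene]), cl$class)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    s <- stats::sd(x)
    if (length(x) >= 2L && !is.na(s) && s > 0) {
      tt <- stats::t.test(x, mu = reference_mean)
      tv <- unname(tt$statistic); pv <- tt$p.value
    } else if (length(x) >= 1L && (is.na(s) || s == 0)) {
      # Degenerate: all values equal; t is 0 when on the reference,
      # undefined otherwise.
      tv <- if (mean(x) == reference_mean) 0 else NA_real_
      pv <- if (mean(x) == reference_mean) 1 else NA_real_
    } else {
      tv <- NA_real_; pv <- NA_real_
    }
    data.frame(class = g, n_genes = length(x), mean_tx = mean(x),
               sd_tx = s, t = tv, p = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_missing_annotation") <- n_missing
  out
}
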