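GENE_CLASSES <- c("biallelic", "DeMA_mat", "DeMA_pat", "RaMA",
                  "not_expressed", "inconclusive")

#' Construct an allele-resolved count table
#'
#' The universal input container: a pair of gene x sample integer count
#' matrices, one per parental allele, plus per-sample metadata. In the
#' C57BL/6J (maternal) x CAST/EiJ (paternal) cross the maternal allele is
#' the "B" column and the paternal allele the "C" column of the on-disk
#' TSV dialect (see [read_allele_counts()]).
#'
#' @param mat_counts integer matrix (genes x samples) of maternal counts.
#' @param pat_counts integer matrix, same shape, paternal counts.
#' @param gene_ids character vector of unique gene identifiers (defaults
#'   to the rownames of `mat_counts`).
#' @param sample_ids character vector of unique sample/cell identifiers.
#' @param meta data.frame with one row per sample and at least columns
#'   `sample`, `population`, `modality` (`"bulk"` or `"single_cell"`).
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(mat_counts, pat_counts,
                          gene_ids = rownames(mat_counts),
                          sample_ids = colnames(mat_counts),
                          meta = NULL) {
  mat_counts <- as.matrix(mat_counts)
  pat_counts <- as.matrix(pat_counts)
  if (!identical(dim(mat_counts), dim(pat_counts)))
    stop("mat_counts and pat_counts must have identical dimensions")
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(mat_counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(mat_counts)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(mat_counts))
    stop("gene_ids length does not match the matrices")
  if (length(sample_ids) != ncol(mat_counts))
    stop("sample_ids length does not match the matrices")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  for (m in list(mat_counts, pat_counts)) {
    if (!is.numeric(m)) stop("counts must be numeric")
    if (anyNA(m)) stop("counts must not contain NA")
    if (any(m < 0)) stop("counts must be non-negative")
    if (any(m != floor(m))) stop("counts must be integers")
  }
  storage.mode(mat_counts) <- "integer"
  storage.mode(pat_counts) <- "integer"
  dimnames(mat_counts) <- dimnames(pat_counts) <- list(gene_ids, sample_ids)
  if (is.null(meta)) {
    meta <- data.frame(sample = sample_ids, population = "all",
                       modality = "single_cell", stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample", "population", "modality")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("meta is missing column(s): ", paste(miss, collapse = ", "))
  if (!setequal(meta$sample, sample_ids))
    stop("meta$sample must cover exactly the sample ids")
  meta <- meta[match(sample_ids, meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  if (anyNA(meta$population)) stop("every sample needs a population label")
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids,
                 mat = mat_counts, pat = pat_counts, meta = meta),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  pops <- table(x$meta$population)
  cat("populations:",
      paste(sprintf("%s (%d, %s)", names(pops), as.integer(pops),
                    vapply(names(pops), function(p)
                      x$meta$modality[match(p, x$meta$population)], "")),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.allele_counts <- function(x) c(length(x$gene_ids), length(x$sample_ids))

#' Read an allele-resolved count TSV
#'
#' Parses the two-columns-per-sample dialect used for F1-hybrid
#' allele-specific counts: for every sample stem `S` the file carries a
#' column `SB` (C57BL/6J allele) and a column `SC` (CAST/EiJ allele).
#' `File5B` is therefore the C57BL/6J (maternal, in the default cross)
#' allele of cell `File5`. Pairing is by shared stem and is independent of
#' column order.
#'
#' @param path TSV file; first column gene ids, header row required.
#' @param metadata optional TSV with columns `sample`, `population`,
#'   `modality` describing each sample stem. When absent all samples get
#'   population `"all"` and modality `"single_cell"`.
#' @param maternal_strain which strain column suffix is the maternal
#'   allele: `"B"` (C57BL/6J, the default cross) or `"C"` for reciprocal
#'   crosses.
#' @return An [allele_counts] object.
#' @export
read_allele_counts <- function(path, metadata = NULL,
                               maternal_strain = c("B", "C")) {
  maternal_strain <- match.arg(maternal_strain)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("malformed count file: no columns")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene id: ", genes[duplicated(genes)][1L])
  cols <- names(df)[-1L]
  suf <- substring(cols, nchar(cols))
  bad <- cols[!suf %in% c("B", "C")]
  if (length(bad))
    stop("unpaired allele column (no B/C suffix): ", bad[1L])
  stems <- substring(cols, 1L, nchar(cols) - 1L)
  for (s in unique(stems)) {
    have <- suf[stems == s]
    if (!all(c("B", "C") %in% have))
      stop("unpaired allele column: ", paste0(s, have[1L]))
  }
  stems_u <- unique(stems)
  get_mat <- function(suffix) {
    m <- matrix(0L, nrow = length(genes), ncol = length(stems_u))
    for (j in seq_along(stems_u)) {
      col <- paste0(stems_u[j], suffix)
      v <- df[[col]]
      if (is.character(v)) {
        vn <- suppressWarnings(as.numeric(v))
        if (anyNA(vn) && !all(is.na(v[is.na(vn)])))
          stop(sprintf("non-numeric count for gene '%s' in column '%s'",
                       genes[which(is.na(vn) & !is.na(v))[1L]], col))
        v <- vn
      }
      if (anyNA(v)) {
        warning(sprintf("missing cells in column '%s' treated as 0", col))
        v[is.na(v)] <- 0
      }
      if (any(v < 0))
        stop(sprintf("negative count for gene '%s' in column '%s'",
                     genes[which(v < 0)[1L]], col))
      if (any(v != floor(v)))
        stop(sprintf("non-integer count for gene '%s' in column '%s'",
                     genes[which(v != floor(v))[1L]], col))
      m[, j] <- as.integer(v)
    }
    m
  }
  b <- get_mat("B")
  c_ <- get_mat("C")
  if (maternal_strain == "B") { mat <- b; pat <- c_ } else { mat <- c_; pat <- b }
  meta <- NULL
  if (!is.null(metadata)) {
    meta <- utils::read.delim(metadata, header = TRUE, check.names = FALSE,
                              stringsAsFactors = FALSE)
  }
  allele_counts(mat, pat, gene_ids = genes, sample_ids = stems_u, meta = meta)
}

#' Write an allele-resolved count TSV
#'
#' Inverse of [read_allele_counts()]: emits one `SB` and one `SC` column
#' per sample stem in canonical (sample, B-then-C) order, so
#' write-then-read round-trips losslessly.
#'
#' @param x an [allele_counts] object.
#' @param path output file path.
#' @param metadata_path optional path for the sample metadata TSV.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "allele_counts"))
  out <- data.frame(gene = x$gene_ids, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (j in seq_along(x$sample_ids)) {
    out[[paste0(x$sample_ids[j], "B")]] <- x$mat[, j]
    out[[paste0(x$sample_ids[j], "C")]] <- x$pat[, j]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(metadata_path))
    utils::write.table(x$meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a gene-class table
#'
#' TSV with columns gene, population, class, n_mono_mat, n_mono_pat,
#' n_biallelic, n_expressed; round-trips losslessly through
#' [read_gene_classes()].
#'
#' @param classes a `gene_classes` data.frame as produced by
#'   [classify_population()] or [classify_bulk()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_classes <- function(classes, path) {
  classes <- validate_gene_classes(classes)
  cols <- c("gene", "population", "class",
            "n_mono_mat", "n_mono_pat", "n_biallelic", "n_expressed")
  utils::write.table(classes[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-class table written by [write_gene_classes()]
#' @param path TSV file path.
#' @return A `gene_classes` data.frame.
#' @export
read_gene_classes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_gene_classes(df)
}

validate_gene_classes <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("gene", "population", "class",
            "n_mono_mat", "n_mono_pat", "n_biallelic", "n_expressed")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene-class table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$class), GENE_CLASSES)
  if (length(bad)) stop("unknown gene class label: ", bad[1L])
  if (anyDuplicated(df[c("gene", "population")]))
    stop("duplicated (gene, population) rows")
  class(df) <- c("gene_classes", "data.frame")
  df
}

#' @export
print.gene_classes <- function(x, ...) {
  cat("gene_classes:", nrow(x), "gene x population calls\n")
  print(table(population = x$population, class = x$class))
  invisible(x)
}

#' @export
summary.gene_classes <- function(object, ...) {
  tab <- as.data.frame(table(population = object$population,
                             class = object$class),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n_genes"
  tab[tab$n_genes > 0, ]
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `term`, `description`,
#' then member gene ids. Duplicate members within a line are deduplicated
#' with a warning; duplicate term names are an error.
#'
#' @param path GMT file path.
#' @return A `gene_sets` object: list with `sets` (named list of character
#'   vectors) and `universe` (NULL unless set later).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    term <- f[1L]
    if (term %in% names(sets)) stop("duplicate term: ", term)
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members in term '%s' deduplicated", term))
      members <- unique(members)
    }
    if (!length(members)) stop(sprintf("GMT line %d defines an empty set", i))
    sets[[term]] <- members
  }
  gene_sets(sets)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (term -> member gene ids).
#' @param universe optional background gene ids.
#' @return A `gene_sets` object.
#' @export
gene_sets <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every set needs a term name")
  if (anyDuplicated(names(sets))) stop("duplicate term names")
  if (any(!vapply(sets, length, 1L))) stop("empty set not allowed")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(sets = sets,
                 universe = if (is.null(universe)) NULL
                            else unique(as.character(universe))),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d terms (set sizes %d-%d)%s\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              if (is.null(x$universe)) ""
              else sprintf(", universe %d genes", length(x$universe))))
  invisible(x)
}
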