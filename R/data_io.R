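# Count matrices, gene sets (GMT) and cell groupings: validation and file I/O.
#
# Counts live in plain base matrices, cells as rows and genes as columns,
# with cell ids as rownames and gene symbols as colnames -- the convention
# every downstream function in the package assumes.

#' Validate a cells-by-genes count matrix
#'
#' Checks that `x` is a nonnegative integer-valued matrix with unique,
#' non-missing cell ids (rownames) and gene names (colnames).  All model
#' and saliency functions in the package call this on their inputs.
#'
#' @param x A numeric matrix, cells as rows, genes as columns.
#' @return `x`, invisibly, with storage mode coerced to double.
#' @export
validate_counts <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_oae("oae_malformed_input", "counts must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_oae("oae_malformed_input",
             "counts must carry cell ids as rownames and gene names as colnames")
  bad <- which(!is.finite(x) | x < 0 | x != round(x))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x))
    stop_oae("oae_malformed_input",
             "counts must be nonnegative integers; first offending entry is cell '",
             rownames(x)[i[1]], "', gene '", colnames(x)[i[2]], "' (value ",
             format(x[bad[1]]), ")")
  }
  if (anyDuplicated(rownames(x)))
    stop_oae("oae_duplicate_identifier", "duplicate cell id: '",
             rownames(x)[duplicated(rownames(x))][1], "'")
  if (anyDuplicated(colnames(x)))
    stop_oae("oae_duplicate_identifier", "duplicate gene name: '",
             colnames(x)[duplicated(colnames(x))][1], "'")
  storage.mode(x) <- "double"
  invisible(x)
}

#' Read a count matrix
#'
#' Reads raw counts from either a dense delimited file (gene names in the
#' header row, cell ids in the first column; tab or comma auto-detected)
#' or a Matrix Market triplet file with two plain-text sidecars giving
#' row and column names (one per line).
#'
#' @param path Path to the count file (`.mtx` for Matrix Market).
#' @param fmt `"dense_delimited"` or `"matrix_market"`.
#' @param genes_as_rows Set `TRUE` when the file stores genes as rows
#'   (10x-style exports); the matrix is transposed on read.  The default
#'   orientation is cells as rows.
#' @param row_names,col_names For `matrix_market` only: sidecar file
#'   paths.  Default `<path>.rownames` / `<path>.colnames`.
#' @return A validated cells-by-genes numeric matrix.
#' @seealso [write_counts()], [read_gmt()], [restrict_to_signature_genes()]
#' @export
read_counts <- function(path, fmt = c("dense_delimited", "matrix_market"),
                        genes_as_rows = FALSE,
                        row_names = paste0(path, ".rownames"),
                        col_names = paste0(path, ".colnames")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path))
    stop_oae("oae_malformed_input", "file not found: ", path)
  if (fmt == "dense_delimited") {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    df <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                     check.names = FALSE, comment.char = "", quote = "\"")
    x <- as.matrix(df)
    if (!is.numeric(x))
      stop_oae("oae_malformed_input", "non-numeric entries in ", path)
  } else {
    m <- Matrix::readMM(path)
    if (!file.exists(row_names) || !file.exists(col_names))
      stop_oae("oae_malformed_input",
               "matrix_market input needs name sidecar files: ",
               row_names, ", ", col_names)
    rn <- readLines(row_names)
    cn <- readLines(col_names)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop_oae("oae_malformed_input",
               "sidecar name counts do not match matrix dimensions")
    x <- as.matrix(m)
    # pattern-format files (e.g. an all-zero matrix) read back as logical
    if (is.logical(x)) storage.mode(x) <- "double"
    dimnames(x) <- list(rn, cn)
  }
  if (genes_as_rows) x <- t(x)
  x <- validate_counts(x)
  x
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; both formats round-trip exactly.
#'
#' @inheritParams read_counts
#' @param x A validated cells-by-genes count matrix.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, fmt = c("dense_delimited", "matrix_market"),
                         row_names = paste0(path, ".rownames"),
                         col_names = paste0(path, ".colnames")) {
  fmt <- match.arg(fmt)
  validate_counts(x)
  if (fmt == "dense_delimited") {
    df <- data.frame(cell_id = rownames(x), x, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    m <- methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"),
                     "generalMatrix")
    Matrix::writeMM(m, path)
    writeLines(rownames(x), row_names)
    writeLines(colnames(x), col_names)
  }
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.  Symbols
#'   are de-duplicated within each set; empty sets and duplicate set
#'   names are errors.
#' @param provenance Free-text source tag (e.g. the GMT description
#'   column or a file name).
#' @return An object of class `gene_sets`: the named list with a
#'   `provenance` attribute.
#' @export
gene_sets <- function(sets, provenance = "") {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop_oae("oae_malformed_input", "sets must be a fully named list")
  if (anyDuplicated(names(sets)))
    stop_oae("oae_duplicate_identifier", "duplicate gene-set name: '",
             names(sets)[duplicated(names(sets))][1], "'")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0))
    stop_oae("oae_malformed_input", "empty gene set: '",
             names(sets)[lengths(sets) == 0][1], "'")
  structure(sets, provenance = provenance, class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("Gene-set collection:", length(x), "sets,",
      length(unique(unlist(x))), "distinct genes\n")
  prov <- attr(x, "provenance")
  if (nzchar(prov[1])) cat("Provenance:", prov[1], "\n")
  show <- head(seq_along(x), 6)
  for (i in show)
    cat("  ", names(x)[i], " (", length(x[[i]]), " genes)\n", sep = "")
  if (length(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate symbols within a line are collapsed; the description fields
#' are kept as provenance.
#'
#' @param path Path to a GMT file.
#' @return A [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_oae("oae_malformed_input", "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop_oae("oae_malformed_gmt", "GMT line ", short[1],
             " has fewer than 3 tab-separated fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop_oae("oae_duplicate_identifier", "duplicate gene-set name: '",
             nm[duplicated(nm)][1], "'")
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_sets(sets, provenance = paste0(basename(path), ": ",
                                      paste(unique(desc), collapse = "; ")))
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_sets()] collection.
#' @param path Output path.
#' @param description Description field written for every line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = attr(sets, "provenance")) {
  if (is.null(description) || !nzchar(description[1])) description <- "na"
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[1], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a count matrix to signature genes
#'
#' Keeps exactly the genes appearing in the union of all gene sets,
#' preserving the original column order.  Training on the signature gene
#' space keeps the model small and every input feature scoreable.
#'
#' @param counts Cells-by-genes count matrix.
#' @param signatures A [gene_sets()] collection.
#' @param ignore_case Fold both sides to upper case before matching
#'   (gene symbols are matched by exact string equality by default).
#' @return The restricted count matrix (idempotent).
#' @export
restrict_to_signature_genes <- function(counts, signatures, ignore_case = FALSE) {
  validate_counts(counts)
  sig <- unique(unlist(signatures))
  gn <- colnames(counts)
  keep <- if (ignore_case) toupper(gn) %in% toupper(sig) else gn %in% sig
  if (!any(keep))
    stop_oae("oae_empty_feature_space",
             "no gene of the count matrix appears in the signatures")
  counts[, keep, drop = FALSE]
}

#' Construct a cell grouping
#'
#' @param assignment Named character vector or factor: names are cell
#'   ids, values are group labels.
#' @return An object of class `cell_grouping`: a factor named by cell
#'   id whose levels are the sorted distinct labels.
#' @export
cell_grouping <- function(assignment) {
  if (is.null(names(assignment)) || any(names(assignment) == ""))
    stop_oae("oae_malformed_input", "assignment must be named by cell id")
  if (anyDuplicated(names(assignment)))
    stop_oae("oae_duplicate_identifier", "cell id assigned twice: '",
             names(assignment)[duplicated(names(assignment))][1], "'")
  f <- factor(as.character(assignment),
              levels = sort(unique(as.character(assignment))))
  names(f) <- names(assignment)
  structure(f, class = c("cell_grouping", "factor"))
}

#' @export
print.cell_grouping <- function(x, ...) {
  cat("Cell grouping:", length(x), "cells in", nlevels(x), "groups\n")
  print(table(group = as.character(x)))
  invisible(x)
}

#' Read cell group labels
#'
#' Two-column delimited file (`cell_id`, `group`), with or without a
#' header; tab or comma auto-detected.
#'
#' @param path Path to the label file.
#' @return A [cell_grouping()].
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_oae("oae_malformed_input", "file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  header <- grepl("cell", strsplit(first, sep, fixed = TRUE)[[1]][1],
                  ignore.case = TRUE)
  df <- read.table(path, header = header, sep = sep, colClasses = "character")
  if (ncol(df) < 2)
    stop_oae("oae_malformed_input", "label file needs two columns (cell_id, group)")
  cell_grouping(stats::setNames(df[[2]], df[[1]]))
}

#' Write cell group labels
#'
#' @param grouping A [cell_grouping()].
#' @param path Output path (TSV with header `cell_id`, `group`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(grouping, path) {
  write.table(data.frame(cell_id = names(grouping),
                         group = as.character(grouping)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
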