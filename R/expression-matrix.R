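#' Expression matrix with gene and library metadata
#'
#' The container every stage of the pipeline consumes: a genes x cells matrix
#' of non-negative values tagged with its unit (`"counts"`, `"fpkm"` or
#' `"log2fpkm"`), per-gene transcript lengths in bp, and per-library mapped
#' read totals. Lengths and totals travel with the matrix because FPKM
#' normalization and the mapped-read QC filter need them.
#'
#' @param values Numeric genes x cells matrix, no negative entries.
#' @param gene_ids Character vector, unique, length `nrow(values)`.
#' @param cell_ids Character vector, unique, length `ncol(values)`.
#' @param gene_length_bp Positive numeric vector per gene (may be `NULL` for
#'   matrices already in FPKM).
#' @param mapped_total Positive numeric vector per cell: total mapped reads in
#'   the library (not the column sum of the count matrix, which excludes
#'   reads mapped outside annotated genes). May be `NULL`.
#' @param unit One of `"counts"`, `"fpkm"`, `"log2fpkm"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids,
                              gene_length_bp = NULL, mapped_total = NULL,
                              unit = c("counts", "fpkm", "log2fpkm")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(gene_ids)) {
    stop_config("matrix has ", nrow(values), " rows but ", length(gene_ids),
                " gene ids")
  }
  if (ncol(values) != length(cell_ids)) {
    stop_config("matrix has ", ncol(values), " columns but ", length(cell_ids),
                " cell ids")
  }
  if (anyDuplicated(gene_ids)) stop_config("gene_ids must be unique")
  if (anyDuplicated(cell_ids)) stop_config("cell_ids must be unique")
  if (length(values) && min(values) < 0) {
    stop_config("expression values must be non-negative")
  }
  if (!is.null(gene_length_bp)) {
    stopifnot(length(gene_length_bp) == nrow(values))
    if (any(gene_length_bp <= 0)) stop_config("gene lengths must be positive")
  }
  if (!is.null(mapped_total)) {
    stopifnot(length(mapped_total) == ncol(values))
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(cell_ids))
  structure(
    list(values = values,
         gene_ids = as.character(gene_ids),
         cell_ids = as.character(cell_ids),
         gene_length_bp = gene_length_bp,
         mapped_total = mapped_total,
         unit = unit),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  if (!is.null(x$mapped_total)) {
    cat(sprintf("  mapped reads/library: median %.3g (range %.3g-%.3g)\n",
                median(x$mapped_total), min(x$mapped_total),
                max(x$mapped_total)))
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or cell ids
#'
#' @param x An `expression_matrix`.
#' @param genes,cells Character ids (or `NULL` to keep all). Unknown ids are
#'   an error.
#' @return An `expression_matrix` restricted to the requested rows/columns.
#' @export
subset_matrix <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else match(genes, x$gene_ids)
  ci <- if (is.null(cells)) seq_along(x$cell_ids) else match(cells, x$cell_ids)
  if (anyNA(gi)) stop_config("unknown gene ids: ",
                             paste(head(genes[is.na(gi)], 5), collapse = ", "))
  if (anyNA(ci)) stop_config("unknown cell ids: ",
                             paste(head(cells[is.na(ci)], 5), collapse = ", "))
  expression_matrix(x$values[gi, ci, drop = FALSE],
                    x$gene_ids[gi], x$cell_ids[ci],
                    gene_length_bp = x$gene_length_bp[gi],
                    mapped_total = x$mapped_total[ci],
                    unit = x$unit)
}

#' Write an expression matrix to disk
#'
#' Two encodings: MatrixMarket (`<prefix>.mtx` with `genes.tsv` /
#' `cells.tsv` sidecars) for sparse counts, or a single dense TSV. Both
#' round-trip values, ids, gene lengths, mapped totals and the unit tag
#' losslessly through [read_expression()].
#'
#' @param x An `expression_matrix`.
#' @param path For `format = "mtx"`, a directory (created if needed); for
#'   `"tsv"`, a file path.
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("mtx", "tsv")) {
  stopifnot(inherits(x, "expression_matrix"))
  format <- match.arg(format)
  genes <- data.frame(gene_id = x$gene_ids,
                      length_bp = if (is.null(x$gene_length_bp)) NA_real_
                                  else x$gene_length_bp)
  cells <- data.frame(cell_id = x$cell_ids,
                      mapped_total = if (is.null(x$mapped_total)) NA_real_
                                     else x$mapped_total,
                      unit = x$unit)
  if (format == "mtx") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(x$values, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    write_tsv(genes, file.path(path, "genes.tsv"))
    write_tsv(cells, file.path(path, "cells.tsv"))
  } else {
    df <- data.frame(gene_id = x$gene_ids,
                     length_bp = genes$length_bp,
                     as.data.frame(x$values, check.names = FALSE))
    write_tsv(df, path)
    write_tsv(cells, paste0(path, ".cells.tsv"))
  }
  invisible(path)
}

#' Read an expression matrix written by [write_expression()]
#'
#' @param path Directory (MatrixMarket layout) or TSV file path.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path) {
  if (dir.exists(path)) {
    mtx_path <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx_path)) stop_config("no matrix.mtx under ", path)
    m <- tryCatch(as.matrix(Matrix::readMM(mtx_path)),
                  error = function(e) {
                    stop_config("failed to parse ", mtx_path, ": ",
                                conditionMessage(e))
                  })
    genes <- read_tsv(file.path(path, "genes.tsv"))
    cells <- read_tsv(file.path(path, "cells.tsv"))
    if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m)) {
      stop_config("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
                  " but sidecars list ", nrow(genes), " genes and ",
                  nrow(cells), " cells")
    }
  } else {
    df <- read_tsv(path)
    genes <- df[, c("gene_id", "length_bp")]
    m <- as.matrix(df[, setdiff(names(df), c("gene_id", "length_bp")),
                      drop = FALSE])
    cells <- read_tsv(paste0(path, ".cells.tsv"))
    if (nrow(cells) != ncol(m)) {
      stop_config("dimension mismatch: matrix has ", ncol(m),
                  " cell columns but sidecar lists ", nrow(cells))
    }
  }
  expression_matrix(
    m, genes$gene_id, cells$cell_id,
    gene_length_bp = if (all(is.na(genes$length_bp))) NULL else genes$length_bp,
    mapped_total = if (all(is.na(cells$mapped_total))) NULL
                   else cells$mapped_total,
    unit = cells$unit[1]
  )
}
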