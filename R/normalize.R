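# FPKM normalization, log transform, expressed-gene filter.

#' Convert counts to FPKM
#'
#' `FPKM = counts / (length_kb * mapped_total / 1e6)`, using each library's
#' total mapped reads (not the column sum of the count matrix) as the
#' per-million denominator.
#'
#' @param x An `expression_matrix` with unit `"counts"`, gene lengths and
#'   mapped totals present.
#' @return An `expression_matrix` with unit `"fpkm"`.
#' @export
compute_fpkm <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$unit != "counts") stop_config("compute_fpkm needs counts, got ", x$unit)
  if (is.null(x$gene_length_bp)) stop_config("gene lengths missing")
  if (is.null(x$mapped_total)) stop_config("mapped totals missing")
  if (any(x$mapped_total <= 0)) stop_config("zero mapped_total for library: ",
                                            x$cell_ids[x$mapped_total <= 0][1])
  if (any(x$gene_length_bp <= 0)) stop_config("zero gene length")
  denom <- outer(x$gene_length_bp / 1000, x$mapped_total / 1e6)
  expression_matrix(x$values / denom, x$gene_ids, x$cell_ids,
                    gene_length_bp = x$gene_length_bp,
                    mapped_total = x$mapped_total, unit = "fpkm")
}

#' Log2 transform of FPKM
#'
#' `log2(FPKM + pseudocount)`. The default pseudocount of 1 maps FPKM 0 to 0
#' and FPKM 1 to 1; set `pseudocount = 0` to take raw logs of positive values
#' (zeros then become `-Inf`, so that dialect is only for matrices already
#' filtered to expressed genes).
#'
#' @param x An `expression_matrix` with unit `"fpkm"`.
#' @param pseudocount Non-negative offset (default 1).
#' @return An `expression_matrix` with unit `"log2fpkm"`.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$unit != "fpkm") stop_config("log2_transform needs fpkm, got ", x$unit)
  check_scalar_number(pseudocount, "pseudocount", lower = 0)
  v <- log2(x$values + pseudocount)
  out <- x
  out$values <- v
  dimnames(out$values) <- dimnames(x$values)
  out$unit <- "log2fpkm"
  out
}

#' Keep genes expressed in at least one cell
#'
#' Genes that register zero in every retained sample carry no information and
#' are omitted; a gene nonzero in a single cell is kept.
#'
#' @param x An `expression_matrix` (counts or FPKM).
#' @param mode Only `"any_nonzero"` is defined.
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(x, mode = "any_nonzero") {
  stopifnot(inherits(x, "expression_matrix"))
  if (!x$unit %in% c("counts", "fpkm")) {
    stop_config("filter_expressed needs counts or fpkm, got ", x$unit)
  }
  mode <- match.arg(mode, "any_nonzero")
  if (ncol(x$values) == 0 || nrow(x$values) == 0) return(character())
  x$gene_ids[rowSums(x$values > 0) >= 1]
}
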