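# Highly variable gene selection by the CV^2-versus-mean criterion.
#
# CV^2 (= variance / mean^2, sample variance with n-1) is computed on linear
# FPKM; the per-gene mean is then reported as log2(mean + pseudocount) because
# the selection thresholds live on log2 FPKM / CV^2 axes. A hyperbolic trend
# CV^2(m) = a1/m + a0 is fitted for diagnostics (for Poisson-limited counts
# a1 is 1 and a0 is 0); selection itself depends only on the two thresholds,
# not the fit.

#' Per-gene mean and CV^2 with a hyperbolic trend fit
#'
#' @param x An `expression_matrix` with unit `"fpkm"` (or counts for
#'   technical-noise calibration).
#' @param genes Optional gene-id subset; default all genes.
#' @param pseudocount Offset in the reported log2 mean (default 1).
#' @return A `variable_genes` object: data.frame `stats` with `gene_id`,
#'   `mean_fpkm`, `mean_log2fpkm`, `cv2`; trend coefficients `a0`, `a1`.
#' @export
fit_cv2_trend <- function(x, genes = NULL, pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!is.null(genes)) x <- subset_matrix(x, genes = genes)
  v <- x$values
  m <- rowMeans(v)
  if (sum(m > 0) < 10) stop_config("need >= 10 genes with positive mean")
  s2 <- apply(v, 1, var)
  cv2 <- ifelse(m > 0, s2 / m^2, NA_real_)
  pos <- which(m > 0)
  if (length(unique(m[pos])) < 2) stop_config("degenerate fit: all means equal")
  fit <- stats::lm(cv2[pos] ~ I(1 / m[pos]))
  stats_df <- data.frame(gene_id = x$gene_ids, mean_fpkm = m,
                         mean_log2fpkm = log2(m + pseudocount), cv2 = cv2,
                         stringsAsFactors = FALSE)
  structure(list(stats = stats_df,
                 a0 = unname(coef(fit)[1]), a1 = unname(coef(fit)[2]),
                 pseudocount = pseudocount),
            class = "variable_genes")
}

#' @export
print.variable_genes <- function(x, ...) {
  cat(sprintf("variable_genes: %d genes; trend CV^2(m) = %.3g/m + %.3g\n",
              nrow(x$stats), x$a1, x$a0))
  invisible(x)
}

#' Select highly variable genes by strict thresholds
#'
#' A gene is selected iff `mean_log2fpkm > mean_threshold` AND
#' `cv2 > cv2_threshold`, both strict; the defaults (1, 0.5) are the standard
#' thresholds on the log2 FPKM and CV^2 axes.
#'
#' @param vg A `variable_genes` object from [fit_cv2_trend()].
#' @param mean_threshold Threshold on log2(mean FPKM + pseudocount)
#'   (default 1).
#' @param cv2_threshold Threshold on CV^2 (default 0.5).
#' @return Character vector of selected gene ids (sorted as in the input);
#'   warns when empty.
#' @export
select_variable_genes <- function(vg, mean_threshold = 1, cv2_threshold = 0.5) {
  stopifnot(inherits(vg, "variable_genes"))
  s <- vg$stats
  sel <- !is.na(s$cv2) & s$mean_log2fpkm > mean_threshold &
    s$cv2 > cv2_threshold
  out <- s$gene_id[sel]
  if (!length(out)) warning("no genes pass the variable-gene thresholds")
  out
}

#' Merge per-group variable-gene lists
#'
#' Variable genes are computed within each group (e.g. per reprogramming
#' driver) and then merged to a single list: the set union, sorted by gene id
#' for determinism.
#'
#' @param lists A list of character vectors (>= 1).
#' @return Sorted character vector of the union.
#' @export
merge_variable_lists <- function(lists) {
  if (!is.list(lists) || length(lists) < 1) {
    stop_config("need at least one gene list")
  }
  sort(unique(unlist(lists, use.names = FALSE)))
}
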