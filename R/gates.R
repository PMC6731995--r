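# Co-expression gating and immunofluorescence positivity quantification.

#' Four-way co-expression gate on two genes
#'
#' Classifies every cell by strict thresholds on two genes — the
#' double-positive gate used to call, e.g., Nanog+Gata6+ early-ICM-like
#' intermediates. The default threshold of 1 on log2(FPKM+1) matches the
#' variable-gene mean threshold and is a convention of this package, not a
#' published cutoff.
#'
#' @param x An `expression_matrix`.
#' @param gene_a,gene_b Gene ids (an absent gene is an error naming it).
#' @param threshold_a,threshold_b Strict ">" cutoffs (default 1).
#' @return A `gate_result`: list with per-cell `classification` (factor with
#'   levels double_negative, A_only, B_only, double_positive), `counts`,
#'   `percent`, and the thresholds used.
#' @export
co_expression_gate <- function(x, gene_a, gene_b,
                               threshold_a = 1, threshold_b = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  for (g in c(gene_a, gene_b)) {
    if (!g %in% x$gene_ids) stop_config("gene '", g, "' not in the matrix")
  }
  a <- x$values[match(gene_a, x$gene_ids), ]
  b <- x$values[match(gene_b, x$gene_ids), ]
  pos_a <- a > threshold_a
  pos_b <- b > threshold_b
  cls <- factor(ifelse(pos_a & pos_b, "double_positive",
                ifelse(pos_a, "A_only",
                ifelse(pos_b, "B_only", "double_negative"))),
                levels = c("double_negative", "A_only", "B_only",
                           "double_positive"))
  counts <- table(cls)
  structure(list(cell_id = x$cell_ids, classification = cls,
                 counts = counts,
                 percent = 100 * as.numeric(counts) / length(cls),
                 gene_a = gene_a, gene_b = gene_b,
                 threshold_a = threshold_a, threshold_b = threshold_b),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("gate_result: %s vs %s (thresholds %g, %g)\n",
              x$gene_a, x$gene_b, x$threshold_a, x$threshold_b))
  print(x$counts)
  invisible(x)
}

#' Percent positive cells by the mean + 2 SD control threshold
#'
#' The stringent positivity call for immunofluorescence intensities: the
#' threshold is the control (marker-negative reference) mean plus two sample
#' standard deviations (n-1 denominator); a test cell is positive iff its
#' intensity strictly exceeds the threshold. For a test population identical
#' to a normal control this calls ~2.3% of cells (the upper tail beyond
#' +2 SD).
#'
#' @param test,control Numeric intensity vectors; `control` needs n >= 2.
#' @return An `if_quant`: list with `threshold`, `n_total`, `n_positive`,
#'   `percent_positive`.
#' @export
if_percent_positive <- function(test, control) {
  if (length(control) < 2) {
    stop_config("need >= 2 control intensities to estimate the SD")
  }
  if (anyNA(test) || anyNA(control)) stop_config("intensities contain NA")
  threshold <- mean(control) + 2 * sd(control)
  n_pos <- sum(test > threshold)
  structure(list(threshold = threshold, n_total = length(test),
                 n_positive = n_pos,
                 percent_positive = 100 * n_pos / length(test)),
            class = "if_quant")
}

#' @export
print.if_quant <- function(x, ...) {
  cat(sprintf("if_quant: %d/%d cells positive (%.2f%%) at threshold %.4g\n",
              x$n_positive, x$n_total, x$percent_positive, x$threshold))
  invisible(x)
}
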