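# Library-level quality control: mapped-read depth and gene-body coverage
# bias. A library passes overall iff it passes both filters.

#' Flag libraries with too few mapped reads
#'
#' Libraries with fewer than `min_mapped` mapped reads are excluded; a
#' library exactly at the threshold is kept (the rule is "fewer than").
#'
#' @param x An `expression_matrix` with `mapped_total` present.
#' @param min_mapped Minimum mapped reads (default 500000).
#' @return Data.frame: `library`, `mapped_total`, `pass_mapped`, `reason`.
#' @export
filter_min_mapped <- function(x, min_mapped = 5e5) {
  stopifnot(inherits(x, "expression_matrix"))
  check_scalar_number(min_mapped, "min_mapped", lower = 0)
  if (is.null(x$mapped_total)) {
    stop_config("mapped_total missing for all libraries")
  }
  if (anyNA(x$mapped_total)) {
    stop_config("mapped_total missing for library: ",
                paste(x$cell_ids[is.na(x$mapped_total)][1], collapse = ", "))
  }
  pass <- x$mapped_total >= min_mapped
  data.frame(library = x$cell_ids, mapped_total = x$mapped_total,
             pass_mapped = pass,
             reason = ifelse(pass, "",
                             sprintf("mapped_total %s < %s",
                                     format(x$mapped_total, trim = TRUE,
                                            scientific = FALSE),
                                     format(min_mapped,
                                            scientific = FALSE))),
             stringsAsFactors = FALSE)
}

#' Gene-body coverage bias ratio per library
#'
#' The 3'/5' bias statistic: reads in positional bins covering percentiles
#' 50-100 of gene length divided by reads in bins covering percentiles 1-49,
#' summed over all genes of a library. With 100 bins the split is 51 bins
#' versus 49, so perfectly uniform coverage gives 51/49, not 1. Libraries
#' with ratio strictly greater than `max_ratio` fail; a ratio of exactly
#' `max_ratio` passes. A zero 5' denominator leaves the ratio undefined and
#' fails the library.
#'
#' @param coverage Data.frame with columns `library`, `bin`, `reads`
#'   (optionally `gene`; reads are summed over genes), bins numbered
#'   1..n_bins along the gene body 5' to 3'.
#' @param n_bins Number of positional bins the histograms use.
#' @param max_ratio Exclusion threshold (default 2, strict ">").
#' @return Data.frame: `library`, `bias_ratio` (NA when undefined),
#'   `pass_bias`, `reason`.
#' @export
bias_ratio <- function(coverage, n_bins = 100, max_ratio = 2) {
  check_scalar_number(n_bins, "n_bins", lower = 2)
  stopifnot(all(c("library", "bin", "reads") %in% names(coverage)))
  if (any(coverage$bin < 1 | coverage$bin > n_bins)) {
    stop_config("bins must lie in 1..", n_bins)
  }
  split_bin <- floor(0.49 * n_bins)   # 49 for percentile bins
  five <- tapply(coverage$reads * (coverage$bin <= split_bin),
                 coverage$library, sum)
  three <- tapply(coverage$reads * (coverage$bin > split_bin),
                  coverage$library, sum)
  libs <- names(five)
  ratio <- ifelse(five > 0, three / five, NA_real_)
  pass <- !is.na(ratio) & ratio <= max_ratio
  reason <- ifelse(is.na(ratio), "no 5' coverage",
                   ifelse(pass, "", sprintf("bias ratio %.4g > %.4g",
                                            ratio, max_ratio)))
  data.frame(library = libs, bias_ratio = as.numeric(ratio),
             pass_bias = pass, reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combined library QC report
#'
#' A library passes iff it has at least `min_mapped` mapped reads AND a
#' defined gene-body bias ratio not exceeding `max_ratio`. The two filters
#' commute: the pass set is the intersection of their individual pass sets.
#'
#' @inheritParams filter_min_mapped
#' @inheritParams bias_ratio
#' @return A `qc_report`: data.frame with per-library `mapped_total`,
#'   `bias_ratio`, `pass_mapped`, `pass_bias`, `pass`, `reason`.
#' @export
qc_report <- function(x, coverage, min_mapped = 5e5, n_bins = 100,
                      max_ratio = 2) {
  mm <- filter_min_mapped(x, min_mapped)
  br <- bias_ratio(coverage, n_bins = n_bins, max_ratio = max_ratio)
  i <- match(mm$library, br$library)
  if (anyNA(i)) {
    stop_config("no coverage histogram for library: ",
                paste(head(mm$library[is.na(i)], 5), collapse = ", "))
  }
  out <- data.frame(library = mm$library, mapped_total = mm$mapped_total,
                    bias_ratio = br$bias_ratio[i],
                    pass_mapped = mm$pass_mapped, pass_bias = br$pass_bias[i],
                    stringsAsFactors = FALSE)
  out$pass <- out$pass_mapped & out$pass_bias
  out$reason <- trimws(paste(mm$reason, br$reason[i], sep = " "))
  class(out) <- c("qc_report", "data.frame")
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d/%d libraries pass (%d fail depth, %d fail bias)\n",
              sum(x$pass), nrow(x), sum(!x$pass_mapped), sum(!x$pass_bias)))
  invisible(x)
}
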