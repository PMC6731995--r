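# Local (LOESS-style) polynomial regression of expression against pseudotime.
#
# Conventions, stated exactly because they are the contract downstream tests
# hold this code to: at each query point the window is the k = ceiling(span*n)
# nearest x-neighbours; tricube weights w = (1 - (d/d_max)^3)^3 with d_max the
# distance to the k-th neighbour (a point exactly at d_max gets weight zero,
# and if every in-window weight vanishes the window grows by one neighbour);
# a weighted polynomial of the requested degree is fitted and evaluated at
# the query. No robustness iterations. Defaults: span = 1/3, degree = 2.

#' Local polynomial (LOESS) fit
#'
#' @param x,y Numeric vectors of equal length n >= degree + 2.
#' @param span Window fraction in (0, 1]; `ceiling(span * n)` neighbours per
#'   window (default 1/3).
#' @param degree Local polynomial degree 0, 1 or 2 (default 2).
#' @param query_points Points at which to evaluate; default a 100-point grid
#'   over `range(x)`.
#' @return A `loess_fit`: list with `query_points`, `fitted_values`, `span`,
#'   `degree`, `n_points`.
#' @export
loess_fit <- function(x, y, span = 1/3, degree = 2, query_points = NULL) {
  stopifnot(length(x) == length(y))
  check_scalar_number(span, "span", lower = 1e-12, upper = 1)
  if (!degree %in% 0:2) stop_config("degree must be 0, 1 or 2")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < degree + 2) stop_config("need at least degree + 2 points")
  k <- ceiling(span * n)
  if (k < degree + 1) stop_config("span * n too small for the degree")
  if (is.null(query_points)) {
    query_points <- seq(min(x), max(x), length.out = 100)
  }
  query_points <- sort(query_points)

  fitted <- vapply(query_points, function(q) {
    d <- abs(x - q)
    ord <- order(d, seq_along(d))
    kk <- k
    repeat {
      idx <- ord[seq_len(kk)]
      dmax <- d[ord[kk]]
      w <- if (dmax == 0) rep(1, kk) else {
        u <- pmin(d[idx] / dmax, 1)
        (1 - u^3)^3
      }
      if (any(w > 0) || kk == n) break
      kk <- kk + 1L
    }
    if (all(w == 0)) w <- rep(1, kk)   # all points coincide at dmax
    fit_window(x[idx], y[idx], w, q, degree)
  }, numeric(1))

  structure(list(query_points = query_points, fitted_values = fitted,
                 span = span, degree = degree, n_points = n),
            class = "loess_fit")
}

# Weighted polynomial fit in one window, evaluated at the query point.
# Falls back to a lower degree (with a warning) when the local design matrix
# is singular, e.g. fewer distinct x values than degree + 1.
fit_window <- function(xw, yw, w, q, degree) {
  pos <- w > 0
  xw <- xw[pos]; yw <- yw[pos]; w <- w[pos]
  for (deg in seq(degree, 0)) {
    if (length(unique(xw)) >= deg + 1) {
      X <- outer(xw - q, 0:deg, `^`)
      fit <- tryCatch(lm.wfit(X, yw, w), error = function(e) NULL)
      if (!is.null(fit) && !anyNA(fit$coefficients)) {
        if (deg < degree) {
          warning("singular local design; degree reduced to ", deg,
                  call. = FALSE)
        }
        return(unname(fit$coefficients[1]))
      }
    }
  }
  sum(w * yw) / sum(w)
}

#' @export
print.loess_fit <- function(x, ...) {
  cat(sprintf("loess_fit: span %.3g, degree %d, %d points, %d query points\n",
              x$span, x$degree, x$n_points, length(x$query_points)))
  invisible(x)
}

#' Expression kinetics along pseudotime, per gene and group
#'
#' For each (gene, group) pair, fits [loess_fit()] of expression (typically
#' log2 FPKM) against pseudotime on a shared query grid, the long-format
#' table behind kinetics line plots.
#'
#' @param x An `expression_matrix` (usually `"log2fpkm"`).
#' @param pseudotime A `pseudotime_assignment` (cells missing from it are
#'   ignored).
#' @param genes Character vector of gene ids to fit.
#' @param groups Named character vector: group label per cell id, or `NULL`
#'   for a single group `"all"`.
#' @param span,degree Passed to [loess_fit()].
#' @param n_query Grid size over [0, 1] (default 100).
#' @return Data.frame: `group`, `gene`, `query`, `fitted`.
#' @export
kinetics_table <- function(x, pseudotime, genes, groups = NULL,
                           span = 1/3, degree = 2, n_query = 100) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(pseudotime, "pseudotime_assignment"))
  missing_genes <- setdiff(genes, x$gene_ids)
  if (length(missing_genes)) {
    stop_config("genes not in matrix: ",
                paste(head(missing_genes, 5), collapse = ", "))
  }
  if (is.null(groups)) {
    groups <- setNames(rep("all", length(x$cell_ids)), x$cell_ids)
  }
  grid <- seq(0, 1, length.out = n_query)
  out <- list()
  for (g in sort(unique(groups))) {
    cells <- intersect(names(groups)[groups == g], pseudotime$cell_id)
    pt <- pseudotime$pseudotime[match(cells, pseudotime$cell_id)]
    # pseudotime is rank-normalized within the full cohort; re-grade within
    # the group so each group's own ordering spans [0, 1]
    if (length(cells) > 1) pt <- (rank(pt, ties.method = "first") - 1) /
        (length(cells) - 1)
    kmin <- ceiling(span * length(cells))
    if (length(cells) < degree + 2 || kmin < degree + 1) {
      warning("group '", g, "' smaller than the minimum window; skipped")
      next
    }
    sub <- x$values[match(genes, x$gene_ids), match(cells, x$cell_ids),
                    drop = FALSE]
    for (gi in seq_along(genes)) {
      fit <- loess_fit(pt, sub[gi, ], span = span, degree = degree,
                       query_points = grid)
      out[[length(out) + 1L]] <- data.frame(
        group = g, gene = genes[gi], query = grid,
        fitted = fit$fitted_values, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(group = character(), gene = character(),
                                      query = numeric(), fitted = numeric()))
  do.call(rbind, out)
}
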