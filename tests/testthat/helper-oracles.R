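# Independent oracles used by the tests. These deliberately share no code
# with the package implementation they check.

# Exhaustive simplex grid search for the constrained least-squares problem:
# minimises ||x - S f||^2 over f >= 0, sum(f) = 1 on a grid of step `step`.
grid_qp_oracle <- function(x, S, step = 0.01) {
  k <- ncol(S)
  stopifnot(k == 3)
  m <- round(1 / step)
  best <- Inf
  best_f <- NULL
  for (i in 0:m) {
    for (j in 0:(m - i)) {
      f <- c(i, j, m - i - j) / m
      obj <- sum((x - S %*% f)^2)
      if (obj < best) { best <- obj; best_f <- f }
    }
  }
  list(objective = best, fractions = best_f)
}

# KKT residual of a candidate solution of the same problem: the gradient
# 2 S'(S f - x) must be constant (= -lambda) on the support and no smaller
# than that constant on the zero set.
kkt_residual <- function(x, S, f, support_tol = 1e-10) {
  grad <- as.vector(2 * crossprod(S, S %*% f - x))
  supp <- f > support_tol
  mu <- mean(grad[supp])
  r_supp <- max(abs(grad[supp] - mu))
  r_zero <- if (any(!supp)) max(0, max(mu - grad[!supp])) else 0
  r_feas <- max(abs(sum(f) - 1), max(0, -min(f)))
  max(r_supp, r_zero, r_feas)
}

# One-shot weighted least squares at a single query point, with the same
# window convention the package documents (k nearest, tricube on d/d_max).
wls_loess_oracle <- function(x, y, span, degree, q) {
  n <- length(x)
  k <- ceiling(span * n)
  d <- abs(x - q)
  ord <- order(d, seq_along(d))
  idx <- ord[seq_len(k)]
  dmax <- d[ord[k]]
  u <- pmin(d[idx] / dmax, 1)
  w <- (1 - u^3)^3
  keep <- w > 0
  X <- outer(x[idx][keep] - q, 0:degree, `^`)
  W <- diag(w[keep])
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y[idx][keep])
  beta[1]
}

# Brute-force agglomerative clustering: at every step recompute all
# inter-cluster distances from the raw pairwise matrix under the given
# criterion and merge the closest pair. Returns merge partitions and heights.
brute_force_agglomeration <- function(M, linkage = c("average", "ward_d2")) {
  linkage <- match.arg(linkage)
  n <- nrow(M)
  D <- as.matrix(dist(M))
  clusters <- as.list(seq_len(n))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- clusters[[i]]; b <- clusters[[j]]
        d <- if (linkage == "average") {
          mean(D[a, b])
        } else {
          # Ward.D2: sqrt of the increase-in-SS criterion, computed from
          # centroids and sizes (2 * na*nb/(na+nb) * ||ca - cb||^2)
          ca <- colMeans(M[a, , drop = FALSE])
          cb <- colMeans(M[b, , drop = FALSE])
          sqrt(2 * length(a) * length(b) / (length(a) + length(b)) *
                 sum((ca - cb)^2))
        }
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    merges[[length(merges) + 1L]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  list(partitions = merges, heights = heights)
}

# Lance-Williams recomputation of Ward.D2 heights: squared-distance updates,
# heights reported as square roots of the merge criterion.
lance_williams_ward2 <- function(M) {
  n <- nrow(M)
  D2 <- as.matrix(dist(M))^2
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (D2[i, j] < best) { best <- D2[i, j]; bi <- i; bj <- j }
    }
    heights <- c(heights, sqrt(best))
    ni <- size[bi]; nj <- size[bj]
    for (k in setdiff(active, c(bi, bj))) {
      nk <- size[k]
      D2[bi, k] <- D2[k, bi] <-
        ((ni + nk) * D2[bi, k] + (nj + nk) * D2[bj, k] - nk * D2[bi, bj]) /
        (ni + nj + nk)
    }
    size[bi] <- ni + nj
    active <- setdiff(active, bj)
  }
  heights
}

# Convert hclust merges to leaf partitions for comparison with brute force.
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", n - 1)
  out <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    get <- function(v) if (v < 0) -v else members[[v]]
    members[[s]] <- c(get(hc$merge[s, 1]), get(hc$merge[s, 2]))
    out[[s]] <- sort(members[[s]])
  }
  out
}

# Small expression matrix fixture with known lengths/totals.
tiny_counts <- function(n_genes = 30, n_cells = 8, seed = 42) {
  set.seed(seed)
  vals <- matrix(rpois(n_genes * n_cells, 20), n_genes)
  expression_matrix(vals,
                    gene_ids = sprintf("g%03d", seq_len(n_genes)),
                    cell_ids = sprintf("c%02d", seq_len(n_cells)),
                    gene_length_bp = sample(500:5000, n_genes, replace = TRUE),
                    mapped_total = sample(6e5:2e6, n_cells),
                    unit = "counts")
}
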