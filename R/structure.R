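# Population-structure analyses: PCA on variable genes, hierarchical
# clustering in the two linkage dialects used for expression data (Ward.D2
# and average, both on Euclidean distances), k-means with elbow selection,
# Venn partitioning of DE gene lists, and a rank-sum DE caller.

#' PCA of cells on a gene subset
#'
#' Cells are observations, genes are features. Centering and unit-variance
#' scaling are on by default; zero-variance genes are dropped with a warning
#' when scaling. Component signs are fixed deterministically: the
#' largest-magnitude entry of each loading column is made positive.
#'
#' @param x An `expression_matrix` (typically `"log2fpkm"`).
#' @param genes Optional gene-id subset.
#' @param center,scale Logical (defaults `TRUE`).
#' @return A `pca_result`: `scores` (cells x m), `loadings` (genes x m),
#'   `explained` (variance fractions, non-increasing), `center`, `scale`.
#' @export
pca_cells <- function(x, genes = NULL, center = TRUE, scale = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  check_flag(center, "center"); check_flag(scale, "scale")
  if (!is.null(genes)) x <- subset_matrix(x, genes = genes)
  if (nrow(x$values) < 2 || ncol(x$values) < 2) {
    stop_config("need >= 2 genes and >= 2 cells after subsetting")
  }
  M <- t(x$values)                     # cells x genes
  if (scale) {
    v <- apply(M, 2, var)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance genes dropped before scaling")
      M <- M[, v > 0, drop = FALSE]
      if (ncol(M) < 2) stop_config("fewer than 2 genes with variance")
    }
  }
  p <- prcomp(M, center = center, scale. = scale)
  flip <- apply(p$rotation, 2, function(col) {
    sign(col[which.max(abs(col))])
  })
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, `*`)
  loadings <- sweep(p$rotation, 2, flip, `*`)
  rownames(scores) <- x$cell_ids
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings, explained = expl,
                 center = center, scale = scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d cells, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * x$explained[1],
              100 * x$explained[2]))
  invisible(x)
}

#' Hierarchical clustering of samples on Euclidean distances
#'
#' Agglomerative clustering with either the Ward.D2 criterion (squared
#' Euclidean Lance-Williams updates, heights reported on the distance scale)
#' or average linkage (UPGMA) — the two dialects used for expression data.
#'
#' @param x An `expression_matrix` (samples = columns are clustered) or a
#'   numeric samples x features matrix.
#' @param linkage `"ward_d2"` or `"average"` (explicit; no default).
#' @return A `fate_dendrogram`: list wrapping the `hclust` object with the
#'   linkage and metric recorded.
#' @export
hierarchical_cluster <- function(x, linkage = c("ward_d2", "average")) {
  linkage <- match.arg(linkage)
  M <- if (inherits(x, "expression_matrix")) t(x$values) else as.matrix(x)
  if (nrow(M) < 2) stop_config("need at least 2 samples")
  if (anyNA(M)) stop_config("NaN/NA in input")
  hc <- hclust(dist(M, method = "euclidean"),
               method = c(ward_d2 = "ward.D2", average = "average")[linkage])
  structure(list(hclust = hc, linkage = linkage, metric = "euclidean",
                 labels = rownames(M)),
            class = "fate_dendrogram")
}

#' @export
print.fate_dendrogram <- function(x, ...) {
  cat(sprintf("fate_dendrogram: %d leaves, %s linkage, %s metric\n",
              length(x$hclust$order), x$linkage, x$metric))
  invisible(x)
}

#' Export a dendrogram as a Newick string or file
#'
#' @param dend A `fate_dendrogram`.
#' @param path Optional file to write; when `NULL` the string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
as_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "fate_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_centers <- function(M, k) {
  n <- nrow(M)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((M - M[rep(centers[1], n), , drop = FALSE])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      centers[j + 1] <- sample.int(n, 1)
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    dn <- rowSums((M - M[rep(centers[j + 1], n), , drop = FALSE])^2)
    d2 <- pmin(d2, dn)
  }
  M[centers, , drop = FALSE]
}

#' k-means clustering with elbow selection of k
#'
#' For each k in `k_min..k_max`, runs Lloyd's algorithm from k-means++
#' initializations, keeping the best of `n_restarts` runs by within-cluster
#' sum of squares (WCSS). The elbow is formalized as the interior k
#' maximizing the second difference `WCSS(k-1) - 2 WCSS(k) + WCSS(k+1)`.
#' Deterministic given the seed.
#'
#' @param x An `expression_matrix` (cells clustered) or samples x features
#'   matrix.
#' @param k_min,k_max Range of k (k_min >= 2; k_max < n samples, and
#'   `k_max >= k_min + 2` so an interior k exists).
#' @param n_restarts Restarts per k (default 10).
#' @param seed Integer seed.
#' @return A `kmeans_elbow` list: `k` (chosen), `assignments` (for chosen k),
#'   `wcss` (named vector over the k range).
#' @export
kmeans_elbow <- function(x, k_min = 2, k_max = 8, n_restarts = 10, seed = 1L) {
  M <- if (inherits(x, "expression_matrix")) t(x$values) else as.matrix(x)
  if (k_min < 2) stop_config("k_min must be >= 2")
  if (k_max >= nrow(M)) stop_config("k_max must be < number of samples")
  if (k_max < k_min + 2) stop_config("need k_max >= k_min + 2 for an elbow")
  set.seed(derive_seed(seed, "kmeans_elbow"))
  ks <- k_min:k_max
  wcss <- setNames(numeric(length(ks)), ks)
  best_fit <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    best <- Inf
    for (r in seq_len(n_restarts)) {
      fit <- suppressWarnings(
        kmeans(M, centers = kmeanspp_centers(M, ks[i]),
               iter.max = 100, algorithm = "Lloyd"))
      if (fit$tot.withinss < best) {
        best <- fit$tot.withinss
        best_fit[[i]] <- fit
      }
    }
    wcss[i] <- best
  }
  interior <- seq(2, length(ks) - 1)
  second_diff <- wcss[interior - 1] - 2 * wcss[interior] + wcss[interior + 1]
  chosen <- ks[interior][which.max(second_diff)]
  structure(list(k = chosen,
                 assignments = best_fit[[match(chosen, ks)]]$cluster,
                 wcss = wcss),
            class = "kmeans_elbow")
}

#' @export
print.kmeans_elbow <- function(x, ...) {
  cat(sprintf("kmeans_elbow: chose k = %d over k in %s..%s\n", x$k,
              names(x$wcss)[1], names(x$wcss)[length(x$wcss)]))
  invisible(x)
}

#' Venn-region partition of DE gene lists
#'
#' Given one DE gene list per driver, computes the exact membership of all
#' 2^k - 1 non-empty intersection regions — the "unique and shared" counts.
#' Duplicates within a list and list order are irrelevant.
#'
#' @param lists Named list (>= 2) of character gene vectors.
#' @return A `de_partition`: `regions` (data.frame: region key like
#'   `"A&B"`, count), `unique_counts` (per driver), `shared_all` (count in
#'   every list), `union_size`, `membership` (named character: gene ->
#'   region key).
#' @export
de_partition <- function(lists) {
  if (!is.list(lists) || length(lists) < 2) stop_config("need >= 2 DE lists")
  if (is.null(names(lists)) || any(names(lists) == "")) {
    names(lists) <- paste0("set", seq_along(lists))
  }
  lists <- lapply(lists, unique)
  all_genes <- sort(unique(unlist(lists, use.names = FALSE)))
  member <- vapply(lists, function(l) all_genes %in% l,
                   logical(length(all_genes)))
  if (length(all_genes) == 1) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL,
                                                               names(lists)))
  key <- apply(member, 1, function(row) {
    paste(names(lists)[row], collapse = "&")
  })
  names(key) <- all_genes
  counts <- table(key)
  regions <- data.frame(region = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  unique_counts <- setNames(
    vapply(names(lists), function(nm) sum(key == nm), integer(1)),
    names(lists))
  shared_all <- sum(key == paste(names(lists), collapse = "&"))
  structure(list(regions = regions, unique_counts = unique_counts,
                 shared_all = shared_all, union_size = length(all_genes),
                 membership = key),
            class = "de_partition")
}

#' @export
print.de_partition <- function(x, ...) {
  cat(sprintf("de_partition: union %d genes, %d non-empty regions; %d shared by all\n",
              x$union_size, nrow(x$regions), x$shared_all))
  invisible(x)
}

#' Rank-sum differential expression between two cell groups
#'
#' A two-sided Wilcoxon rank-sum test per gene with Benjamini-Hochberg
#' adjustment — a distribution-free DE caller for count or FPKM data. This is
#' the package's own DE step; per-cell error-model methods are out of scope.
#'
#' @param x An `expression_matrix`.
#' @param group_a,group_b Cell-id vectors, each >= 3 cells.
#' @param fdr_threshold BH-adjusted significance cutoff (default 0.05).
#' @param pseudocount Offset for the reported log2 fold change (default 1).
#' @return Data.frame (one row per gene, all genes): `gene_id`, `p_value`,
#'   `p_adjusted`, `log2_fold_change` (A over B), `significant`.
#' @export
rank_sum_de <- function(x, group_a, group_b, fdr_threshold = 0.05,
                        pseudocount = 1) {
  stopifnot(inherits(x, "expression_matrix"))
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop_config("both groups need >= 3 cells")
  }
  A <- subset_matrix(x, cells = group_a)$values
  B <- subset_matrix(x, cells = group_b)$values
  p <- vapply(seq_len(nrow(A)), function(i) {
    a <- A[i, ]; b <- B[i, ]
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  padj <- p.adjust(p, method = "BH")
  lfc <- log2(rowMeans(A) + pseudocount) - log2(rowMeans(B) + pseudocount)
  data.frame(gene_id = x$gene_ids, p_value = p, p_adjusted = padj,
             log2_fold_change = lfc,
             significant = padj < fdr_threshold,
             stringsAsFactors = FALSE)
}
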