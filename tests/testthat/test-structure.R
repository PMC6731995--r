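# PCA, hierarchical clustering, k-means elbow, DE partitioning, rank-sum DE.

test_that("PCA matches the covariance eigendecomposition and fixes signs", {
  set.seed(2)
  vals <- matrix(runif(30 * 100, 0, 10), 100, 30)    # 100 genes x 30 cells
  m <- expression_matrix(vals, sprintf("g%03d", 1:100),
                         sprintf("c%02d", 1:30), unit = "log2fpkm")
  p <- pca_cells(m, center = TRUE, scale = FALSE)
  M <- scale(t(vals), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(M), symmetric = TRUE)$values
  expect_equal(p$explained[1:29], (ev / sum(ev))[1:29], tolerance = 1e-8)
  # reconstruction: scores %*% t(loadings) gives back the centered matrix
  expect_equal(p$scores %*% t(p$loadings), M, tolerance = 1e-8,
               ignore_attr = TRUE)
  # explained fractions sum to 1 and are non-increasing
  expect_equal(sum(p$explained), 1)
  expect_true(all(diff(p$explained) < 1e-12))
  # sign convention: largest-magnitude loading entry is positive
  expect_true(all(apply(p$loadings, 2,
                        function(col) col[which.max(abs(col))] > 0)))
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("collinear cells put all variance on PC1", {
  vals <- rbind(seq(1, 5), 2 * seq(1, 5))             # 2 genes, on a line
  m <- expression_matrix(vals, c("g1", "g2"), sprintf("c%d", 1:5),
                         unit = "log2fpkm")
  p <- pca_cells(m, scale = FALSE)
  expect_equal(p$explained[1], 1)
  # zero-variance gene dropped with a warning when scaling
  vals2 <- rbind(vals, 3)
  m2 <- expression_matrix(vals2, c("g1", "g2", "flat"), sprintf("c%d", 1:5),
                          unit = "log2fpkm")
  expect_warning(pca_cells(m2, scale = TRUE), "zero-variance")
})

test_that("average-linkage merges equal brute-force agglomeration", {
  set.seed(10)
  for (trial in 1:20) {
    n <- sample(4:8, 1)
    M <- matrix(rnorm(n * 5), n)
    rownames(M) <- sprintf("s%d", seq_len(n))
    dend <- hierarchical_cluster(M, "average")
    oracle <- brute_force_agglomeration(M, "average")
    expect_equal(hclust_partitions(dend$hclust), oracle$partitions)
    expect_equal(dend$hclust$height, oracle$heights, tolerance = 1e-10)
    # average-linkage heights bounded by the pairwise distance range
    D <- dist(M)
    expect_true(all(dend$hclust$height >= min(D) - 1e-12))
    expect_true(all(dend$hclust$height <= max(D) + 1e-12))
  }
})

test_that("Ward.D2 heights match the Lance-Williams recomputation", {
  set.seed(11)
  for (trial in 1:20) {
    n <- sample(5:9, 1)
    M <- matrix(rnorm(n * 4), n)
    dend <- hierarchical_cluster(M, "ward_d2")
    expect_equal(dend$hclust$height, lance_williams_ward2(M),
                 tolerance = 1e-10)
  }
  # two identical points merge at height zero; closest pair merges first
  M <- rbind(c(0, 0), c(0, 0), c(10, 0))
  d0 <- hierarchical_cluster(M, "ward_d2")
  expect_equal(d0$hclust$height[1], 0)
  M3 <- rbind(a = c(0, 0), b = c(1, 0), c = c(3, 0))  # distances 1, 2, 3
  d3 <- hierarchical_cluster(M3, "average")
  expect_equal(sort(hclust_partitions(d3$hclust)[[1]]), c(1, 2))
  expect_error(hierarchical_cluster(rbind(c(1, NA), c(0, 1)), "average"),
               "NaN|NA")
})

test_that("dendrograms export as valid Newick", {
  set.seed(12)
  M <- matrix(rnorm(12), 6)
  rownames(M) <- sprintf("leaf%d", 1:6)
  dend <- hierarchical_cluster(M, "average")
  nwk <- as_newick(dend)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(M))
})

test_that("k-means elbow finds three well-separated blobs deterministically", {
  set.seed(13)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  M <- centers[rep(1:3, each = 100), ] + matrix(rnorm(600, 0, 0.1), 300)
  km1 <- kmeans_elbow(M, k_min = 2, k_max = 6, n_restarts = 5, seed = 99)
  km2 <- kmeans_elbow(M, k_min = 2, k_max = 6, n_restarts = 5, seed = 99)
  expect_equal(km1$k, 3)
  expect_identical(km1, km2)
  # WCSS non-increasing in k
  expect_true(all(diff(km1$wcss) <= 1e-8))
  # duplicated rows always co-assigned
  expect_equal(km1$assignments[1], km1$assignments[2])
  expect_error(kmeans_elbow(M, k_min = 1), "k_min")
})

test_that("DE partition enumerates Venn regions exactly", {
  p <- de_partition(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                         C = "c"))
  expect_equal(unname(p$unique_counts), c(1L, 1L, 0L))
  expect_equal(p$shared_all, 1L)
  expect_equal(p$union_size, 4L)
  expect_equal(sum(p$regions$count), p$union_size)
  same <- de_partition(list(X = c("a", "b"), Y = c("b", "a", "a")))
  expect_equal(same$shared_all, 2L)
  expect_equal(nrow(same$regions), 1L)
})

test_that("partition counts sum to the union on random triples", {
  set.seed(14)
  pool <- sprintf("g%03d", 1:60)
  for (trial in 1:100) {
    lists <- lapply(1:3, function(i) sample(pool, sample(5:30, 1)))
    names(lists) <- c("A", "B", "C")
    p <- de_partition(lists)
    expect_equal(sum(p$regions$count), length(unique(unlist(lists))))
    # invariant to list order and duplicates
    p2 <- de_partition(rev(lapply(lists, rep, 2)))
    expect_equal(sum(p2$regions$count), sum(p$regions$count))
    expect_equal(sort(unname(p2$unique_counts)),
                 sort(unname(p$unique_counts)))
  }
})

test_that("rank-sum DE detects a shifted gene and behaves under identity", {
  set.seed(15)
  n <- 50
  vals <- matrix(rpois(100 * 2 * n, 20), 100)
  vals[1, 1:n] <- rpois(n, 200)                      # 10x shift in group A
  m <- expression_matrix(vals, sprintf("g%03d", 1:100),
                         sprintf("c%03d", 1:(2 * n)), unit = "fpkm")
  a <- m$cell_ids[1:n]; b <- m$cell_ids[(n + 1):(2 * n)]
  de <- rank_sum_de(m, a, b)
  expect_true(de$significant[1])
  expect_gt(de$log2_fold_change[1], 2)
  # identical groups: nothing is called
  de_same <- rank_sum_de(m, a, a)
  expect_false(any(de_same$significant))
  # BH monotone: raising the threshold never removes genes
  lo <- de$gene_id[de$p_adjusted < 0.01]
  hi <- de$gene_id[de$p_adjusted < 0.1]
  expect_true(all(lo %in% hi))
  expect_error(rank_sum_de(m, a[1:2], b), "3 cells")
})
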