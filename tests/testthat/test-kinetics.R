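# Local regression of expression against pseudotime, gates and IF counts.

test_that("local regression reproduces polynomials exactly", {
  set.seed(3)
  x <- sort(runif(60))
  q <- seq(0.1, 0.9, length.out = 25)
  lin <- loess_fit(x, 2 * x + 1, span = 1/3, degree = 2, query_points = q)
  expect_lt(max(abs(lin$fitted_values - (2 * q + 1))), 1e-8)
  lin2 <- loess_fit(x, 2 * x + 1, span = 0.8, degree = 1, query_points = q)
  expect_lt(max(abs(lin2$fitted_values - (2 * q + 1))), 1e-8)
  quad <- loess_fit(x, x^2, span = 1/3, degree = 2, query_points = q)
  expect_lt(max(abs(quad$fitted_values - q^2)), 1e-8)
})

test_that("noisy single-query fit equals the one-shot WLS oracle", {
  set.seed(9)
  for (trial in 1:10) {
    x <- runif(45)
    y <- sin(3 * x) + rnorm(45, 0, 0.2)
    q <- runif(1, 0.2, 0.8)
    for (degree in 0:2) {
      fit <- loess_fit(x, y, span = 1/3, degree = degree, query_points = q)
      expect_equal(fit$fitted_values,
                   wls_loess_oracle(x, y, 1/3, degree, q),
                   tolerance = 1e-10)
    }
  }
})

test_that("span 1 / degree 1 equals global OLS on linear data", {
  set.seed(4)
  x <- runif(50)
  y <- -1.3 * x + 0.7
  q <- seq(0, 1, length.out = 20)
  fit <- loess_fit(x, y, span = 1, degree = 1, query_points = q)
  ols <- lm(y ~ x)
  expect_lt(max(abs(fit$fitted_values - predict(ols,
                                                data.frame(x = q)))), 1e-8)
})

test_that("fitted values are invariant to point order and flat for constants", {
  set.seed(6)
  x <- runif(40); y <- cos(2 * x) + rnorm(40, 0, 0.1)
  q <- seq(0.1, 0.9, length.out = 15)
  f1 <- loess_fit(x, y, query_points = q)
  p <- sample(40)
  f2 <- loess_fit(x[p], y[p], query_points = q)
  expect_equal(f1$fitted_values, f2$fitted_values, tolerance = 1e-12)
  fc <- loess_fit(x, rep(3.5, 40), query_points = q)
  expect_lt(max(abs(fc$fitted_values - 3.5)), 1e-10)
  # approximate agreement with the reference local-regression implementation
  sl <- stats::loess(y ~ x, span = 1/3, degree = 2, surface = "direct")
  ours <- loess_fit(x, y, span = 1/3, degree = 2, query_points = x)
  expect_lt(max(abs(ours$fitted_values - predict(sl, sort(x)))), 0.2)
})

test_that("kinetics table recovers activation of a destination marker", {
  gm <- gene_universe(400, 20, seed = 41)
  sigs <- build_signatures(gm, default_states(), seed = 41)
  rc <- route_config("direct", n_cells = 200, seed = 41)
  sim <- simulate_cells(sigs, rc, gm)
  fpkm <- compute_fpkm(sim$matrix)
  pr <- fractional_identity(fpkm, sigs)
  pt <- assign_pseudotime(pr)
  lg <- log2_transform(fpkm)
  dest_gene <- gm$gene_id[gm$module == "destination_marker"][1]
  orig_gene <- gm$gene_id[gm$module == "origin_marker"][1]
  kin <- kinetics_table(lg, pt, c(dest_gene, orig_gene))
  act <- kin[kin$gene == dest_gene, ]
  expect_gt(act$fitted[act$query == 1], act$fitted[act$query == 0])
  sil <- kin[kin$gene == orig_gene, ]
  expect_lt(sil$fitted[sil$query == 1], sil$fitted[sil$query == 0])
  # two groups holding the same cells give identical curves
  k_g1 <- kinetics_table(lg, pt, dest_gene,
                         setNames(rep("g1", length(lg$cell_ids)),
                                  lg$cell_ids))
  k_g2 <- kinetics_table(lg, pt, dest_gene,
                         setNames(rep("g2", length(lg$cell_ids)),
                                  lg$cell_ids))
  expect_equal(k_g1$fitted, k_g2$fitted)
  # constant gene: flat line at the constant
  lg2 <- lg
  lg2$values[1, ] <- 2
  kin2 <- kinetics_table(lg2, pt, lg$gene_ids[1])
  expect_lt(max(abs(kin2$fitted - 2)), 1e-10)
})

test_that("co-expression gate partitions cells exhaustively", {
  v <- rbind(A = c(5, 5, 0, 0, 3), B = c(5, 0, 5, 0, 0.5))
  m <- expression_matrix(v, c("A", "B"), sprintf("c%d", 1:5),
                         unit = "log2fpkm")
  g <- co_expression_gate(m, "A", "B", 1, 1)
  expect_equal(as.character(g$classification),
               c("double_positive", "A_only", "B_only", "double_negative",
                 "A_only"))
  expect_equal(sum(g$counts), 5)
  g_hi <- co_expression_gate(m, "A", "B", 100, 100)
  expect_true(all(g_hi$classification == "double_negative"))
  expect_error(co_expression_gate(m, "A", "nope"), "nope")
})

test_that("mid-trajectory ICM-detour cells are double positive more often", {
  gm <- gene_universe(400, 20, seed = 51)
  sigs <- build_signatures(gm, default_states(), seed = 51)
  rc <- route_config("icm_route", n_cells = 300, detour_signature = "icm",
                     detour_amplitude = 0.3, seed = 51)
  sim <- simulate_cells(sigs, rc, gm)
  lg <- log2_transform(compute_fpkm(sim$matrix))
  # one destination marker (naive, Nanog-like), one ICM marker (Gata6-like)
  ga <- gm$gene_id[gm$module == "destination_marker"][1]
  gb <- gm$gene_id[gm$module == "icm_marker"][1]
  t <- sim$truth$t_true
  dp_rate <- function(cells) {
    g <- co_expression_gate(subset_matrix(lg, cells = cells), ga, gb, 3, 3)
    mean(g$classification == "double_positive")
  }
  mid <- sim$truth$cell_id[t > 0.35 & t < 0.65]
  start <- sim$truth$cell_id[t < 0.2]
  end <- sim$truth$cell_id[t > 0.8]
  expect_gt(dp_rate(mid), dp_rate(start))
  expect_gt(dp_rate(mid), dp_rate(end))
})

test_that("IF positivity uses the control mean + 2 SD threshold", {
  q <- if_percent_positive(c(15, 13, 16, 9), c(8, 10, 12))
  expect_equal(q$threshold, 14)
  expect_equal(q$n_positive, 2L)
  expect_equal(q$percent_positive, 50)
  expect_error(if_percent_positive(c(1, 2), 5), "control")
  none <- if_percent_positive(c(1, 2, 3), c(8, 10, 12))
  expect_equal(none$percent_positive, 0)
  # affine invariance: a*x + b on both tables leaves the call unchanged
  set.seed(12)
  ctrl <- rnorm(500, 10, 2); tst <- rnorm(500, 14, 3)
  q1 <- if_percent_positive(tst, ctrl)
  q2 <- if_percent_positive(3 * tst + 5, 3 * ctrl + 5)
  expect_equal(q1$percent_positive, q2$percent_positive)
})

test_that("a normal test population identical to control has ~2.3% positives", {
  set.seed(77)
  ctrl <- rnorm(1e5)
  tst <- rnorm(1e5)
  q <- if_percent_positive(tst, ctrl)
  expect_lt(abs(q$percent_positive - 2.275), 0.3)
})
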