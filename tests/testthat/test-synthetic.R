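# Synthetic generator: construction guarantees, seeded determinism, and the
# distributional contracts downstream recovery relies on.

test_that("signatures elevate markers in their state and are seed-stable", {
  gm <- gene_universe(300, 20, seed = 7)
  sigs <- build_signatures(gm, default_states(), fold_high = 10,
                           noise_sd = 0, seed = 7)
  origin_markers <- gm$gene_id[gm$module == "origin_marker"]
  i <- match(origin_markers, sigs$gene_ids)
  expect_equal(sigs$profiles[i, "origin"],
               setNames(10 * gm$baseline_expression[match(origin_markers,
                                                          gm$gene_id)],
                        origin_markers))
  expect_equal(sigs$profiles[i, "destination"],
               setNames(gm$baseline_expression[match(origin_markers,
                                                     gm$gene_id)],
                        origin_markers))
  sigs2 <- build_signatures(gm, default_states(), fold_high = 10,
                            noise_sd = 0, seed = 7)
  expect_identical(sigs, sigs2)
  expect_error(build_signatures(gm, list(one = "origin_marker")),
               "at least 2")
})

test_that("five-state signature sets have all pairwise correlations < 1", {
  gm <- gene_universe(500, 25, seed = 11)
  states <- c(default_states(),
              list(morula = c("icm_marker", "mesoderm_marker")))
  sigs <- build_signatures(gm, states, seed = 11)
  cc <- cor(sigs$profiles)
  off_diag <- cc[upper.tri(cc)]
  expect_true(all(off_diag < 1))
})

test_that("mixing fractions lie on the simplex and detour-free routes are pure interpolations", {
  gm <- gene_universe(300, 20, seed = 5)
  sigs <- build_signatures(gm, default_states(), seed = 5)
  for (amp in c(0, 0.3)) {
    rc <- route_config("r", n_cells = 150,
                       detour_signature = if (amp > 0) "mesoderm" else NULL,
                       detour_amplitude = amp, seed = 5)
    sim <- simulate_cells(sigs, rc, gm)
    fr <- as.matrix(sim$truth[, paste0("frac_", sigs$names)])
    expect_true(all(fr >= 0))
    expect_true(all(abs(rowSums(fr) - 1) < 1e-12))
    if (amp == 0) {
      expect_true(all(fr[, c("frac_mesoderm", "frac_icm")] == 0))
      expect_equal(sim$truth$detour_weight, rep(0, 150))
    } else {
      expect_gt(max(fr[, "frac_mesoderm"]), 0.2)
    }
  }
})

test_that("simulate_cells is seed-reproducible and endpoint cells match the origin signature", {
  gm <- gene_universe(300, 20, seed = 9)
  sigs <- build_signatures(gm, default_states(), seed = 9)
  rc <- route_config("r", n_cells = 40, seed = 9)
  s1 <- simulate_cells(sigs, rc, gm)
  s2 <- simulate_cells(sigs, rc, gm)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth, s2$truth)

  # noiseless endpoint: expected counts of a t = 0, no-dropout, Poisson-free
  # cell equal the origin signature converted to counts at its library size
  rc0 <- route_config("r0", n_cells = 500, nb_dispersion = 0,
                      t_alpha = 1e-6, t_beta = 1e6, depth_mean = 1e7,
                      seed = 2)
  s0 <- simulate_cells(sigs, rc0, gm)
  mu_expect <- sigs$profiles[, "origin"] * (gm$length_bp / 1000)
  # per-cell scaling by library size; compare mean observed/expected ratio
  obs <- rowMeans(sweep(s0$matrix$values, 2, s0$truth$library_size / 1e6,
                        `/`))
  expect_lt(max(abs(obs - mu_expect) / pmax(mu_expect, 1)), 0.1)
})

test_that("negative binomial parameterization gives variance mu + phi mu^2", {
  set.seed(1)
  # a single gene at mu = 50, phi = 0.1, through the generator's count layer
  gm <- gene_universe(300, 20, seed = 13)
  gm$length_bp[] <- 1000
  gm$baseline_expression[] <- 50
  sigs <- build_signatures(gm, default_states(), fold_high = 1, noise_sd = 0,
                           seed = 13)
  rc <- route_config("r", n_cells = 2000, nb_dispersion = 0.1,
                     depth_mean = 1e6, seed = 13)
  sim <- simulate_cells(sigs, rc, gm)
  draws <- sim$matrix$values[1, ]            # raw counts of one gene
  mu_i <- 50 * sim$truth$library_size / 1e6  # its per-cell NB mean
  # standardized residual variance: var((x - mu)/sqrt(mu + phi mu^2)) ~ 1
  z <- (draws - mu_i) / sqrt(mu_i + 0.1 * mu_i^2)
  expect_lt(abs(var(z) - 1), 0.15)
})

test_that("expected total counts scale linearly with library size", {
  gm <- gene_universe(200, 10, seed = 21)
  sigs <- build_signatures(gm, default_states(), seed = 21)
  rc <- route_config("r", n_cells = 500, seed = 21)
  sim <- simulate_cells(sigs, rc, gm)
  totals <- colSums(sim$matrix$values)
  fit <- lm(totals ~ sim$truth$library_size + 0)
  # analytic slope: average over cells of sum_g fpkm_g * len_kb_g / 1e6
  fr <- as.matrix(sim$truth[, paste0("frac_", sigs$names)])
  mu_fpkm <- sigs$profiles %*% t(fr)
  slope_true <- mean(colSums(mu_fpkm * (gm$length_bp / 1000)) / 1e6)
  expect_lt(abs(coef(fit)[1] - slope_true) / slope_true, 0.05)
})

test_that("coverage simulation matches its exponential-bias expectation", {
  mat <- tiny_counts(n_genes = 50, n_cells = 3)
  mat$values <- matrix(1000, 50, 3,
                       dimnames = dimnames(mat$values)) # plenty of reads
  cov0 <- simulate_coverage(mat, bias_strength = 0, n_bins = 100, seed = 1)
  r0 <- bias_ratio(cov0, n_bins = 100)
  expect_true(all(abs(r0$bias_ratio - 51 / 49) < 0.15))

  # choose bias so the analytic 3'/5' ratio is 3 and check within 10%
  bins <- 1:100
  ratio_of <- function(b) {
    p <- exp(b * bins / 100)
    sum(p[bins > 49]) / sum(p[bins <= 49])
  }
  b3 <- uniroot(function(b) ratio_of(b) - 3, c(0.1, 10))$root
  cov3 <- simulate_coverage(mat, bias_strength = b3, n_bins = 100, seed = 1)
  r3 <- bias_ratio(cov3, n_bins = 100, max_ratio = 10)
  expect_true(all(abs(r3$bias_ratio - 3) / 3 < 0.1))

  # zero-read library flagged undefined downstream
  mat0 <- mat
  mat0$values[, 2] <- 0
  covz <- simulate_coverage(mat0, bias_strength = 0, n_bins = 100, seed = 1)
  rz <- bias_ratio(covz, n_bins = 100)
  expect_true(is.na(rz$bias_ratio[rz$library == mat$cell_ids[2]]))
  expect_false(rz$pass_bias[rz$library == mat$cell_ids[2]])
  expect_error(simulate_coverage(mat, n_bins = 1), "n_bins")
})

test_that("IF intensity fixtures are seeded and respect frac_positive", {
  a <- simulate_if_intensities(500, 500, 0.25, seed = 3)
  b <- simulate_if_intensities(500, 500, 0.25, seed = 3)
  expect_identical(a, b)
  expect_equal(mean(a$test$true_positive), 0.25, tolerance = 0.2)
  z <- simulate_if_intensities(2000, 2000, 0, seed = 4)
  expect_false(any(z$test$true_positive))
  # frac_positive = 0: test and control from the same distribution
  expect_lt(abs(median(z$test$intensity) - median(z$control$intensity)),
            0.1 * median(z$control$intensity))
})
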