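# Synthetic reprogramming-data generator.
#
# Emulates what the real experiment measures: an origin population (primed
# EpiSC-like), a destination population (naive PSC-like), asynchronous
# intermediates interpolating between them, and route-specific transient
# detours through a third signature (mesoderm-like or early-ICM-like).
# Every cell carries full generative ground truth so downstream recovery is
# testable without any deposited data.

#' Build a default gene universe
#'
#' Genes belong to one of five modules: markers of the origin state, of the
#' destination state, of the two detour signatures (mesoderm-like and
#' ICM-like), and housekeeping genes expressed everywhere. Baseline ("off")
#' expression and transcript lengths are drawn once, deterministically under
#' the seed.
#'
#' @param n_genes Total genes (default 2000).
#' @param n_markers_per_module Marker genes per non-housekeeping module
#'   (default 50).
#' @param seed Integer seed.
#' @return A data.frame with columns `gene_id`, `length_bp`, `module`,
#'   `baseline_expression` (expected FPKM in the module's off state).
#' @export
gene_universe <- function(n_genes = 2000, n_markers_per_module = 50,
                          seed = 1L) {
  check_scalar_number(n_genes, "n_genes", lower = 1)
  check_scalar_number(n_markers_per_module, "n_markers_per_module", lower = 1)
  modules <- c("origin_marker", "destination_marker", "mesoderm_marker",
               "icm_marker")
  n_marked <- length(modules) * n_markers_per_module
  if (n_marked >= n_genes) {
    stop_config("need n_genes > ", n_marked, " to leave room for housekeeping")
  }
  set.seed(derive_seed(seed, "gene_universe"))
  module <- c(rep(modules, each = n_markers_per_module),
              rep("housekeeping", n_genes - n_marked))
  data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    length_bp = pmax(100L, as.integer(round(rlnorm(n_genes, log(2000), 0.5)))),
    module = module,
    baseline_expression = round(rlnorm(n_genes, log(5), 1), 4),
    stringsAsFactors = FALSE
  )
}

#' Construct signature transcriptomes for a set of states
#'
#' Each state gets a mean-FPKM profile over the full gene universe: marker
#' genes of the modules assigned "high" in that state are elevated
#' `fold_high`-fold over baseline; everything else sits at baseline. A small
#' lognormal wobble (sd `noise_sd` on the log scale) makes profiles of
#' different states less than perfectly correlated, as real bulk signatures
#' are.
#'
#' @param gene_models Data.frame from [gene_universe()].
#' @param states Named list: state name -> character vector of marker modules
#'   that are high in that state (may be empty). At least 2 states.
#' @param fold_high Fold elevation of a high marker over its baseline
#'   (default 10).
#' @param noise_sd Lognormal sd of the per-state wobble (default 0.1).
#' @param seed Integer seed; same seed gives a bit-identical set.
#' @return A `signature_set`: list with `profiles` (genes x states matrix of
#'   mean FPKM), `gene_ids`, `names`.
#' @export
build_signatures <- function(gene_models, states, fold_high = 10,
                             noise_sd = 0.1, seed = 1L) {
  if (!is.list(states) || length(states) < 2 || is.null(names(states))) {
    stop_config("'states' must be a named list of at least 2 states")
  }
  known <- unique(gene_models$module)
  for (s in names(states)) {
    bad <- setdiff(states[[s]], known)
    if (length(bad)) stop_config("state '", s, "' names unknown modules: ",
                                 paste(bad, collapse = ", "))
  }
  set.seed(derive_seed(seed, "build_signatures"))
  profiles <- matrix(0, nrow(gene_models), length(states),
                     dimnames = list(gene_models$gene_id, names(states)))
  for (j in seq_along(states)) {
    fold <- ifelse(gene_models$module %in% states[[j]], fold_high, 1)
    wobble <- if (noise_sd > 0) rlnorm(nrow(gene_models), 0, noise_sd) else 1
    profiles[, j] <- gene_models$baseline_expression * fold * wobble
  }
  signature_set(profiles, gene_models$gene_id)
}

#' Default reprogramming states for the synthetic experiment
#'
#' Origin (primed-like) and destination (naive-like) anchor states plus the
#' two transient-detour signatures observed in the biology: a mesoderm-like
#' state and an early-ICM-like state.
#'
#' @return A named list suitable for [build_signatures()].
#' @export
default_states <- function() {
  list(origin = "origin_marker",
       destination = "destination_marker",
       mesoderm = "mesoderm_marker",
       icm = "icm_marker")
}

#' Route configuration for the cell simulator
#'
#' @param route_name Label recorded in the truth table.
#' @param n_cells Cells to simulate.
#' @param detour_signature Name of the signature the route transiently visits,
#'   or `NULL` for a pure origin-to-destination interpolation.
#' @param detour_amplitude Peak detour weight (0 disables the detour).
#' @param detour_center,detour_width Center in (0,1) and width (> 0) of the
#'   Gaussian detour bump in trajectory position.
#' @param depth_mean Expected mapped reads per cell (default 1e6).
#' @param nb_dispersion Negative-binomial dispersion phi in
#'   variance = mu + phi * mu^2 (0 = Poisson; default 0.1).
#' @param dropout_midpoint Logistic dropout midpoint on the log-mean-count
#'   scale; `-Inf` (default) disables dropout, as appropriate for full-length
#'   library chemistry.
#' @param t_alpha,t_beta Beta(alpha, beta) shape for trajectory positions;
#'   the default (1,1) is Uniform(0,1), i.e. fully asynchronous progression.
#' @param seed Integer seed.
#' @return A `route_config` list.
#' @export
route_config <- function(route_name, n_cells = 200, detour_signature = NULL,
                         detour_amplitude = 0, detour_center = 0.5,
                         detour_width = 0.15, depth_mean = 1e6,
                         nb_dispersion = 0.1, dropout_midpoint = -Inf,
                         t_alpha = 1, t_beta = 1, seed = 1L) {
  check_scalar_number(n_cells, "n_cells", lower = 1)
  check_scalar_number(detour_amplitude, "detour_amplitude", lower = 0)
  check_scalar_number(detour_center, "detour_center", lower = 0, upper = 1)
  check_scalar_number(detour_width, "detour_width", lower = 1e-6)
  check_scalar_number(depth_mean, "depth_mean", lower = 1)
  check_scalar_number(nb_dispersion, "nb_dispersion", lower = 0)
  if (detour_amplitude > 0 && is.null(detour_signature)) {
    stop_config("detour_amplitude > 0 requires a detour_signature")
  }
  structure(list(route_name = route_name, n_cells = as.integer(n_cells),
                 detour_signature = detour_signature,
                 detour_amplitude = detour_amplitude,
                 detour_center = detour_center, detour_width = detour_width,
                 depth_mean = depth_mean, nb_dispersion = nb_dispersion,
                 dropout_midpoint = dropout_midpoint,
                 t_alpha = t_alpha, t_beta = t_beta,
                 seed = as.integer(seed)),
            class = "route_config")
}

#' Simulate single cells along a reprogramming route
#'
#' Each cell draws a trajectory position t from Beta(t_alpha, t_beta)
#' (Uniform by default). Its detour weight is a Gaussian bump
#' `w = amplitude * exp(-(t - center)^2 / (2 width^2))`. Expected FPKM is the
#' mixture `(1 - t - w) * S_origin + t * S_destination + w * S_detour`; if
#' the origin share would go negative the raw weights are clipped at zero and
#' renormalized to sum to one, and the renormalized fractions are what the
#' truth table records. Counts are negative binomial with mean
#' `FPKM * length_kb * library_size / 1e6` and variance `mu + phi mu^2`,
#' optionally zeroed by logistic dropout in the log mean. Library sizes are
#' lognormal around `depth_mean` (cv 0.3).
#'
#' @param signatures A `signature_set` containing at least `origin` and
#'   `destination` columns.
#' @param config A [route_config()].
#' @param gene_models The [gene_universe()] the signatures were built from.
#' @return A list with `matrix` (an `expression_matrix` of counts) and
#'   `truth` (data.frame: cell_id, t_true, route, detour_weight,
#'   library_size, plus one `frac_<state>` column per signature).
#' @export
simulate_cells <- function(signatures, config, gene_models) {
  stopifnot(inherits(signatures, "signature_set"),
            inherits(config, "route_config"))
  S <- signatures$profiles
  if (!all(c("origin", "destination") %in% colnames(S))) {
    stop_config("signatures must include 'origin' and 'destination'")
  }
  det <- config$detour_signature
  if (!is.null(det) && !det %in% colnames(S)) {
    stop_config("detour signature '", det, "' not in the signature set")
  }
  n <- config$n_cells
  set.seed(derive_seed(config$seed, paste0("simulate_cells:",
                                           config$route_name)))
  t_true <- rbeta(n, config$t_alpha, config$t_beta)
  w <- if (is.null(det) || config$detour_amplitude == 0) rep(0, n) else
    config$detour_amplitude *
      exp(-(t_true - config$detour_center)^2 / (2 * config$detour_width^2))

  k <- ncol(S)
  fractions <- matrix(0, n, k, dimnames = list(NULL, colnames(S)))
  fractions[, "origin"] <- pmax(0, 1 - t_true - w)
  fractions[, "destination"] <- t_true
  if (!is.null(det)) fractions[, det] <- fractions[, det] + w
  fractions <- fractions / rowSums(fractions)
  stopifnot(all(abs(rowSums(fractions) - 1) < 1e-12), all(fractions >= 0))

  lib <- pmax(1, round(rlnorm(n, log(config$depth_mean) - 0.3^2 / 2, 0.3)))
  mu_fpkm <- S %*% t(fractions)                     # genes x cells
  len_kb <- gene_models$length_bp / 1000
  mu_counts <- mu_fpkm * len_kb * rep(lib / 1e6, each = nrow(S))

  counts <- if (config$nb_dispersion == 0) {
    matrix(rpois(length(mu_counts), mu_counts), nrow(S))
  } else {
    matrix(rnbinom(length(mu_counts), size = 1 / config$nb_dispersion,
                   mu = mu_counts), nrow(S))
  }
  if (is.finite(config$dropout_midpoint)) {
    p_drop <- plogis(config$dropout_midpoint - log(mu_counts + 1e-12))
    counts[runif(length(counts)) < p_drop] <- 0
  }

  cell_ids <- sprintf("%s_cell_%04d", config$route_name, seq_len(n))
  truth <- data.frame(cell_id = cell_ids, t_true = t_true,
                      route = config$route_name,
                      detour_weight = if (is.null(det)) rep(0, n)
                                      else fractions[, det],
                      library_size = lib, stringsAsFactors = FALSE)
  frac_df <- as.data.frame(fractions)
  names(frac_df) <- paste0("frac_", colnames(S))
  truth <- cbind(truth, frac_df)

  mat <- expression_matrix(counts, signatures$gene_ids, cell_ids,
                           gene_length_bp = gene_models$length_bp,
                           mapped_total = as.numeric(lib), unit = "counts")
  list(matrix = mat, truth = truth)
}

#' Simulate several routes and combine them
#'
#' @param signatures,gene_models As in [simulate_cells()].
#' @param configs List of [route_config()] objects.
#' @return A list with a combined `matrix` and `truth` across all routes.
#' @export
simulate_routes <- function(signatures, configs, gene_models) {
  sims <- lapply(configs, simulate_cells, signatures = signatures,
                 gene_models = gene_models)
  values <- do.call(cbind, lapply(sims, function(s) s$matrix$values))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  lib <- unlist(lapply(sims, function(s) s$matrix$mapped_total))
  mat <- expression_matrix(values, signatures$gene_ids, truth$cell_id,
                           gene_length_bp = gene_models$length_bp,
                           mapped_total = lib, unit = "counts")
  list(matrix = mat, truth = truth)
}

#' Simulate gene-body coverage histograms
#'
#' Distributes each library's reads over positional bins along the gene body
#' with probability proportional to `exp(bias_strength * bin / n_bins)`:
#' `bias_strength = 0` gives uniform coverage, positive values pile reads
#' toward the 3' end the way degraded or poly(A)-biased libraries do.
#'
#' @param matrix_counts An `expression_matrix` of counts.
#' @param bias_strength Scalar or per-library vector, >= 0.
#' @param n_bins Positional bins (>= 2; default 100, i.e. percentiles).
#' @param seed Integer seed.
#' @param per_gene If `TRUE`, draw and report per-gene histograms
#'   (library, gene, bin, reads); the default aggregates over genes per
#'   library, which is distributionally identical because the bin
#'   probabilities are shared.
#' @return Data.frame with columns `library`, `gene` (`"all"` when
#'   aggregated), `bin`, `reads`.
#' @export
simulate_coverage <- function(matrix_counts, bias_strength = 0, n_bins = 100,
                              seed = 1L, per_gene = FALSE) {
  stopifnot(inherits(matrix_counts, "expression_matrix"))
  check_scalar_number(n_bins, "n_bins", lower = 2)
  if (any(bias_strength < 0)) stop_config("bias_strength must be >= 0")
  n_lib <- ncol(matrix_counts$values)
  bias <- rep_len(bias_strength, n_lib)
  set.seed(derive_seed(seed, "simulate_coverage"))
  bins <- seq_len(n_bins)
  out <- vector("list", n_lib)
  for (j in seq_len(n_lib)) {
    p <- exp(bias[j] * bins / n_bins)
    p <- p / sum(p)
    if (per_gene) {
      cnt <- matrix_counts$values[, j]
      keep <- which(cnt > 0)
      reads <- vapply(keep, function(g) rmultinom(1, cnt[g], p)[, 1],
                      numeric(n_bins))
      out[[j]] <- data.frame(
        library = matrix_counts$cell_ids[j],
        gene = rep(matrix_counts$gene_ids[keep], each = n_bins),
        bin = rep(bins, length(keep)),
        reads = as.vector(reads))
    } else {
      total <- sum(matrix_counts$values[, j])
      reads <- if (total > 0) rmultinom(1, total, p)[, 1] else rep(0, n_bins)
      out[[j]] <- data.frame(library = matrix_counts$cell_ids[j],
                             gene = "all", bin = bins, reads = reads)
    }
  }
  do.call(rbind, out)
}

#' Simulate immunofluorescence intensity tables
#'
#' A control table drawn from the negative (marker-off) lognormal population
#' and a test table mixing `frac_positive` positive cells in, with per-cell
#' truth labels — the fixture for mean + 2 SD positivity quantification.
#'
#' @param n_control,n_test Cell counts.
#' @param frac_positive Fraction of test cells from the positive population,
#'   in [0, 1].
#' @param neg_params,pos_params Length-2 vectors `c(meanlog, sdlog)` of the
#'   negative and positive lognormal intensity populations.
#' @param seed Integer seed.
#' @return List of data.frames `control` (cell, intensity) and `test`
#'   (cell, intensity, true_positive).
#' @export
simulate_if_intensities <- function(n_control, n_test, frac_positive,
                                    neg_params = c(log(10), 0.4),
                                    pos_params = c(log(200), 0.4),
                                    seed = 1L) {
  check_scalar_number(frac_positive, "frac_positive", lower = 0, upper = 1)
  stopifnot(length(neg_params) == 2, length(pos_params) == 2)
  set.seed(derive_seed(seed, "simulate_if_intensities"))
  control <- data.frame(cell = sprintf("ctrl_%05d", seq_len(n_control)),
                        intensity = rlnorm(n_control, neg_params[1],
                                           neg_params[2]))
  is_pos <- runif(n_test) < frac_positive
  intensity <- ifelse(is_pos,
                      rlnorm(n_test, pos_params[1], pos_params[2]),
                      rlnorm(n_test, neg_params[1], neg_params[2]))
  test <- data.frame(cell = sprintf("test_%05d", seq_len(n_test)),
                     intensity = intensity, true_positive = is_pos)
  list(control = control, test = test)
}
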