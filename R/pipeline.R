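# Pipeline orchestration: a validated config drives
# simulate -> qc -> hvg -> signatures -> deconvolve -> pseudotime ->
# kinetics -> structure -> report, every stage writing its outputs before the
# next starts and a manifest with checksums written last. Reruns from the
# same config and seed are byte-identical (the manifest's own timestamps are
# excluded from checksumming).

#' Default pipeline configuration
#'
#' Every stage block carries the pipeline's standard constants: the 500,000
#' mapped-read floor and the bias-ratio 2 cutoff for QC; the log2 FPKM > 1
#' and CV^2 > 0.5 variable-gene thresholds with pseudocount 1; LOESS span 1/3
#' and degree 2; and a three-route synthetic experiment (2,000 genes, 200
#' cells per route) with one detour-free route and one route detouring
#' through each of the mesoderm-like and early-ICM-like signatures.
#'
#' @param seed Global integer seed; per-stage seeds are derived from it by
#'   [derive_seed()].
#' @return A nested list, serializable to/from YAML losslessly.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      n_genes = 2000L, n_markers_per_module = 50L,
      fold_high = 10, signature_noise_sd = 0.1,
      routes = list(
        list(route_name = "direct", n_cells = 200L,
             detour_signature = NULL, detour_amplitude = 0),
        list(route_name = "mesoderm_route", n_cells = 200L,
             detour_signature = "mesoderm", detour_amplitude = 0.3),
        list(route_name = "icm_route", n_cells = 200L,
             detour_signature = "icm", detour_amplitude = 0.3)
      ),
      detour_center = 0.5, detour_width = 0.15,
      depth_mean = 1e6, nb_dispersion = 0.1,
      coverage_bias_strength = 0.5, coverage_n_bins = 100L
    ),
    qc = list(min_mapped = 5e5, max_bias_ratio = 2, n_bins = 100L),
    hvg = list(mean_threshold = 1, cv2_threshold = 0.5, pseudocount = 1),
    pseudotime = list(origin = "origin", destination = "destination"),
    kinetics = list(span = 1 / 3, degree = 2L, n_query = 100L,
                    genes_per_module = 2L),
    structure = list(pca_center = TRUE, pca_scale = TRUE,
                     linkage = "ward_d2",
                     kmeans_k_min = 2L, kmeans_k_max = 8L,
                     kmeans_restarts = 10L,
                     de_fdr = 0.05, de_reference_quantile = 0.1),
    stages = list(simulate = TRUE, qc = TRUE, hvg = TRUE,
                  deconvolve = TRUE, pseudotime = TRUE, kinetics = TRUE,
                  structure = TRUE)
  )
}

#' Validate a pipeline config against the default schema
#'
#' Unknown keys anywhere in the nesting are a config error naming the key;
#' missing keys inherit defaults.
#'
#' @param config Nested list (e.g. from [read_config()]).
#' @return The config merged over the defaults.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check_keys <- function(cfg, ref, path) {
    if (!is.list(cfg)) return(invisible())
    unknown <- setdiff(names(cfg), names(ref))
    if (length(unknown)) {
      stop_config("unknown config key: ",
                  paste0(path, unknown, collapse = ", "))
    }
    for (nm in names(cfg)) {
      if (nm == "routes") next   # free-form list of route blocks
      if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
        check_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
      }
    }
  }
  check_keys(config, ref, "")
  merge <- function(base, over) {
    for (nm in names(over)) {
      if (nm != "routes" && is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(base[[nm]]))) {
        base[[nm]] <- merge(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  merge(ref, config)
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file path.
#' @return `read_config`: the validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config Config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

route_from_block <- function(block, sim, seed) {
  route_config(
    route_name = block$route_name,
    n_cells = block$n_cells,
    detour_signature = block$detour_signature,
    detour_amplitude = block$detour_amplitude,
    detour_center = sim$detour_center,
    detour_width = sim$detour_width,
    depth_mean = sim$depth_mean,
    nb_dispersion = sim$nb_dispersion,
    seed = derive_seed(seed, paste0("route:", block$route_name))
  )
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order under `out_dir`, writing
#' each stage's outputs before the next starts, the resolved config beside
#' them, and a run manifest (with md5 checksums of every output) last.
#'
#' @param config Config list (validated; see [default_config()]).
#' @param out_dir Output directory, created if needed.
#' @param quiet Suppress progress messages.
#' @return The manifest list, invisibly. Side effects: files under `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  outputs <- character()
  warnings_log <- character()
  add_out <- function(...) outputs <<- c(outputs, ...)

  write_config(config, file.path(out_dir, "config_resolved.yaml"))

  ## --- simulate ------------------------------------------------------
  say("stage simulate")
  sim <- config$simulate
  gm <- gene_universe(sim$n_genes, sim$n_markers_per_module,
                      seed = derive_seed(seed, "gene_universe"))
  sigs <- build_signatures(gm, default_states(), fold_high = sim$fold_high,
                           noise_sd = sim$signature_noise_sd,
                           seed = derive_seed(seed, "signatures"))
  configs <- lapply(sim$routes, route_from_block, sim = sim, seed = seed)
  simulated <- simulate_routes(sigs, configs, gm)
  coverage <- simulate_coverage(simulated$matrix,
                                bias_strength = sim$coverage_bias_strength,
                                n_bins = sim$coverage_n_bins,
                                seed = derive_seed(seed, "coverage"))
  counts_dir <- file.path(out_dir, "counts")
  write_expression(simulated$matrix, counts_dir, format = "mtx")
  write_tsv(simulated$truth, file.path(out_dir, "truth.tsv"))
  write_tsv(coverage, file.path(out_dir, "coverage.tsv"))
  sig_df <- data.frame(gene_id = sigs$gene_ids, sigs$profiles,
                       check.names = FALSE)
  write_tsv(sig_df, file.path(out_dir, "signatures.tsv"))
  add_out(file.path(counts_dir, c("matrix.mtx", "genes.tsv", "cells.tsv")),
          file.path(out_dir, c("truth.tsv", "coverage.tsv",
                               "signatures.tsv")))

  ## --- qc ------------------------------------------------------------
  if (isTRUE(config$stages$qc)) {
    say("stage qc")
    qc <- qc_report(simulated$matrix, coverage,
                    min_mapped = config$qc$min_mapped,
                    n_bins = config$qc$n_bins,
                    max_ratio = config$qc$max_bias_ratio)
    write_tsv(qc, file.path(out_dir, "qc_report.tsv"))
    jsonlite::write_json(list(n_libraries = nrow(qc), n_pass = sum(qc$pass)),
                         file.path(out_dir, "qc_summary.json"),
                         auto_unbox = TRUE)
    add_out(file.path(out_dir, c("qc_report.tsv", "qc_summary.json")))
    kept <- qc$library[qc$pass]
  } else {
    kept <- simulated$matrix$cell_ids
  }
  mat <- subset_matrix(simulated$matrix, cells = kept)
  truth <- simulated$truth[match(kept, simulated$truth$cell_id), ]

  ## --- normalize + hvg ------------------------------------------------
  say("stage hvg")
  fpkm <- compute_fpkm(mat)
  expressed <- filter_expressed(fpkm)
  fpkm <- subset_matrix(fpkm, genes = expressed)
  per_route <- split(truth$cell_id, truth$route)
  hvg_lists <- lapply(per_route, function(cells) {
    vg <- fit_cv2_trend(subset_matrix(fpkm, cells = cells),
                        pseudocount = config$hvg$pseudocount)
    select_variable_genes(vg, config$hvg$mean_threshold,
                          config$hvg$cv2_threshold)
  })
  hvg <- merge_variable_lists(hvg_lists)
  writeLines(hvg, file.path(out_dir, "variable_genes.txt"))
  add_out(file.path(out_dir, "variable_genes.txt"))

  ## --- deconvolve + pseudotime ----------------------------------------
  if (!isTRUE(config$stages$deconvolve) || !isTRUE(config$stages$pseudotime)) {
    if (isTRUE(config$stages$kinetics) || isTRUE(config$stages$structure)) {
      stop_config("kinetics/structure stages require deconvolve and",
                  " pseudotime to be enabled")
    }
  }
  if (isTRUE(config$stages$deconvolve)) {
    say("stage deconvolve")
    sigs_kept <- signature_set(
      sigs$profiles[match(expressed, sigs$gene_ids), , drop = FALSE],
      gene_ids = expressed)
    profiles <- fractional_identity(fpkm, sigs_kept)
    frac_df <- as.data.frame(profiles)
    write_tsv(frac_df, file.path(out_dir, "fractions.tsv"))
    pt <- assign_pseudotime(profiles, config$pseudotime$origin,
                            config$pseudotime$destination)
    write_tsv(as.data.frame(pt), file.path(out_dir, "pseudotime.tsv"))
    summ <- similarity_summary(profiles,
                               truth$route[match(profiles$cell_id,
                                                 truth$cell_id)])
    write_tsv(summ, file.path(out_dir, "similarity_summary.tsv"))
    add_out(file.path(out_dir, c("fractions.tsv", "pseudotime.tsv",
                                 "similarity_summary.tsv")))
  }

  ## --- kinetics --------------------------------------------------------
  lg <- log2_transform(fpkm)
  if (isTRUE(config$stages$kinetics)) {
    say("stage kinetics")
    gm_kept <- gm[match(expressed, gm$gene_id), ]
    marker_genes <- unlist(lapply(
      split(gm_kept$gene_id, gm_kept$module),
      head, config$kinetics$genes_per_module), use.names = FALSE)
    groups <- setNames(truth$route, truth$cell_id)
    kin <- kinetics_table(lg, pt, marker_genes, groups,
                          span = config$kinetics$span,
                          degree = config$kinetics$degree,
                          n_query = config$kinetics$n_query)
    write_tsv(kin, file.path(out_dir, "kinetics.tsv"))
    add_out(file.path(out_dir, "kinetics.tsv"))
  }

  ## --- structure -------------------------------------------------------
  if (isTRUE(config$stages$structure)) {
  say("stage structure")
  st <- config$structure
  pca <- pca_cells(lg, genes = hvg, center = st$pca_center,
                   scale = st$pca_scale)
  scores <- data.frame(cell_id = rownames(pca$scores),
                       pca$scores[, seq_len(min(10, ncol(pca$scores))),
                                  drop = FALSE],
                       check.names = FALSE)
  write_tsv(scores, file.path(out_dir, "pca_scores.tsv"))
  dend <- hierarchical_cluster(subset_matrix(lg, genes = hvg),
                               linkage = st$linkage)
  as_newick(dend, file.path(out_dir, "dendrogram.newick"))
  km <- kmeans_elbow(pca$scores[, 1:2],
                     k_min = st$kmeans_k_min, k_max = st$kmeans_k_max,
                     n_restarts = st$kmeans_restarts,
                     seed = derive_seed(seed, "kmeans"))
  # DE per route: route cells vs the origin-most cells of that route
  de_lists <- lapply(names(per_route), function(r) {
    cells <- intersect(per_route[[r]], pt$cell_id)
    ptr <- pt$pseudotime[match(cells, pt$cell_id)]
    early <- cells[ptr <= quantile(ptr, st$de_reference_quantile)]
    late <- cells[ptr >= quantile(ptr, 1 - st$de_reference_quantile)]
    if (length(early) < 3 || length(late) < 3) return(character())
    de <- rank_sum_de(subset_matrix(lg, cells = c(early, late)),
                      late, early, fdr_threshold = st$de_fdr)
    de$gene_id[de$significant]
  })
  names(de_lists) <- names(per_route)
  part <- de_partition(de_lists)
  jsonlite::write_json(
    list(kmeans_k = km$k, wcss = as.list(km$wcss),
         de_regions = setNames(as.list(part$regions$count),
                               part$regions$region),
         de_unique = as.list(part$unique_counts),
         de_shared_all = part$shared_all,
         pca_explained = pca$explained[1:5]),
    file.path(out_dir, "structure.json"), auto_unbox = TRUE, digits = NA)
  add_out(file.path(out_dir, c("pca_scores.tsv", "dendrogram.newick",
                               "structure.json")))
  }

  ## --- manifest --------------------------------------------------------
  say("stage report")
  checksums <- tools::md5sum(outputs)
  rel_names <- substring(outputs, nchar(out_dir) + 2)
  manifest <- list(
    artifact = "fateline",
    version = as.character(utils::packageVersion("fateline")),
    seed = seed,
    config_hash = unname(tools::md5sum(file.path(out_dir,
                                                 "config_resolved.yaml"))),
    outputs = as.list(setNames(unname(checksums), rel_names)),
    timestamp = format(Sys.time(), tz = "UTC"),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", out_dir)
  invisible(manifest)
}
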