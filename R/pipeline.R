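#' Run the full noise-variation pipeline
#'
#' Orchestrates QC filtering, normalisation, the per-gene NLPD test, full-data
#' heteroscedastic variance-map fitting for the detected noisy genes,
#' noise-pattern clustering and (optionally) explanatory-variable analysis,
#' writing each stage's tabular outputs plus a manifest to `out_dir`.
#' Re-running with an identical configuration reproduces the outputs.
#'
#' @param config a list (or path to a JSON file) with entries:
#'   `counts` (path to a dense-TSV count matrix, or a [spatial_counts]
#'   object), optional `coords` (coordinate TSV path), `out_dir`,
#'   `alpha` (0.05), `repeats` (10), `train_fraction` (0.9), `seed` (1),
#'   `k_clusters` (NULL = skip clustering when fewer noisy genes than
#'   clusters), `rho_threshold` (0.35), `n_controls` (1000), `n_bins` (50),
#'   `min_total` (3), `drop_prefixes` (`c("ERCC","MT-")`), optional
#'   `markers` (path to a marker TSV), optional `genes` (character vector
#'   restricting the tested genes), `n_restarts` (2), `maxit` (100).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the per-stage results (`qc`, `normalized`,
#'   `test`, `variance_maps`, `clustering`, `association`, `out_dir`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(alpha = 0.05, repeats = 10, train_fraction = 0.9, seed = 1,
         k_clusters = NULL, rho_threshold = 0.35, n_controls = 1000,
         n_bins = 50, min_total = 3, drop_prefixes = c("ERCC", "MT-"),
         n_restarts = 2, maxit = 100),
    config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[novatest] ", ...)

  ## Stage 1: input + QC
  raw <- if (inherits(cfg$counts, "spatial_counts")) cfg$counts
         else read_counts(cfg$counts, "dense-tsv", coords_path = cfg$coords)
  say("input: ", nrow(raw$counts), " spots x ", ncol(raw$counts), " genes")
  qc <- qc_filter(raw, min_total = cfg$min_total,
                  drop_prefixes = cfg$drop_prefixes)
  say("QC retained ", ncol(qc$counts), " genes")
  utils::write.table(qc$qc_log %||%
                       data.frame(gene = character(0), reason = character(0)),
                     file.path(cfg$out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## Stage 2: normalisation
  norm <- normalize_and_stabilize(qc)
  utils::write.table(
    data.frame(spot_id = rownames(norm$values), norm$values,
               check.names = FALSE),
    file.path(cfg$out_dir, "normalized.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  ## Stage 3: noise-variation test
  values <- norm$values
  if (!is.null(cfg$genes)) values <- values[, intersect(cfg$genes, colnames(values)),
                                            drop = FALSE]
  plan <- split_plan(nrow(values), n_repeats = cfg$repeats,
                     train_fraction = cfg$train_fraction, seed = cfg$seed)
  say("testing ", ncol(values), " genes over ", cfg$repeats, " splits")
  test <- noise_variation_test(values, norm$coords, plan = plan,
                               alpha = cfg$alpha, n_restarts = cfg$n_restarts,
                               seed = cfg$seed, maxit = cfg$maxit,
                               verbose = verbose)
  utils::write.table(test$results, file.path(cfg$out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(test$failed, file.path(cfg$out_dir, "failed_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  noisy <- test$results$gene[test$results$is_noisy]
  say(length(noisy), " noisy gene(s) at FDR ", cfg$alpha)

  ## Stage 4: full-data variance maps for noisy genes + clustering
  variance_maps <- NULL
  clustering <- NULL
  if (length(noisy) > 0) {
    variance_maps <- vapply(noisy, function(g) {
      fit_hgp(values[, g], norm$coords, n_restarts = cfg$n_restarts,
              seed = derive_seed(cfg$seed, g),
              maxit = cfg$maxit)$noise_variance
    }, numeric(nrow(values)))
    colnames(variance_maps) <- noisy
    utils::write.table(
      data.frame(spot_id = rownames(values), norm$coords, variance_maps,
                 check.names = FALSE),
      file.path(cfg$out_dir, "variance_maps.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cfg$k_clusters) && length(noisy) >= cfg$k_clusters) {
      clustering <- cluster_noisy_genes(variance_maps, k = cfg$k_clusters)
      utils::write.table(
        data.frame(gene = names(clustering$labels),
                   cluster = unname(clustering$labels)),
        file.path(cfg$out_dir, "clusters.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(spot_id = rownames(values), norm$coords,
                   clustering$representatives, check.names = FALSE),
        file.path(cfg$out_dir, "cluster_representatives.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## Stage 5: explanatory analysis
  association <- NULL
  if (!is.null(variance_maps)) {
    abundance <- cell_abundance(qc)
    association <- list(
      cell_abundance = bivariate_association(variance_maps, abundance,
                                             rho_threshold = cfg$rho_threshold))
    if (!is.null(cfg$markers)) {
      markers <- read_marker_sets(cfg$markers)
      enr <- enrichment_pvalues(norm, markers, n_controls = cfg$n_controls,
                                n_bins = cfg$n_bins, seed = cfg$seed)
      utils::write.table(
        data.frame(spot_id = rownames(values), enr$p_values,
                   cell_type_count = enr$cell_type_count,
                   check.names = FALSE),
        file.path(cfg$out_dir, "enrichment.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      association$cell_type_heterogeneity <-
        bivariate_association(variance_maps, enr$cell_type_count,
                              rho_threshold = cfg$rho_threshold)
    }
    for (nm in names(association)) {
      utils::write.table(association[[nm]],
                         file.path(cfg$out_dir,
                                   paste0("association_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## Manifest
  manifest <- cfg
  manifest$counts <- if (is.character(cfg$counts)) cfg$counts else "<in-memory>"
  manifest$package_version <- as.character(utils::packageVersion("novatest"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(qc = qc, normalized = norm, test = test,
                 variance_maps = variance_maps, clustering = clustering,
                 association = association, out_dir = cfg$out_dir))
}
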