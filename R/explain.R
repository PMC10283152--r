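#' Per-spot cell abundance proxy
#'
#' The total transcript (UMI) count of a spot tracks the number of cells it
#' covers, so the per-spot sum of raw counts over all genes serves as a
#' proxy for cell abundance.
#'
#' @param data a [spatial_counts] object (raw, pre-normalisation counts).
#' @return A nonnegative vector of length N (one value per spot).
#' @export
cell_abundance <- function(data) {
  stopifnot(inherits(data, "spatial_counts"))
  rowSums(data$counts)
}

#' Read cell-type marker sets from a two-column TSV
#'
#' @param path TSV with columns `cell_type` and `gene`.
#' @return A named list: cell type -> character vector of marker genes.
#' @export
read_marker_sets <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% colnames(tab)))
    stop("marker file must have columns cell_type and gene")
  split(as.character(tab$gene), tab$cell_type)
}

#' Marker-set enrichment p-values per spot and cell type
#'
#' For each cell type, the program score of a spot is the mean normalised
#' expression of the marker genes at that spot. `n_controls` control sets
#' are built by replacing every marker with a random gene drawn (with
#' replacement) from the same aggregate-expression bin, where genes are
#' partitioned into `n_bins` equal-frequency bins of their summed
#' expression. The empirical p-value of a spot is the fraction of control
#' scores strictly greater than the program score; a spot is enriched when
#' p < 0.05, and the per-spot count of enriched cell types measures
#' cell-type heterogeneity.
#'
#' @param expr a `normalized_expression` object (or N x G matrix).
#' @param markers named list of marker gene vectors, one per cell type.
#' @param n_controls number of control sets (default 1000).
#' @param n_bins number of expression bins (default 50).
#' @param seed RNG seed for control-set sampling.
#' @return A list with `p_values` (N x types matrix), `enriched`
#'   (logical matrix, p < 0.05), `cell_type_count` (length-N integer) and
#'   `dropped_markers` (markers absent from the matrix).
#' @export
enrichment_pvalues <- function(expr, markers, n_controls = 1000,
                               n_bins = 50, seed = 1) {
  values <- if (inherits(expr, "normalized_expression")) expr$values
            else as.matrix(expr)
  genes <- colnames(values)
  if (is.null(genes)) stop("expression matrix must have gene names")
  agg <- colSums(values)
  n_bins <- min(n_bins, length(genes))
  # Equal-frequency bins of aggregate expression; rank ties broken stably.
  bin_of <- ceiling(rank(agg, ties.method = "first") / length(agg) * n_bins)
  bins <- split(seq_along(genes), bin_of)
  dropped <- list()
  p_values <- with_seed(seed, function() {
    vapply(names(markers), function(ct) {
      mk <- intersect(markers[[ct]], genes)
      miss <- setdiff(markers[[ct]], genes)
      if (length(miss) > 0) {
        dropped[[ct]] <<- miss
        warning("cell type ", ct, ": ", length(miss),
                " marker(s) absent from the expression matrix")
      }
      if (length(mk) == 0)
        stop("cell type ", ct, ": no marker present in the expression matrix")
      idx <- match(mk, genes)
      program <- rowMeans(values[, idx, drop = FALSE])
      exceed <- numeric(nrow(values))
      mk_bins <- bin_of[idx]
      for (b in seq_len(n_controls)) {
        ctrl_idx <- vapply(mk_bins, function(bb) {
          pool <- bins[[as.character(bb)]]
          if (length(pool) == 1) pool else pool[sample.int(length(pool), 1)]
        }, integer(1))
        ctrl <- rowMeans(values[, ctrl_idx, drop = FALSE])
        exceed <- exceed + (ctrl > program)
      }
      exceed / n_controls
    }, numeric(nrow(values)))
  })
  p_values <- matrix(p_values, nrow = nrow(values),
                     dimnames = list(rownames(values), names(markers)))
  enriched <- p_values < 0.05
  list(p_values = p_values, enriched = enriched,
       cell_type_count = rowSums(enriched),
       dropped_markers = dropped)
}

#' Spearman association between noise-variance maps and an explanatory variable
#'
#' For every gene, the Spearman correlation between its per-spot predicted
#' noise variance and the explanatory variable (e.g. cell abundance or
#' cell-type heterogeneity) is computed with its p-value; p-values are
#' BH-adjusted across genes, and a gene is flagged as explained when
#' `|rho| > rho_threshold` and `q < alpha`.
#'
#' @param variance_maps N x G matrix (or named list) of per-spot noise
#'   variances of the noisy genes.
#' @param explanatory length-N numeric vector, not constant.
#' @param rho_threshold minimum absolute Spearman correlation (default 0.35).
#' @param alpha FDR level (default 0.05).
#' @return A data frame with columns `gene`, `rho`, `p_value`, `q_value`,
#'   `flagged`.
#' @export
bivariate_association <- function(variance_maps, explanatory,
                                  rho_threshold = 0.35, alpha = 0.05) {
  if (is.list(variance_maps)) variance_maps <- do.call(cbind, variance_maps)
  variance_maps <- as.matrix(variance_maps)
  if (is.null(colnames(variance_maps)))
    colnames(variance_maps) <- paste0("gene_", seq_len(ncol(variance_maps)))
  explanatory <- as.numeric(explanatory)
  stopifnot(length(explanatory) == nrow(variance_maps))
  if (stats::sd(explanatory) == 0)
    stop("explanatory variable is constant; association undefined")
  tests <- lapply(seq_len(ncol(variance_maps)), function(j) {
    suppressWarnings(stats::cor.test(variance_maps[, j], explanatory,
                                     method = "spearman",
                                     exact = nrow(variance_maps) < 10))
  })
  rho <- vapply(tests, function(t) unname(t$estimate), numeric(1))
  p <- vapply(tests, function(t) t$p.value, numeric(1))
  q <- bh_fdr(p)
  data.frame(gene = colnames(variance_maps), rho = rho, p_value = p,
             q_value = q,
             flagged = abs(rho) > rho_threshold & q < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Local mean-variance Spearman correlation
#'
#' Diagnostic for mean-variance artefacts: at every spot, the Spearman
#' correlation between the modelled mean and the modelled noise variance is
#' computed over the spot's `n_neighbors` nearest neighbours (Euclidean,
#' excluding the spot itself). Genes whose variance pattern merely mirrors
#' their mean pattern show uniformly high local correlation.
#'
#' @param mean_map,var_map length-N vectors of modelled mean and variance.
#' @param coords N x 2 spot coordinates.
#' @param n_neighbors neighbourhood size (default 12).
#' @return A length-N vector of local Spearman correlations (NA where the
#'   neighbourhood is degenerate).
#' @export
local_mean_variance_correlation <- function(mean_map, var_map, coords,
                                            n_neighbors = 12) {
  mean_map <- as.numeric(mean_map)
  var_map <- as.numeric(var_map)
  coords <- as.matrix(coords)
  n <- length(mean_map)
  stopifnot(length(var_map) == n, nrow(coords) == n, n > n_neighbors)
  D2 <- cross_sq_dists(coords, coords)
  vapply(seq_len(n), function(i) {
    # order() is stable, so exact distance ties resolve by spot index.
    nb <- order(D2[i, ])[-1][seq_len(n_neighbors)]
    suppressWarnings(stats::cor(mean_map[nb], var_map[nb],
                                method = "spearman"))
  }, numeric(1))
}
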