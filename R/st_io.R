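#' Spot-by-gene spatial count matrix
#'
#' Container for raw UMI counts on a spatial array: an N x G integer count
#' matrix (rows = spots, columns = genes) plus an N x 2 matrix of spot
#' coordinates (columns `x1`, `x2`, in array units).
#'
#' @param counts integer-valued N x G matrix of UMI counts, spots in rows.
#' @param coords numeric N x 2 matrix of spot coordinates.
#' @param gene_names,spot_ids optional identifiers; default to the dimnames
#'   of `counts`.
#' @param qc_log optional data frame recording genes dropped by QC.
#' @return An object of class `spatial_counts`.
#' @export
spatial_counts <- function(counts, coords, gene_names = colnames(counts),
                           spot_ids = rownames(counts), qc_log = NULL) {
  counts <- as.matrix(counts)
  coords <- as.matrix(coords)
  if (is.null(gene_names)) gene_names <- paste0("gene_", seq_len(ncol(counts)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(counts)))
  if (length(gene_names) != ncol(counts))
    stop("gene_names length does not match the number of count columns")
  if (length(spot_ids) != nrow(counts))
    stop("spot_ids length does not match the number of count rows")
  if (nrow(coords) != nrow(counts))
    stop("coordinate table has ", nrow(coords), " rows but the count matrix has ",
         nrow(counts), " spots")
  if (ncol(coords) != 2) stop("coords must have exactly two columns (x1, x2)")
  if (any(!is.finite(coords))) stop("coords must be finite")
  if (anyDuplicated(coords) > 0) stop("coords rows must be unique")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integer-valued")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(spot_ids, gene_names)
  dimnames(coords) <- list(spot_ids, c("x1", "x2"))
  structure(list(counts = counts, coords = coords,
                 gene_names = gene_names, spot_ids = spot_ids,
                 qc_log = qc_log),
            class = "spatial_counts")
}

#' @export
print.spatial_counts <- function(x, ...) {
  cat("spatial_counts:", nrow(x$counts), "spots x", ncol(x$counts), "genes\n")
  if (!is.null(x$qc_log) && nrow(x$qc_log) > 0)
    cat("  QC dropped", nrow(x$qc_log), "genes\n")
  invisible(x)
}

#' @export
dim.spatial_counts <- function(x) dim(x$counts)

.parse_coord_ids <- function(ids) {
  m <- regexec("^(-?[0-9]+\\.?[0-9]*)x(-?[0-9]+\\.?[0-9]*)$", ids)
  parts <- regmatches(ids, m)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad) > 0)
    stop("cannot parse coordinates from spot id(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  cbind(x1 = as.numeric(vapply(parts, `[`, "", 2L)),
        x2 = as.numeric(vapply(parts, `[`, "", 3L)))
}

.read_coord_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("spot_id", "x1", "x2")
  if (!all(need %in% colnames(tab)))
    stop("coordinate table must have columns spot_id, x1, x2")
  co <- as.matrix(tab[, c("x1", "x2")])
  rownames(co) <- as.character(tab$spot_id)
  co
}

#' Read a spatial count matrix
#'
#' Two on-disk dialects are supported. `"dense-tsv"` is a tab-separated
#' matrix with spots in rows and genes in columns whose first column holds
#' spot identifiers; identifiers of the form `"12x34"` encode the spot
#' coordinates directly, otherwise a coordinate table must be supplied.
#' `"mtx-triplet"` is a MatrixMarket sparse matrix (spots x genes) with
#' sidecar files listing gene names and spot ids, plus a coordinate table.
#'
#' @param path path to the count matrix file.
#' @param fmt `"dense-tsv"` or `"mtx-triplet"`.
#' @param coords_path optional coordinate table (TSV with columns
#'   `spot_id`, `x1`, `x2`); required for `"mtx-triplet"`.
#' @param genes_path,spots_path sidecar files (one name per line) for
#'   `"mtx-triplet"`.
#' @return A [spatial_counts] object.
#' @export
read_counts <- function(path, fmt = c("dense-tsv", "mtx-triplet"),
                        coords_path = NULL, genes_path = NULL,
                        spots_path = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "dense-tsv") {
    if (file.info(path)$size == 0) stop("empty count file: ", path)
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0 || ncol(tab) < 2)
      stop("count file has no spots or no genes: ", path)
    spot_ids <- as.character(tab[[1]])
    mat <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(mat)) stop("non-numeric entries in the count matrix")
    if (any(mat != round(mat)))
      stop("non-integer count values in the count matrix")
    rownames(mat) <- spot_ids
    if (is.null(coords_path)) {
      coords <- .parse_coord_ids(spot_ids)
      rownames(coords) <- spot_ids
    } else {
      coords <- .read_coord_table(coords_path)
    }
  } else {
    if (is.null(coords_path) || is.null(genes_path) || is.null(spots_path))
      stop("mtx-triplet format requires coords_path, genes_path and spots_path")
    m <- Matrix::readMM(path)
    genes <- readLines(genes_path)
    spots <- readLines(spots_path)
    if (nrow(m) != length(spots) || ncol(m) != length(genes))
      stop("MatrixMarket dimensions (", nrow(m), " x ", ncol(m),
           ") do not match sidecar files (", length(spots), " spots, ",
           length(genes), " genes)")
    mat <- as.matrix(m)
    dimnames(mat) <- list(spots, genes)
    spot_ids <- spots
    coords <- .read_coord_table(coords_path)
  }
  if (!setequal(rownames(coords), spot_ids) && nrow(coords) != nrow(mat))
    stop("coordinate table and count matrix disagree on the spot set")
  if (all(spot_ids %in% rownames(coords))) coords <- coords[spot_ids, , drop = FALSE]
  spatial_counts(mat, coords)
}

#' Write a spatial count matrix as dense TSV
#'
#' Inverse of [read_counts] for the `"dense-tsv"` dialect. When spot ids do
#' not encode their coordinates, pass `coords_path` to write a sidecar table.
#'
#' @param data a [spatial_counts] object.
#' @param path output TSV path.
#' @param coords_path optional path for a `spot_id`/`x1`/`x2` table.
#' @export
write_counts <- function(data, path, coords_path = NULL) {
  df <- data.frame(spot_id = data$spot_ids,
                   data$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(coords_path)) {
    utils::write.table(
      data.frame(spot_id = data$spot_ids,
                 x1 = data$coords[, 1], x2 = data$coords[, 2]),
      coords_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Quality-control gene filtering
#'
#' Removes spike-in and mitochondrial genes by name prefix and genes whose
#' total count across all spots falls below `min_total`. Spots are never
#' removed and the relative order of retained genes is preserved. The reason
#' each gene was dropped is recorded in the returned object's `qc_log`.
#'
#' @param data a [spatial_counts] object.
#' @param min_total minimum total UMI count for a gene to be retained
#'   (default 3: genes seen fewer than 3 times are considered practically
#'   unobservable).
#' @param drop_prefixes character vector of case-insensitive gene-name
#'   prefixes to drop (default ERCC spike-ins and `MT-` mitochondrial genes).
#' @return A filtered [spatial_counts] with a populated `qc_log`.
#' @export
qc_filter <- function(data, min_total = 3,
                      drop_prefixes = c("ERCC", "MT-")) {
  stopifnot(inherits(data, "spatial_counts"), min_total >= 0)
  g <- data$gene_names
  reason <- rep(NA_character_, length(g))
  for (p in drop_prefixes) {
    hit <- startsWith(toupper(g), toupper(p)) & is.na(reason)
    reason[hit] <- paste0("prefix:", p)
  }
  totals <- colSums(data$counts)
  low <- is.na(reason) & totals < min_total
  reason[low] <- paste0("total_count<", min_total)
  keep <- is.na(reason)
  if (!any(keep))
    stop("QC filtering removed every gene; check drop_prefixes/min_total")
  log_new <- data.frame(gene = g[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  qc_log <- rbind(data$qc_log, log_new)
  spatial_counts(data$counts[, keep, drop = FALSE], data$coords,
                 gene_names = g[keep], spot_ids = data$spot_ids,
                 qc_log = qc_log)
}

#' Library-size normalised, variance-stabilised expression
#'
#' Each spot's counts are rescaled so its library size matches the median
#' library size, then the Anscombe square-root transform is applied:
#' \deqn{y_{ij} = 2\sqrt{\bar{s}\, c_{ij}/s_i + 3/8}}
#' where \eqn{c_{ij}} is the UMI count, \eqn{s_i} the spot's library size and
#' \eqn{\bar{s}} the median library size. The transform approximately
#' stabilises the count variance so a Gaussian process model is appropriate.
#'
#' @param data a [spatial_counts] object.
#' @return An object of class `normalized_expression` with fields `values`
#'   (N x G), `coords`, `gene_names`, `lib_sizes` and `scale_factor`.
#' @export
normalize_and_stabilize <- function(data) {
  stopifnot(inherits(data, "spatial_counts"))
  s <- rowSums(data$counts)
  if (any(s == 0))
    stop("spot(s) with zero library size: ",
         paste(utils::head(data$spot_ids[s == 0], 5), collapse = ", "))
  sbar <- stats::median(s)
  values <- 2 * sqrt(sweep(data$counts, 1, sbar / s, `*`) + 3 / 8)
  normalized_expression(values, data$coords, data$gene_names,
                        lib_sizes = s, scale_factor = sbar)
}

#' @rdname normalize_and_stabilize
#' @param values transformed N x G expression matrix.
#' @param coords N x 2 spot coordinates.
#' @param gene_names gene identifiers.
#' @param lib_sizes per-spot library sizes used in the normalisation.
#' @param scale_factor the common library size the spots were scaled to.
#' @export
normalized_expression <- function(values, coords, gene_names = colnames(values),
                                  lib_sizes = NULL, scale_factor = NULL) {
  values <- as.matrix(values)
  coords <- as.matrix(coords)
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (nrow(values) != nrow(coords)) stop("values/coords spot mismatch")
  if (is.null(gene_names)) gene_names <- paste0("gene_", seq_len(ncol(values)))
  colnames(values) <- gene_names
  colnames(coords) <- c("x1", "x2")
  structure(list(values = values, coords = coords, gene_names = gene_names,
                 lib_sizes = lib_sizes, scale_factor = scale_factor),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat("normalized_expression:", nrow(x$values), "spots x",
      ncol(x$values), "genes\n")
  invisible(x)
}
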