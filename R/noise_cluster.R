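#' Otsu threshold of a nonnegative vector
#'
#' Histogram-based threshold selection: values are binned into `n_bins`
#' equal-width bins over `[min, max]` and the bin-edge threshold maximising
#' the between-class variance `w0 * w1 * (m0 - m1)^2` is returned (class
#' means are computed from the raw values, so the search is exact within the
#' binned candidate set). Used to binarise per-gene spatial noise-variance
#' maps before Jaccard comparison.
#'
#' @param values numeric vector, not all equal.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold; entries with `value > threshold` form the
#'   high-variance mask.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- as.numeric(values)
  stopifnot(all(is.finite(values)))
  if (diff(range(values)) == 0)
    stop("Otsu threshold undefined for a constant vector")
  lo <- min(values); hi <- max(values)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
              n_bins)
  cnt <- tabulate(bin, n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(values[bin == b]),
                 numeric(1))
  n <- length(values)
  c0 <- cumsum(cnt)[-n_bins]          # class 0: bins 1..t
  s0 <- cumsum(sums)[-n_bins]
  c1 <- n - c0
  s1 <- sum(values) - s0
  valid <- c0 > 0 & c1 > 0
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (c0[valid] / n) * (c1[valid] / n) *
    (s0[valid] / c0[valid] - s1[valid] / c1[valid])^2
  t_best <- which.max(bcv)
  edges[t_best + 1]
}

#' Jaccard distance between binary spatial masks
#'
#' `JD = 1 - |a AND b| / |a OR b|`: zero when two genes are "high variance"
#' in exactly the same spots, one when the high-variance regions are
#' disjoint. Two all-false masks get distance 0 by convention; an all-false
#' vs a nonempty mask gets 1.
#'
#' @param a,b logical vectors of equal length.
#' @return The distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(0)
  1 - sum(a & b) / u
}

#' Cluster noisy genes by spatial noise-variance pattern
#'
#' Each gene's variance map is binarised at its own Otsu threshold, pairwise
#' Jaccard distances between the masks are computed, and average- (or
#' complete-) linkage agglomerative clustering is cut at `k` clusters.
#' Cluster representatives are the elementwise means of the raw (not
#' binarised) variance maps of the members. Genes with constant maps cannot
#' be binarised and are excluded with a warning.
#'
#' @param variance_maps N x G matrix (or named list of length-N vectors) of
#'   per-spot noise variances for the genes to cluster.
#' @param k number of clusters.
#' @param linkage `"average"` or `"complete"`.
#' @return An object of class `noise_clustering`: `labels` (named integer
#'   vector), `k`, `representatives` (N x k matrix), `distance_matrix`,
#'   `masks` (N x G logical), `thresholds`, `dropped`.
#' @export
cluster_noisy_genes <- function(variance_maps, k,
                                linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  if (is.list(variance_maps))
    variance_maps <- do.call(cbind, variance_maps)
  variance_maps <- as.matrix(variance_maps)
  if (is.null(colnames(variance_maps)))
    colnames(variance_maps) <- paste0("gene_", seq_len(ncol(variance_maps)))
  constant <- apply(variance_maps, 2, function(v) diff(range(v)) == 0)
  dropped <- colnames(variance_maps)[constant]
  if (length(dropped) > 0) {
    warning("excluding ", length(dropped),
            " gene(s) with constant variance maps from clustering")
    variance_maps <- variance_maps[, !constant, drop = FALSE]
  }
  g <- ncol(variance_maps)
  stopifnot(k >= 1, g >= k)
  thresholds <- apply(variance_maps, 2, otsu_threshold)
  masks <- sweep(variance_maps, 2, thresholds, `>`)
  jd <- matrix(0, g, g, dimnames = list(colnames(masks), colnames(masks)))
  for (i in seq_len(g - 1)) {
    for (j in seq(i + 1, g)) {
      jd[i, j] <- jd[j, i] <- jaccard_distance(masks[, i], masks[, j])
    }
  }
  if (g == 1) {
    labels <- stats::setNames(1L, colnames(masks))
  } else {
    hc <- stats::hclust(stats::as.dist(jd), method = linkage)
    labels <- stats::cutree(hc, k = k)
  }
  reps <- vapply(seq_len(k), function(cl)
    rowMeans(variance_maps[, labels == cl, drop = FALSE]),
    numeric(nrow(variance_maps)))
  colnames(reps) <- paste0("cluster_", seq_len(k))
  structure(list(labels = labels, k = k, representatives = reps,
                 distance_matrix = jd, masks = masks,
                 thresholds = thresholds, dropped = dropped),
            class = "noise_clustering")
}

#' @export
print.noise_clustering <- function(x, ...) {
  cat("noise_clustering of", length(x$labels), "genes into", x$k, "clusters\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Mean silhouette width over a Jaccard distance matrix for a range of k
#'
#' Helper for choosing the number of noise-pattern clusters when no external
#' guidance exists: computes the average silhouette width of the
#' agglomerative clustering at each candidate `k`.
#'
#' @param variance_maps as in [cluster_noisy_genes].
#' @param ks candidate cluster counts (each >= 2).
#' @param linkage linkage method.
#' @return A data frame with columns `k` and `mean_silhouette`.
#' @export
silhouette_scan <- function(variance_maps, ks = 2:6,
                            linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(all(ks >= 2))
  res <- vapply(ks, function(k) {
    cl <- cluster_noisy_genes(variance_maps, k, linkage)
    d <- cl$distance_matrix
    lab <- cl$labels
    s <- vapply(seq_along(lab), function(i) {
      own <- lab == lab[i]
      own[i] <- FALSE
      a <- if (any(own)) mean(d[i, own]) else 0
      b <- min(vapply(setdiff(unique(lab), lab[i]), function(other)
        mean(d[i, lab == other]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }, numeric(1))
  data.frame(k = ks, mean_silhouette = res)
}
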