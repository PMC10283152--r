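#' Negative log predictive density
#'
#' Average negative log density of held-out observations under Gaussian
#' predictive distributions:
#' \deqn{\mathrm{NLPD} = \frac{1}{N'} \sum_i \frac12\left[\log(2\pi\sigma_i^2)
#'   + (y_i-\mu_i)^2/\sigma_i^2\right].}
#' Lower is better; unlike MSE it penalises both over- and under-confident
#' variance predictions.
#'
#' @param y_val held-out observations.
#' @param pred_mean,pred_var predictive means and variances (same length).
#' @param var_floor variances are floored at this value before evaluation to
#'   guard against degenerate clipped predictions.
#' @return The scalar NLPD.
#' @export
nlpd <- function(y_val, pred_mean, pred_var, var_floor = 1e-8) {
  y_val <- as.numeric(y_val)
  stopifnot(length(pred_mean) == length(y_val),
            length(pred_var) == length(y_val))
  v <- pmax(pred_var, var_floor)
  if (any(v <= 0) || any(!is.finite(v)))
    stop("nonpositive or non-finite predictive variance after flooring")
  mean(0.5 * (log(2 * pi * v) + (y_val - pred_mean)^2 / v))
}

#' Repeated random train/validation split plan
#'
#' Draws `n_repeats` independent random partitions of the spots into a
#' training set (`train_fraction` of spots) and a validation set. The same
#' plan is reused for every gene so NLPD comparisons are paired across genes
#' and splits.
#'
#' @param n_spots number of spots N.
#' @param n_repeats number of random splits (default 10).
#' @param train_fraction fraction of spots used for training (default 0.9).
#' @param seed RNG seed making the plan reproducible.
#' @return An object of class `split_plan`: a list of
#'   `list(train =, validation =)` index vectors plus the settings.
#' @export
split_plan <- function(n_spots, n_repeats = 10, train_fraction = 0.9,
                       seed = 1) {
  stopifnot(n_repeats >= 1, train_fraction > 0, train_fraction < 1)
  n_val <- round((1 - train_fraction) * n_spots)
  if (n_val < 2)
    stop("validation sets would have fewer than 2 spots; decrease train_fraction")
  splits <- with_seed(seed, function() {
    lapply(seq_len(n_repeats), function(i) {
      va <- sort(sample.int(n_spots, n_val))
      list(train = setdiff(seq_len(n_spots), va), validation = va)
    })
  })
  structure(list(n_spots = n_spots, n_repeats = n_repeats,
                 train_fraction = train_fraction, seed = seed,
                 splits = splits),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d repeats of %d/%d train/validation spots (seed %s)\n",
              x$n_repeats, length(x$splits[[1]]$train),
              length(x$splits[[1]]$validation), format(x$seed)))
  invisible(x)
}

#' Paired NLPDs of the homoscedastic and heteroscedastic models for one gene
#'
#' For each split of the plan both models are fitted on the training spots
#' and scored by [nlpd] on the identical validation spots. The homoscedastic
#' predictive variance is the latent posterior variance plus the fitted noise
#' variance `sigma_n2`; the heteroscedastic predictive variance is the
#' clipped stage-1 posterior variance plus the stage-2 variance-residual
#' posterior mean, bounded below by the stage-2 posterior standard deviation
#' (see [hgp_predict]). Stage-2 hyperparameters are refitted on every training
#' split so no validation information leaks into the variance model.
#'
#' @param y expression vector for the gene (nonzero variance).
#' @param coords N x 2 spot coordinates.
#' @param plan a [split_plan].
#' @param n_restarts,seed optimiser settings (see [fit_homoscedastic_gp]).
#' @param var_floor predictive-variance floor for [nlpd].
#' @param sq_dists optional precomputed N x N squared-distance matrix.
#' @param maxit L-BFGS-B iteration cap.
#' @return A list with numeric vectors `nlpd_homo` and `nlpd_hetero` of
#'   length `plan$n_repeats`.
#' @export
evaluate_gene <- function(y, coords = NULL, plan, n_restarts = 2,
                          seed = NULL, var_floor = 1e-8, sq_dists = NULL,
                          maxit = 100) {
  y <- as.numeric(y)
  stopifnot(inherits(plan, "split_plan"), length(y) == plan$n_spots)
  if (stats::var(y) == 0) stop("gene has zero variance across spots")
  D2 <- sq_dists %||% cross_sq_dists(coords, coords)
  homo <- hetero <- numeric(plan$n_repeats)
  for (r in seq_len(plan$n_repeats)) {
    tr <- plan$splits[[r]]$train
    va <- plan$splits[[r]]$validation
    split_seed <- if (is.null(seed)) NULL else seed + 2L * (r - 1L)
    core <- tryCatch(
      .hgp_fit_core(y[tr], D2[tr, tr, drop = FALSE], n_restarts, split_seed,
                    maxit = maxit),
      error = function(e)
        stop("model fitting failed on split ", r, ": ",
             conditionMessage(e), call. = FALSE))
    D2_qt <- D2[va, tr, drop = FALSE]
    pr <- .hgp_predict_core(core, D2_qt)
    homo[r] <- nlpd(y[va], pr$mean, pr$var_latent + core$p1$sigma_n2,
                    var_floor)
    hetero[r] <- nlpd(y[va], pr$mean, pr$variance_floored, var_floor)
  }
  list(nlpd_homo = homo, nlpd_hetero = hetero)
}

#' Exact Wilcoxon signed-rank test for paired NLPDs
#'
#' Tests whether the paired values `a` are systematically smaller than `b`.
#' Zero differences are discarded (p = 1 if all are zero); ties in the
#' absolute differences receive average ranks. The null distribution of the
#' positive-rank sum is computed exactly by convolution over all `2^R` sign
#' assignments, so p-values at R = 10 splits are exact (granularity 1/1024).
#'
#' @param a,b paired numeric vectors (length >= 5).
#' @param alternative `"less"` (a stochastically smaller than b) or
#'   `"two.sided"`.
#' @return The p-value.
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- as.numeric(a) - as.numeric(b)
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  n <- length(d)
  r <- rank(abs(d))
  # Doubled ranks are integers even with average ranks from ties.
  r2 <- as.integer(round(2 * r))
  w2 <- round(2 * sum(r[d > 0]))
  counts <- numeric(sum(r2) + 1)
  counts[1] <- 1
  for (ri in r2) {
    counts <- counts + c(numeric(ri), counts[seq_len(length(counts) - ri)])
  }
  probs <- counts / 2^n
  support <- seq_along(counts) - 1
  p_le <- sum(probs[support <= w2])
  if (alternative == "less") {
    min(1, p_le)
  } else {
    p_ge <- sum(probs[support >= w2])
    min(1, 2 * min(p_le, p_ge))
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * G / j`, capped at 1
#' and returned in the input order.
#'
#' @param p_values p-values in `[0, 1]`.
#' @return The adjusted q-values.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  stopifnot(all(p >= 0 & p <= 1))
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(n / seq(n, 1) * p[o]))
  q[order(o)]
}

#' Call noisy genes from paired NLPD vectors
#'
#' One-sided Wilcoxon signed-rank p-value per gene (heteroscedastic NLPD
#' stochastically smaller than homoscedastic), Benjamini-Hochberg adjustment
#' across all tested genes, and a gene is called noisy when its q-value is
#' below `alpha`.
#'
#' @param results named list, one element per gene, each a list with
#'   `nlpd_homo` and `nlpd_hetero` (as returned by [evaluate_gene]).
#' @param alpha FDR level (default 0.05).
#' @return A data frame with columns `gene`, `p_value`, `q_value`,
#'   `is_noisy`, `mean_nlpd_homo`, `mean_nlpd_hetero`.
#' @export
call_noisy_genes <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 1)
  genes <- names(results) %||% paste0("gene_", seq_along(results))
  p <- vapply(results, function(r)
    wilcoxon_signed_rank(r$nlpd_hetero, r$nlpd_homo, "less"), numeric(1))
  q <- bh_fdr(p)
  data.frame(gene = genes,
             p_value = unname(p),
             q_value = q,
             is_noisy = q < alpha,
             mean_nlpd_homo = vapply(results, function(r)
               mean(r$nlpd_homo), numeric(1)),
             mean_nlpd_hetero = vapply(results, function(r)
               mean(r$nlpd_hetero), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the noise-variation test over a whole expression matrix
#'
#' Applies [evaluate_gene] to every column of the expression matrix under a
#' single shared [split_plan] and calls noisy genes with [call_noisy_genes].
#' Per-gene optimiser seeds are derived deterministically from `seed` and the
#' gene name, so results do not depend on gene processing order. Genes whose
#' fit fails on any split are excluded from the FDR step and reported.
#'
#' @param values N x G matrix of normalised expression (or a
#'   `normalized_expression` object).
#' @param coords N x 2 spot coordinates (taken from `values` if it is a
#'   `normalized_expression`).
#' @param plan a [split_plan]; by default 10 repeats of a 90/10 split seeded
#'   by `seed`.
#' @param alpha FDR level for the noisy call.
#' @param n_restarts optimiser restarts per fit.
#' @param seed base seed for the split plan and per-gene restarts.
#' @param maxit L-BFGS-B iteration cap.
#' @param verbose print progress every 25 genes.
#' @return A list with `results` (the [call_noisy_genes] data frame),
#'   `nlpd` (per-gene NLPD vectors), `failed` (data frame of failed genes)
#'   and `plan`.
#' @export
noise_variation_test <- function(values, coords = NULL, plan = NULL,
                                 alpha = 0.05, n_restarts = 2, seed = 1,
                                 maxit = 100, verbose = FALSE) {
  if (inherits(values, "normalized_expression")) {
    coords <- values$coords
    values <- values$values
  }
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("gene_", seq_len(ncol(values)))
  plan <- plan %||% split_plan(nrow(values), seed = seed)
  D2 <- cross_sq_dists(coords, coords)
  nlpds <- list()
  failed <- list()
  for (g in colnames(values)) {
    y <- values[, g]
    if (stats::var(y) == 0) {
      failed[[g]] <- "zero variance across spots"
      next
    }
    r <- tryCatch(
      evaluate_gene(y, plan = plan, n_restarts = n_restarts,
                    seed = derive_seed(seed, g), sq_dists = D2,
                    maxit = maxit),
      error = function(e) e)
    if (inherits(r, "error")) {
      failed[[g]] <- conditionMessage(r)
    } else {
      nlpds[[g]] <- r
    }
    if (verbose && (length(nlpds) + length(failed)) %% 25 == 0)
      message("  tested ", length(nlpds) + length(failed), "/", ncol(values),
              " genes")
  }
  if (length(nlpds) == 0) stop("no gene could be tested")
  failed_df <- data.frame(gene = as.character(names(failed)),
                          reason = as.character(unlist(failed, use.names = FALSE)),
                          stringsAsFactors = FALSE)
  list(results = call_noisy_genes(nlpds, alpha = alpha),
       nlpd = nlpds,
       failed = failed_df,
       plan = plan)
}
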