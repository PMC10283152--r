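#' Variance residuals for the heteroscedastic approximation
#'
#' For each spot, the difference between the one-sample empirical variance
#' around the first-stage posterior mean and the posterior variance at that
#' spot: `z_i = (y_i - mu_GP_i)^2 - Sigma_GP(i,i)`. In expectation `z_i`
#' estimates the local noise variance, so a smooth spatial trend in `z`
#' indicates heteroscedastic noise.
#'
#' @param y expression vector at the training spots.
#' @param posterior a [gp_posterior] evaluated at the same spots.
#' @return A list with `z` (length N) and `coords`.
#' @export
variance_residuals <- function(y, posterior) {
  y <- as.numeric(y)
  if (length(y) != length(posterior$mean))
    stop("y and posterior have different numbers of spots")
  z <- (y - posterior$mean)^2 - posterior$var
  list(z = z, coords = posterior$query_coords)
}

# Internal per-split engine shared by fit_hgp() and evaluate_gene().
# Fits stage 1 (homoscedastic GP on y) and stage 2 (zero-mean GP on z), then
# predicts at query locations given cross-distances. All distance matrices
# are squared distances.
.hgp_fit_core <- function(y, D2_tt, n_restarts, seed, maxit = 100) {
  p1 <- fit_homoscedastic_gp(y, sq_dists = D2_tt, n_restarts = n_restarts,
                             seed = seed, maxit = maxit)
  fac1 <- .gp_factorize(y, D2_tt, p1)
  tr <- .gp_predict(fac1, D2_tt, diag_only = TRUE)
  z <- (y - tr$mean)^2 - tr$var
  p2 <- fit_homoscedastic_gp(z, sq_dists = D2_tt,
                             n_restarts = n_restarts,
                             seed = if (is.null(seed)) NULL else seed + 1L,
                             mean_fixed = 0, maxit = maxit)
  fac2 <- .gp_factorize(z, D2_tt, p2)
  list(p1 = p1, fac1 = fac1, train_mean = tr$mean, train_var = tr$var,
       z = z, p2 = p2, fac2 = fac2)
}

# Held-out prediction. `variance` is the plug-in combination
# max(0, var_GP(q) + mu_GPv(q)); `variance_floored` additionally bounds the
# noise-variance estimate below by its own stage-2 posterior standard
# deviation. The plug-in estimate can dip to (clipped) zero wherever the
# stage-2 posterior mean undershoots, and a near-zero predictive variance
# makes the log predictive density explode on ordinary residuals; an
# estimate smaller than its own standard error carries no evidence that the
# noise really vanishes, so the density evaluation path uses the floored
# version.
.hgp_predict_core <- function(core, D2_qt) {
  s1 <- .gp_predict(core$fac1, D2_qt, diag_only = TRUE)
  s2 <- .gp_predict(core$fac2, D2_qt, diag_only = TRUE)
  plug <- pmax(0, s1$var + s2$mean)
  list(mean = s1$mean,
       var_latent = s1$var,
       variance = plug,
       variance_floored = pmax(plug, s1$var + sqrt(s2$var)))
}

#' Fit an approximate heteroscedastic GP
#'
#' Two-stage approximation: (1) fit a homoscedastic GP to the expression and
#' take its posterior mean/variance at the training spots; (2) fit a second,
#' zero-mean homoscedastic GP (kernel `Sigma_kv`, noise `sigma_nv2`) to the
#' variance residuals `z` from [variance_residuals]. The combined model keeps
#' the first-stage mean and refines only the variance:
#' `mu_HGP = mu_GP`, `sigma_HGP2 = max(0, diag(Sigma_GP) + mu_GPv)`.
#'
#' @param y expression vector (N >= 20 spots).
#' @param coords N x 2 spot coordinates.
#' @param n_restarts,seed,maxit passed to [fit_homoscedastic_gp] (the stage-2
#'   fit uses `seed + 1`).
#' @return An object of class `hgp_fit` with fields `mean` (`mu_HGP`),
#'   `noise_variance` (`sigma_HGP2`, clipped at 0), `z`, `gp_params`
#'   (stage 1) and `variance_gp_params` (stage 2).
#' @export
fit_hgp <- function(y, coords, n_restarts = 2, seed = NULL, maxit = 100) {
  y <- as.numeric(y)
  coords <- as.matrix(coords)
  if (length(y) < 20)
    stop("the two-stage heteroscedastic fit needs at least 20 spots")
  D2 <- cross_sq_dists(coords, coords)
  core <- withCallingHandlers(
    .hgp_fit_core(y, D2, n_restarts, seed, maxit),
    error = function(e) stop("heteroscedastic fit failed: ",
                             conditionMessage(e), call. = FALSE))
  s2 <- .gp_predict(core$fac2, D2, diag_only = TRUE)
  structure(list(mean = core$train_mean,
                 noise_variance = pmax(0, core$train_var + s2$mean),
                 z = core$z,
                 coords = coords, y = y,
                 gp_params = core$p1,
                 variance_gp_params = core$p2,
                 core = core),
            class = "hgp_fit")
}

#' @export
print.hgp_fit <- function(x, ...) {
  cat("hgp_fit over", length(x$mean), "spots\n")
  cat("  stage-1 "); print(x$gp_params)
  cat("  stage-2 "); print(x$variance_gp_params)
  invisible(x)
}

#' Predict mean and variance from a heteroscedastic fit
#'
#' The mean comes from the stage-1 GP posterior; the variance is the clipped
#' sum of the stage-1 latent posterior variance and the stage-2 posterior
#' mean of the variance residuals at the query locations,
#' `max(0, var_GP(q) + mu_GPv(q))`.
#'
#' @param fit an [fit_hgp] result.
#' @param query_coords P x 2 query coordinates.
#' @param uncertainty_floor if `TRUE` (the default, used when evaluating
#'   predictive densities) the noise-variance estimate is bounded below by
#'   its stage-2 posterior standard deviation, preventing spuriously
#'   overconfident near-zero variance predictions; `FALSE` gives the raw
#'   plug-in combination, which at the training spots reproduces
#'   `fit$noise_variance` exactly.
#' @return A list with `mean` and `variance` (length P each).
#' @export
hgp_predict <- function(fit, query_coords, uncertainty_floor = TRUE) {
  stopifnot(inherits(fit, "hgp_fit"))
  D2_qt <- cross_sq_dists(as.matrix(query_coords), fit$coords)
  pr <- .hgp_predict_core(fit$core, D2_qt)
  list(mean = pr$mean,
       variance = if (uncertainty_floor) pr$variance_floored else pr$variance)
}
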