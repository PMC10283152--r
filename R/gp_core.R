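#' GP hyperparameters for a single gene
#'
#' A constant-mean RBF-kernel Gaussian process is parameterised by the prior
#' mean `mu_c` (expression units), the kernel variance `sigma_k2`, the
#' length-scale `length_scale` (coordinate units) and the i.i.d. noise
#' variance `sigma_n2`.
#'
#' @param mu_c constant prior mean.
#' @param sigma_k2 kernel (signal) variance, > 0.
#' @param length_scale RBF length-scale, > 0.
#' @param sigma_n2 noise variance, >= 0.
#' @return An object of class `gp_hyperparams`.
#' @export
gp_hyperparams <- function(mu_c, sigma_k2, length_scale, sigma_n2) {
  stopifnot(is.finite(mu_c), is.finite(sigma_k2), is.finite(length_scale),
            is.finite(sigma_n2))
  if (sigma_k2 <= 0) stop("sigma_k2 must be positive")
  if (length_scale <= 0) stop("length_scale must be positive")
  if (sigma_n2 < 0) stop("sigma_n2 must be nonnegative")
  structure(list(mu_c = mu_c, sigma_k2 = sigma_k2,
                 length_scale = length_scale, sigma_n2 = sigma_n2),
            class = "gp_hyperparams")
}

#' @export
print.gp_hyperparams <- function(x, ...) {
  cat(sprintf("gp_hyperparams: mu_c=%.4g sigma_k2=%.4g length_scale=%.4g sigma_n2=%.4g\n",
              x$mu_c, x$sigma_k2, x$length_scale, x$sigma_n2))
  if (!is.null(attr(x, "nlml")))
    cat(sprintf("  negative log marginal likelihood: %.6g\n", attr(x, "nlml")))
  invisible(x)
}

# Squared Euclidean cross-distances between the rows of two N x 2 matrices.
cross_sq_dists <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Radial basis function kernel
#'
#' `K(a, b) = sigma_k2 * exp(-||a - b||^2 / (2 * length_scale^2))`, evaluated
#' between all row pairs of two coordinate matrices. Nearby spots therefore
#' receive high prior covariance, encoding the assumption that expression
#' varies smoothly across the tissue.
#'
#' @param A,B coordinate matrices (M x 2 and P x 2).
#' @param sigma_k2 kernel variance, > 0.
#' @param length_scale length-scale, > 0.
#' @return An M x P covariance matrix.
#' @export
rbf_kernel <- function(A, B, sigma_k2, length_scale) {
  if (!is.finite(sigma_k2) || sigma_k2 <= 0)
    stop("sigma_k2 must be positive")
  if (!is.finite(length_scale) || length_scale <= 0)
    stop("length_scale must be positive")
  A <- as.matrix(A); B <- as.matrix(B)
  if (any(!is.finite(A)) || any(!is.finite(B)))
    stop("coordinates must be finite")
  sigma_k2 * exp(-cross_sq_dists(A, B) / (2 * length_scale^2))
}

# Relative diagonal jitter applied before every Cholesky factorisation.
.gp_jitter <- 1e-6

#' Negative log marginal likelihood of a homoscedastic GP
#'
#' \deqn{L_1 = \tfrac12 (y-\mu)^\top (\Sigma_k + \sigma_n^2 I)^{-1} (y-\mu)
#'   + \tfrac12 \log|\Sigma_k + \sigma_n^2 I| + \tfrac{N}{2}\log 2\pi}
#' with \eqn{\mu} the constant vector of `mu_c`, computed via a Cholesky
#' factorisation with a relative diagonal jitter of `1e-6 * sigma_k2`.
#'
#' @param y expression vector (length N >= 2).
#' @param coords N x 2 spot coordinates (ignored when `sq_dists` is given).
#' @param params a [gp_hyperparams] object.
#' @param sq_dists optional precomputed N x N squared-distance matrix.
#' @return The scalar negative log marginal likelihood.
#' @export
negative_log_marginal_likelihood <- function(y, coords, params,
                                             sq_dists = NULL) {
  y <- as.numeric(y)
  stopifnot(length(y) >= 2, inherits(params, "gp_hyperparams"))
  D2 <- sq_dists %||% cross_sq_dists(coords, coords)
  res <- gp_nlml_grad_cpp(y, D2, params$mu_c, log(params$sigma_k2),
                          log(params$length_scale),
                          log(max(params$sigma_n2, .Machine$double.xmin)),
                          .gp_jitter, FALSE)
  if (!res$ok)
    stop("kernel matrix not positive definite after jitter")
  res$value
}

#' Fit a homoscedastic GP by marginal-likelihood minimisation
#'
#' Hyperparameters (`mu_c`, `sigma_k2`, `length_scale`, `sigma_n2`) are
#' optimised jointly with L-BFGS-B, the scale parameters in log-space to
#' enforce positivity, using analytic gradients. The default initialisation
#' is scale-aware: `mu_c = mean(y)`, `sigma_k2 = sigma_n2 = var(y)/2`,
#' `length_scale` = median pairwise spot distance; additional restarts
#' perturb the log-scale parameters log-uniformly within a factor of 4.
#'
#' @param y expression vector with nonzero variance.
#' @param coords N x 2 spot coordinates.
#' @param init optional [gp_hyperparams] initialisation.
#' @param n_restarts total number of optimiser starts (first = `init`).
#' @param seed optional seed controlling the restart perturbations.
#' @param sq_dists optional precomputed squared-distance matrix.
#' @param mean_fixed if non-NULL, `mu_c` is fixed at this value (used for the
#'   zero-mean variance GP) and not optimised.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return A [gp_hyperparams] with attribute `"nlml"` (the achieved value).
#' @export
fit_homoscedastic_gp <- function(y, coords = NULL, init = NULL,
                                 n_restarts = 2, seed = NULL,
                                 sq_dists = NULL, mean_fixed = NULL,
                                 maxit = 100) {
  y <- as.numeric(y)
  if (length(y) < 2 || stats::var(y) == 0)
    stop("y must have at least 2 values and nonzero variance")
  D2 <- sq_dists %||% cross_sq_dists(coords, coords)
  v <- stats::var(y)
  med_d <- stats::median(sqrt(D2[upper.tri(D2)]))
  if (!is.finite(med_d) || med_d <= 0) med_d <- 1
  fixed <- !is.null(mean_fixed)
  if (is.null(init)) {
    init <- gp_hyperparams(if (fixed) mean_fixed else mean(y),
                           v / 2, med_d, v / 2)
  }
  theta0 <- c(init$mu_c, log(init$sigma_k2), log(init$length_scale),
              log(max(init$sigma_n2, 1e-12)))

  # Cache the (value, gradient) pair so optim's separate fn/gr calls cost one
  # factorisation.
  cache <- new.env(parent = emptyenv())
  eval_at <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (!identical(cache$key, key)) {
      r <- gp_nlml_grad_cpp(y, D2, theta[1], theta[2], theta[3], theta[4],
                            .gp_jitter, fixed)
      cache$key <- key
      cache$val <- r
    }
    cache$val
  }
  fn <- function(theta) eval_at(theta)$value
  gr <- function(theta) {
    g <- eval_at(theta)$gradient
    if (fixed) g[1] <- 0
    g
  }

  starts <- list(theta0)
  if (n_restarts > 1) {
    perturb <- with_seed(seed, function() {
      lapply(seq_len(n_restarts - 1), function(i)
        theta0 + c(0, stats::runif(3, -log(4), log(4))))
    })
    starts <- c(starts, perturb)
  }

  best <- NULL
  failures <- character(0)
  for (th in starts) {
    fit <- tryCatch(
      stats::optim(th, fn, gr, method = "L-BFGS-B",
                   lower = c(-Inf, log(1e-10), log(med_d * 1e-4), log(1e-12)),
                   upper = c(Inf, log(v * 1e6 + 1), log(med_d * 1e4), log(v * 1e6 + 1)),
                   control = list(maxit = maxit)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, conditionMessage(fit))
      next
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("GP optimisation failed on all starts: ",
         paste(unique(failures), collapse = "; "))
  # Never return a start-point-worse solution.
  if (best$value > fn(theta0)) {
    best <- list(par = theta0, value = fn(theta0))
  }
  out <- gp_hyperparams(if (fixed) mean_fixed else best$par[1],
                        exp(best$par[2]), exp(best$par[3]), exp(best$par[4]))
  attr(out, "nlml") <- best$value
  out
}

# Shared Cholesky machinery: factorise Ky = sigma_k2*E + (sigma_n2+jitter)*I
# on the training set and return the pieces needed for prediction.
.gp_factorize <- function(y, D2_tt, params) {
  n <- length(y)
  Ky <- params$sigma_k2 * exp(-D2_tt / (2 * params$length_scale^2))
  diag(Ky) <- diag(Ky) + params$sigma_n2 + .gp_jitter * params$sigma_k2
  L <- tryCatch(t(chol(Ky)), error = function(e) {
    ev <- min(eigen(Ky, symmetric = TRUE, only.values = TRUE)$values)
    stop("kernel matrix not positive definite after jitter (smallest eigenvalue ",
         format(ev), ")")
  })
  r <- y - params$mu_c
  alpha <- backsolve(t(L), forwardsolve(L, r))
  list(L = L, alpha = alpha, params = params)
}

# Predictive mean / covariance given a factorisation and cross-distances.
# Returns the latent-function posterior (no observation noise added).
.gp_predict <- function(fac, D2_qt, D2_qq = NULL, diag_only = TRUE) {
  p <- fac$params
  Kqt <- p$sigma_k2 * exp(-D2_qt / (2 * p$length_scale^2))
  mean <- p$mu_c + as.numeric(Kqt %*% fac$alpha)
  V <- forwardsolve(fac$L, t(Kqt))
  if (diag_only) {
    var <- pmax(p$sigma_k2 - colSums(V^2), 0)
    list(mean = mean, var = var)
  } else {
    Kqq <- p$sigma_k2 * exp(-D2_qq / (2 * p$length_scale^2))
    cov <- Kqq - crossprod(V)
    cov <- (cov + t(cov)) / 2
    list(mean = mean, cov = cov, var = pmax(diag(cov), 0))
  }
}

#' GP posterior at training or held-out locations
#'
#' Conditions the fitted prior GP on the observations. When
#' `query_coords` equals the training coordinates this reproduces the
#' standard posterior
#' \eqn{\mu_{GP} = \mu + \Sigma_k(\Sigma_k+\sigma_n^2 I)^{-1}(y-\mu)},
#' \eqn{\Sigma_{GP} = \Sigma_k - \Sigma_k(\Sigma_k+\sigma_n^2 I)^{-1}\Sigma_k};
#' held-out locations use the cross-covariance form. The returned covariance
#' is that of the latent function (add `sigma_n2` for the predictive variance
#' of a new observation).
#'
#' @param y training expression vector.
#' @param coords N x 2 training coordinates.
#' @param params fitted [gp_hyperparams].
#' @param query_coords P x 2 query coordinates (default: the training spots).
#' @return A list with `mean` (length P), `cov` (P x P) and `var`
#'   (its clipped diagonal), of class `gp_posterior`.
#' @export
gp_posterior <- function(y, coords, params, query_coords = coords) {
  y <- as.numeric(y)
  coords <- as.matrix(coords)
  query_coords <- as.matrix(query_coords)
  fac <- .gp_factorize(y, cross_sq_dists(coords, coords), params)
  pr <- .gp_predict(fac, cross_sq_dists(query_coords, coords),
                    cross_sq_dists(query_coords, query_coords),
                    diag_only = FALSE)
  structure(list(mean = pr$mean, cov = pr$cov, var = pr$var,
                 train_coords = coords, query_coords = query_coords,
                 params = params),
            class = "gp_posterior")
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat("gp_posterior over", length(x$mean), "locations\n")
  invisible(x)
}
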