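# Independent brute-force oracles used to validate the package's numerics.
# These deliberately use naive dense linear algebra / exhaustive enumeration,
# not the code paths they check.

.jit <- 1e-6

oracle_kernel <- function(A, B, sk2, l) {
  K <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      K[i, j] <- sk2 * exp(-sum((A[i, ] - B[j, ])^2) / (2 * l^2))
    }
  }
  K
}

# Dense explicit-inverse negative log marginal likelihood (same jitter
# convention as the package: 1e-6 * sigma_k2 on the diagonal).
oracle_nlml <- function(y, coords, p) {
  n <- length(y)
  Ky <- oracle_kernel(coords, coords, p$sigma_k2, p$length_scale) +
    diag(p$sigma_n2 + .jit * p$sigma_k2, n)
  r <- y - p$mu_c
  0.5 * drop(t(r) %*% solve(Ky) %*% r) +
    0.5 * determinant(Ky, logarithm = TRUE)$modulus[1] +
    n / 2 * log(2 * pi)
}

# Dense posterior via explicit inverse, at arbitrary query points.
oracle_posterior <- function(y, coords, p, query) {
  Ky <- oracle_kernel(coords, coords, p$sigma_k2, p$length_scale) +
    diag(p$sigma_n2 + .jit * p$sigma_k2, length(y))
  Kqt <- oracle_kernel(query, coords, p$sigma_k2, p$length_scale)
  Kqq <- oracle_kernel(query, query, p$sigma_k2, p$length_scale)
  Kinv <- solve(Ky)
  list(mean = p$mu_c + drop(Kqt %*% Kinv %*% (y - p$mu_c)),
       cov = Kqq - Kqt %*% Kinv %*% t(Kqt))
}

# Exact one-sided ("less") signed-rank p-value by enumerating every sign
# assignment of the rank vector (feasible for n <= 14).
oracle_signed_rank_less <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  mean(w_all <= w_obs + 1e-12)
}

# Exhaustive Otsu: directly maximise the between-class variance over the
# interior bin-edge thresholds, computing class statistics from raw values.
oracle_otsu <- function(values, n_bins = 256) {
  edges <- seq(min(values), max(values), length.out = n_bins + 1)
  cand <- edges[2:n_bins]
  bcv <- vapply(cand, function(thr) {
    lo <- values[values <= thr]
    hi <- values[values > thr]
    # match the package's bin-membership convention at exact edges
    if (length(lo) == 0 || length(hi) == 0) return(-Inf)
    (length(lo) / length(values)) * (length(hi) / length(values)) *
      (mean(lo) - mean(hi))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

# Adjusted Rand index between two label vectors.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

random_params <- function() {
  gp_hyperparams(mu_c = rnorm(1), sigma_k2 = exp(runif(1, -2, 2)),
                 length_scale = exp(runif(1, -1, 2)),
                 sigma_n2 = exp(runif(1, -4, 1)))
}
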