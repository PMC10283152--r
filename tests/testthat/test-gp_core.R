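test_that("rbf_kernel matches its closed form", {
  A <- cbind(c(0, 1, 3), c(0, 0, 4))
  expect_equal(diag(rbf_kernel(A, A, 2.5, 1.3)), rep(2.5, 3))
  # distance exactly one length-scale -> sigma_k2 * exp(-1/2)
  B <- rbind(c(1.3, 0))
  expect_equal(rbf_kernel(rbind(c(0, 0)), B, 2, 1.3)[1, 1], 2 * exp(-0.5))
  # far-field limit
  expect_lt(rbf_kernel(rbind(c(0, 0)), rbind(c(0, 1e4)), 1, 1)[1, 1],
            .Machine$double.eps)
  # symmetry and PSD on a random set
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2)
  K <- rbf_kernel(X, X, 1.7, 0.8)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_error(rbf_kernel(X, X, -1, 1), "sigma_k2")
  expect_error(rbf_kernel(X, X, 1, 0), "length_scale")
})

test_that("marginal likelihood agrees with the dense explicit-inverse oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    coords <- matrix(runif(2 * n, 0, 10), n, 2)
    p <- random_params()
    y <- rnorm(n)
    expect_equal(negative_log_marginal_likelihood(y, coords, p),
                 oracle_nlml(y, coords, p), tolerance = 1e-9)
  }
  # zero residual: quadratic term vanishes
  coords <- matrix(runif(20), 10, 2)
  p <- gp_hyperparams(2, 1, 0.5, 0.3)
  y <- rep(2, 10)
  Ky <- oracle_kernel(coords, coords, 1, 0.5) + diag(0.3 + 1e-6, 10)
  expect_equal(negative_log_marginal_likelihood(y, coords, p),
               0.5 * determinant(Ky)$modulus[1] + 5 * log(2 * pi),
               tolerance = 1e-9)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(7)
  n <- 25
  coords <- matrix(runif(2 * n, 0, 5), n, 2)
  y <- rnorm(n, sd = 1.4)
  for (rep in 1:5) {
    theta <- c(rnorm(1), runif(3, -1, 1))
    D2 <- novatest:::cross_sq_dists(coords, coords)
    g <- novatest:::gp_nlml_grad_cpp(y, D2, theta[1], theta[2], theta[3],
                                     theta[4], 1e-6, FALSE)$gradient
    h <- 1e-5
    for (k in 1:4) {
      up <- dn <- theta
      up[k] <- up[k] + h; dn[k] <- dn[k] - h
      fd <- (novatest:::gp_nlml_grad_cpp(y, D2, up[1], up[2], up[3], up[4],
                                         1e-6, FALSE)$value -
             novatest:::gp_nlml_grad_cpp(y, D2, dn[1], dn[2], dn[3], dn[4],
                                         1e-6, FALSE)$value) / (2 * h)
      expect_equal(g[k], fd, tolerance = 1e-4)
    }
  }
})

test_that("fitting never returns worse than its initialisation", {
  set.seed(11)
  g <- simulate_gene(sim_spec(n_spots = 60, seed = 11))
  init <- gp_hyperparams(mean(g$y), var(g$y) / 2, 2, var(g$y) / 2)
  fit <- fit_homoscedastic_gp(g$y, g$coords, init = init, seed = 1)
  expect_lte(attr(fit, "nlml"),
             negative_log_marginal_likelihood(g$y, g$coords, init) + 1e-8)
  expect_error(fit_homoscedastic_gp(rep(1, 30), g$coords[1:30, ]),
               "variance")
})

test_that("length-scale is recovered within a factor of 2 (median of reps)", {
  ratios <- vapply(1:20, function(s) {
    g <- simulate_gene(sim_spec(
      n_spots = 200, noise_fn = list(kind = "constant", v = 0.25), seed = s))
    fit <- fit_homoscedastic_gp(g$y, g$coords, seed = s)
    fit$length_scale / 3
  }, numeric(1))
  med <- median(ratios)
  expect_gt(med, 0.5)
  expect_lt(med, 2)
})

test_that("white noise decomposes into sigma_k2 + sigma_n2 ~ var(y)", {
  ratios <- vapply(1:10, function(s) {
    set.seed(100 + s)
    coords <- matrix(runif(300, 0, 12), 150, 2)
    y <- rnorm(150, sd = 2)
    fit <- fit_homoscedastic_gp(y, coords, seed = s)
    (fit$sigma_k2 + fit$sigma_n2) / var(y)
  }, numeric(1))
  expect_lt(abs(median(ratios) - 1), 0.2)
})

test_that("posterior matches the dense oracle at train and held-out points", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(4:30, 1)
    coords <- matrix(runif(2 * n, 0, 6), n, 2)
    query <- matrix(runif(8, 0, 6), 4, 2)
    p <- random_params()
    y <- rnorm(n)
    post <- gp_posterior(y, coords, p, query)
    oo <- oracle_posterior(y, coords, p, query)
    expect_equal(post$mean, oo$mean, tolerance = 1e-8)
    expect_equal(post$cov, (oo$cov + t(oo$cov)) / 2, tolerance = 1e-8)
  }
})

test_that("posterior limits: interpolation and prior reversion", {
  set.seed(5)
  coords <- matrix(runif(30, 0, 5), 15, 2)
  y <- rnorm(15)
  # sigma_n2 = 0: interpolates up to the jitter scale
  p0 <- gp_hyperparams(0, 1, 1, 0)
  post <- gp_posterior(y, coords, p0)
  expect_equal(post$mean, y, tolerance = 1e-3)
  expect_lt(max(post$var), 1e-4)
  # huge sigma_n2: mean reverts to the prior mean
  pinf <- gp_hyperparams(0.7, 1, 1, 1e8)
  expect_equal(gp_posterior(y, coords, pinf)$mean, rep(0.7, 15),
               tolerance = 1e-4)
})

test_that("posterior variance never exceeds the prior variance", {
  set.seed(6)
  for (rep in 1:5) {
    coords <- matrix(runif(40, 0, 5), 20, 2)
    query <- matrix(runif(20, -1, 6), 10, 2)
    p <- random_params()
    post <- gp_posterior(rnorm(20), coords, p, query)
    expect_lte(max(post$var), p$sigma_k2 * (1 + 1e-6) + 1e-10)
  }
})

test_that("posterior is equivariant under rigid translation", {
  set.seed(8)
  coords <- matrix(runif(36, 0, 4), 18, 2)
  y <- rnorm(18)
  p <- gp_hyperparams(0.2, 1.5, 1.2, 0.4)
  shift <- c(13.7, -4.2)
  a <- gp_posterior(y, coords, p)
  b <- gp_posterior(y, sweep(coords, 2, shift, `+`), p)
  expect_equal(a$mean, b$mean, tolerance = 1e-10)
  expect_equal(a$cov, b$cov, tolerance = 1e-10)
})
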