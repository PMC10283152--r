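test_that("nlpd matches hand evaluation", {
  # single point, exact prediction, unit variance
  expect_equal(nlpd(1, 1, 1), 0.5 * log(2 * pi))
  # variance 1/(2*pi) makes the log term vanish
  expect_equal(nlpd(2, 2, 1 / (2 * pi)), 0)
  # three points, hand-summed
  y <- c(1, 2, 3); m <- c(0.5, 2, 4); v <- c(0.25, 1, 4)
  by_hand <- mean(0.5 * (log(2 * pi * v) + (y - m)^2 / v))
  expect_equal(nlpd(y, m, v), by_hand, tolerance = 1e-12)
  expect_error(nlpd(1, 1, NaN), "variance")
})

test_that("split plans partition the spots reproducibly", {
  plan <- split_plan(100, n_repeats = 10, train_fraction = 0.9, seed = 5)
  expect_length(plan$splits, 10)
  for (s in plan$splits) {
    expect_equal(sort(c(s$train, s$validation)), 1:100)
    expect_length(s$validation, 10)
  }
  expect_equal(split_plan(100, seed = 5)$splits, plan$splits)
  expect_false(identical(split_plan(100, seed = 6)$splits, plan$splits))
  expect_error(split_plan(10, train_fraction = 0.95), "fewer than 2")
})

test_that("signed-rank p-values are exact", {
  # all a < b with no rank ties: p = 1/2^10
  a <- rep(0, 10); b <- 1:10
  expect_equal(wilcoxon_signed_rank(a, b, "less"), 1 / 1024)
  # identical vectors: no evidence
  expect_equal(wilcoxon_signed_rank(1:6, 1:6), 1)
  # random pairs vs full 2^R enumeration
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:11, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(wilcoxon_signed_rank(a, b, "less"),
                 oracle_signed_rank_less(a, b), tolerance = 1e-12)
  }
  # ties in |differences| are handled by average ranks in both routes
  a <- c(1, 2, 3, 4, 5, 6); b <- c(2, 1, 5, 2, 4, 8)
  expect_equal(wilcoxon_signed_rank(a, b, "less"),
               oracle_signed_rank_less(a, b), tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(9)
  p <- runif(50)^2
  # order equivariance
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  # agreement with the reference implementation
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
})

test_that("evaluate_gene is deterministic and prefers the right model", {
  plan <- split_plan(150, seed = 21)
  het <- simulate_gene(sim_spec(
    n_spots = 150,
    noise_fn = list(kind = "step", v_low = 0.1, v_high = 0.9, axis = "diag"),
    seed = 77))
  r1 <- evaluate_gene(het$y, het$coords, plan, seed = 7)
  r2 <- evaluate_gene(het$y, het$coords, plan, seed = 7)
  expect_identical(r1, r2)
  expect_gte(sum(r1$nlpd_hetero < r1$nlpd_homo), 8)
  expect_error(evaluate_gene(rep(1, 150), het$coords, plan), "zero variance")
})

test_that("NLPD differences show no systematic sign on null genes", {
  # scaled-down null cohort (30 genes at N = 100); the full-size calibration
  # claim is exercised in test-acceptance.R
  co <- simulate_cohort(30, 0, spec_null = sim_spec(n_spots = 100), seed = 31)
  plan <- split_plan(100, seed = 31)
  D2 <- novatest:::cross_sq_dists(co$coords, co$coords)
  deltas <- vapply(colnames(co$values), function(g) {
    r <- evaluate_gene(co$values[, g], plan = plan, sq_dists = D2,
                       seed = novatest:::derive_seed(31, g))
    mean(r$nlpd_hetero - r$nlpd_homo)
  }, numeric(1))
  # one-sided: the heteroscedastic model must not look systematically
  # *better* on null genes (systematically worse is conservative and fine)
  bt <- binom.test(sum(deltas < 0), length(deltas), alternative = "greater")
  expect_gt(bt$p.value, 0.01)
})

test_that("call_noisy_genes applies Wilcoxon + BH with a strict threshold", {
  nl <- list(
    up = list(nlpd_homo = 1:10 + 0.5, nlpd_hetero = 1:10),       # hetero better
    same = list(nlpd_homo = 1:10, nlpd_hetero = 1:10),
    down = list(nlpd_homo = 1:10, nlpd_hetero = 1:10 + 0.5))
  res <- call_noisy_genes(nl, alpha = 0.05)
  expect_equal(res$p_value[res$gene == "up"], 1 / 1024)
  expect_equal(res$p_value[res$gene == "same"], 1)
  expect_equal(res$q_value, bh_fdr(res$p_value))
  expect_equal(res$is_noisy, res$q_value < 0.05)
  # alpha = 0 flags nothing
  expect_false(any(call_noisy_genes(nl, alpha = 0)$is_noisy))
  # identical data -> identical q
  res2 <- call_noisy_genes(list(a = nl$up, b = nl$up, c = nl$up))
  expect_length(unique(res2$q_value), 1)
})

test_that("gene processing order does not change the verdicts", {
  co <- simulate_cohort(4, 2, spec_null = sim_spec(n_spots = 80),
                        spec_noisy = sim_spec(
                          n_spots = 80,
                          noise_fn = list(kind = "step", v_low = 0.1,
                                          v_high = 0.9, axis = 1)),
                        seed = 17)
  plan <- split_plan(80, seed = 17)
  fwd <- noise_variation_test(co$values, co$coords, plan = plan, seed = 17)
  rev_in <- noise_variation_test(co$values[, rev(colnames(co$values))],
                                 co$coords, plan = plan, seed = 17)
  rr <- rev_in$results[match(fwd$results$gene, rev_in$results$gene), ]
  expect_equal(fwd$results$p_value, rr$p_value)
  expect_equal(fwd$results$mean_nlpd_hetero, rr$mean_nlpd_hetero)
})
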