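#' Specification of one simulated spatial gene
#'
#' Describes the world a simulated gene is drawn from: the spot layout, the
#' smooth spatial mean field and the noise-variance field. Defaults encode a
#' typical array-based ST geometry (unit-spaced grid) with a GP-smooth mean
#' (`sigma_k2 = 1`, length-scale 3 array units) and, for heteroscedastic
#' genes, a linear variance ramp with a 9:1 high/low ratio.
#'
#' @param n_spots number of spots (>= 20).
#' @param grid `"square"`, `"hexagonal"` or `"random"` spot layout.
#' @param mean_fn list describing the mean field: `kind` one of `"gp"`
#'   (fields `sigma_k2`, `length_scale`, `mu`), `"constant"` (field `value`)
#'   or `"ramp"` (fields `low`, `high`, `axis`).
#' @param noise_fn list describing the noise-variance field: `kind` one of
#'   `"constant"` (field `v`), `"ramp"` (fields `v_low`, `v_high`, `axis`
#'   where axis 1/2 ramps along x1/x2 and `"diag"` ramps along x2 - x1),
#'   `"step"` (fields `v_low`, `v_high`, `axis`; high variance on the upper
#'   half of the axis) or `"gp-log-variance"` (fields `sigma_k2`,
#'   `length_scale`, `base_v`).
#' @param seed RNG seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_spots = 200, grid = c("square", "hexagonal", "random"),
                     mean_fn = list(kind = "gp", sigma_k2 = 1,
                                    length_scale = 3, mu = 0),
                     noise_fn = list(kind = "constant", v = 0.25),
                     seed = 1) {
  grid <- match.arg(grid)
  stopifnot(n_spots >= 20)
  vs <- unlist(noise_fn[names(noise_fn) %in% c("v", "v_low", "v_high", "base_v")])
  if (any(vs <= 0)) stop("noise variances must be positive")
  structure(list(n_spots = n_spots, grid = grid, mean_fn = mean_fn,
                 noise_fn = noise_fn, seed = seed),
            class = "sim_spec")
}

#' Spot coordinates for a simulation
#'
#' Square grids use unit spacing (`ceiling(sqrt(n))` columns); hexagonal
#' grids offset every other row by half a spacing with row pitch
#' `sqrt(3)/2`; random layouts sample uniformly from the unit square.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [sim_spec].
#' @return An N x 2 coordinate matrix with columns `x1`, `x2`.
#' @export
make_coords <- function(spec) {
  n <- spec$n_spots
  coords <- switch(spec$grid,
    square = {
      side <- ceiling(sqrt(n))
      g <- expand.grid(x1 = seq_len(side), x2 = seq_len(side))
      as.matrix(g[seq_len(n), ])
    },
    hexagonal = {
      side <- ceiling(sqrt(n))
      g <- expand.grid(col = seq_len(side), row = seq_len(side))
      g <- g[seq_len(n), ]
      cbind(x1 = g$col + (g$row %% 2) / 2, x2 = g$row * sqrt(3) / 2)
    },
    random = with_seed(spec$seed, function() {
      cbind(x1 = stats::runif(n), x2 = stats::runif(n))
    }))
  coords <- as.matrix(coords)
  colnames(coords) <- c("x1", "x2")
  rownames(coords) <- paste0("spot_", seq_len(n))
  coords
}

.ramp01 <- function(coords, axis) {
  u <- switch(as.character(axis),
              "1" = coords[, 1],
              "2" = coords[, 2],
              "diag" = coords[, 2] - coords[, 1],
              stop("unknown axis: ", axis))
  r <- range(u)
  if (diff(r) == 0) rep(0.5, nrow(coords)) else (u - r[1]) / diff(r)
}

.sim_mean <- function(mean_fn, coords) {
  switch(mean_fn$kind,
    gp = {
      K <- rbf_kernel(coords, coords, mean_fn$sigma_k2, mean_fn$length_scale)
      diag(K) <- diag(K) + 1e-8 * mean_fn$sigma_k2
      (mean_fn$mu %||% 0) +
        as.numeric(t(chol(K)) %*% stats::rnorm(nrow(coords)))
    },
    constant = rep(mean_fn$value %||% 0, nrow(coords)),
    ramp = {
      t01 <- .ramp01(coords, mean_fn$axis %||% 1)
      (mean_fn$low %||% 0) + t01 * ((mean_fn$high %||% 1) - (mean_fn$low %||% 0))
    },
    stop("unknown mean_fn kind: ", mean_fn$kind))
}

.sim_var <- function(noise_fn, coords) {
  switch(noise_fn$kind,
    constant = rep(noise_fn$v, nrow(coords)),
    ramp = {
      t01 <- .ramp01(coords, noise_fn$axis %||% 1)
      noise_fn$v_low + t01 * (noise_fn$v_high - noise_fn$v_low)
    },
    step = {
      t01 <- .ramp01(coords, noise_fn$axis %||% 1)
      ifelse(t01 >= 0.5, noise_fn$v_high, noise_fn$v_low)
    },
    `gp-log-variance` = {
      K <- rbf_kernel(coords, coords, noise_fn$sigma_k2, noise_fn$length_scale)
      diag(K) <- diag(K) + 1e-8 * noise_fn$sigma_k2
      (noise_fn$base_v %||% 0.25) *
        exp(as.numeric(t(chol(K)) %*% stats::rnorm(nrow(coords))))
    },
    stop("unknown noise_fn kind: ", noise_fn$kind))
}

#' Simulate one gene's spatial expression
#'
#' Draws `y_i = f(x_i) + eps_i` with `eps_i ~ N(0, g(x_i))`, where the mean
#' field `f` and variance field `g` come from the spec. The ground-truth
#' fields are returned so that variance-recovery can be scored.
#'
#' @param spec a [sim_spec].
#' @param coords optional precomputed coordinates (default [make_coords]).
#' @return A list with `y`, `true_mean`, `true_var` and `coords`.
#' @export
simulate_gene <- function(spec, coords = NULL) {
  coords <- coords %||% make_coords(spec)
  with_seed(spec$seed, function() {
    true_mean <- .sim_mean(spec$mean_fn, coords)
    true_var <- .sim_var(spec$noise_fn, coords)
    y <- true_mean + stats::rnorm(nrow(coords), sd = sqrt(true_var))
    list(y = y, true_mean = true_mean, true_var = true_var, coords = coords)
  })
}

#' Simulate a cohort of null and noisy genes
#'
#' Independent genes on a shared spot layout: `n_null` genes from
#' `spec_null` (constant noise variance) and `n_noisy` genes from
#' `spec_noisy` (spatially varying noise variance). Per-gene seeds are
#' derived from the cohort seed so the cohort is reproducible and
#' order-independent.
#'
#' @param n_null,n_noisy numbers of genes of each kind.
#' @param spec_null,spec_noisy [sim_spec]s for the two kinds; they share the
#'   layout of `spec_null`.
#' @param seed cohort seed (overrides the specs' seeds).
#' @return A list with `values` (N x G matrix, genes named
#'   `null_*`/`noisy_*`), `coords`, `labels` (logical: TRUE = noisy),
#'   `true_mean` and `true_var` (N x G matrices).
#' @export
simulate_cohort <- function(n_null, n_noisy,
                            spec_null = sim_spec(),
                            spec_noisy = sim_spec(
                              noise_fn = list(kind = "ramp", v_low = 0.1,
                                              v_high = 0.9, axis = "diag")),
                            seed = 1) {
  stopifnot(n_null >= 0, n_noisy >= 0, n_null + n_noisy >= 1)
  coords <- make_coords(spec_null)
  gene_names <- c(if (n_null > 0) sprintf("null_%03d", seq_len(n_null)),
                  if (n_noisy > 0) sprintf("noisy_%03d", seq_len(n_noisy)))
  labels <- rep(c(FALSE, TRUE), c(n_null, n_noisy))
  sim_one <- function(g) {
    sp <- if (labels[match(g, gene_names)]) spec_noisy else spec_null
    sp$seed <- derive_seed(seed, g)
    simulate_gene(sp, coords = coords)
  }
  sims <- lapply(gene_names, sim_one)
  grab <- function(field) {
    m <- vapply(sims, `[[`, numeric(nrow(coords)), field)
    dimnames(m) <- list(rownames(coords), gene_names)
    m
  }
  list(values = grab("y"), coords = coords,
       labels = stats::setNames(labels, gene_names),
       true_mean = grab("true_mean"), true_var = grab("true_var"))
}

#' Count-valued simulation for the I/O path
#'
#' Converts simulated (Gaussian-scale) expression back to UMI-like counts by
#' inverting the Anscombe transform and Poisson sampling, with log-normal
#' library-size variation across spots. Only intended to exercise QC and
#' normalisation; the test's calibration claims are made on the Gaussian
#' fields the model assumes.
#'
#' @param values N x G matrix of Anscombe-scale expression (e.g. from
#'   [simulate_cohort], shifted to be positive).
#' @param coords N x 2 spot coordinates.
#' @param lib_size_sdlog log-normal sd of the per-spot library-size factor.
#' @param seed RNG seed.
#' @return A [spatial_counts] object.
#' @export
simulate_counts <- function(values, coords, lib_size_sdlog = 0.3, seed = 1) {
  values <- as.matrix(values)
  lambda <- pmax((values / 2)^2 - 3 / 8, 0)
  with_seed(seed, function() {
    f <- stats::rlnorm(nrow(values), 0, lib_size_sdlog)
    counts <- matrix(stats::rpois(length(lambda), sweep(lambda, 1, f, `*`)),
                     nrow = nrow(values), dimnames = dimnames(values))
    spatial_counts(counts, coords)
  })
}
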