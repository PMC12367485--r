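# shared fixtures and independent oracles for the suite

# naive O(n^2 m) evaluation of the squared centered L2-discrepancy,
# straight from the definition (triple loop; independent of the
# vectorized closed form in the package)
brute_cd2 <- function(idx, q) {
  u <- sweep(idx - 0.5, 2, as.numeric(q), "/")
  n <- nrow(u)
  m <- ncol(u)
  t2 <- 0
  for (i in seq_len(n)) {
    p <- 1
    for (k in seq_len(m)) {
      p <- p * (1 + 0.5 * abs(u[i, k] - 0.5) - 0.5 * abs(u[i, k] - 0.5)^2)
    }
    t2 <- t2 + p
  }
  t3 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      p <- 1
      for (k in seq_len(m)) {
        p <- p * (1 + 0.5 * abs(u[i, k] - 0.5) + 0.5 * abs(u[j, k] - 0.5) -
                    0.5 * abs(u[i, k] - u[j, k]))
      }
      t3 <- t3 + p
    }
  }
  (13 / 12)^m - (2 / n) * t2 + t3 / n^2
}

# the hyperparameter grid used by every simulation harness: RBF only,
# the conventional C / gamma ranges at exponent step 4 (fast) or 2
harness_grid_fine <- function() {
  svr_grid("rbf", log2_C = seq(-5, 15, 2), log2_gamma = seq(-15, 3, 2))
}
harness_grid_coarse <- function() {
  svr_grid("rbf", log2_C = seq(-5, 15, 4), log2_gamma = seq(-15, 3, 4))
}

# a small 3-factor landscape: one strongly active factor, two inert
tiny_landscape <- function(noise_sd = 0.5) {
  g <- ud_grid(list(a = c(1, 2, 3, 4, 5), b = c(10, 20, 30, 40, 50),
                    c = c(0.1, 0.2, 0.3, 0.4, 0.5)))
  landscape_spec(g, optimum = c(a = 3), curvature = c(a = -4),
                 base = 50, noise_sd = noise_sd)
}

# 3 active factors, the optimum of `x` above its tested range
boundary_landscape <- function(noise_sd = 1) {
  g <- ud_grid(list(x = c(1, 2, 3, 4), y = c(5, 6, 7, 8),
                    z = c(0.2, 0.4, 0.6, 0.8)))
  landscape_spec(
    g, optimum = c(x = 6, y = 6.5, z = 0.5),
    curvature = c(x = -2, y = -6, z = -60),
    base = 60, noise_sd = noise_sd)
}

# deterministic response table on a full factorial of two small factors
tiny_table <- function(noise_sd = 0, seed = 1) {
  g <- ud_grid(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  X <- enumerate_combinations(g)
  spec <- landscape_spec(g, optimum = c(a = 2, b = 2),
                         curvature = c(a = -3, b = -3),
                         base = 20, noise_sd = noise_sd)
  simulate_round(X, make_landscape(spec), seed = seed)
}

# cache expensive simulation results across test blocks within a run
.harness_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .harness_cache)) {
    assign(key, force(expr), envir = .harness_cache)
  }
  get(key, envir = .harness_cache)
}

# the 20-seed screening recovery harness (the spec'd in-silico
# screening study: 8 factors, 2 inert, noise 3 mg/L, 40-run design)
recovery_harness <- function(n_seeds = 20) {
  cached(paste0("recovery_", n_seeds), {
    fx <- pqq_study()
    land <- make_landscape(default_pqq_landscape(noise_sd = 3))
    lapply(seq_len(n_seeds), function(s) {
      d <- generate_uniform_design(fx$round1_grid, 40, budget = 1000,
                                   seed = s)
      dat <- simulate_round(d, land, seed = 100 + s)
      backward_screen(dat, "pqq", factors = fx$round1_grid$factor,
                      grid = harness_grid_fine(),
                      cv = cv_config(5, seed = s))
    })
  })
}
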