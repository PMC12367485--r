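#' Specify a synthetic response landscape
#'
#' A concave quadratic-with-interactions surface over the physical
#' factor space:
#'   f(x) = base + sum_j c_j (x_j - o_j)^2
#'               + sum_{j<k} b_jk (x_j - o_j)(x_k - o_k)
#' with curvature c_j < 0 for every active factor and inert factors
#' contributing exactly zero. The optimum location o may lie outside
#' the tested range of a factor (the situation the extrapolation rule
#' exists for). The surface must be concave (negative-definite
#' Hessian), so the global maximum `base` is attained exactly at o.
#'
#' @param grid A [ud_grid()] naming every factor (active and inert).
#' @param optimum Named numeric: optimum location per active factor.
#' @param curvature Named negative numeric: quadratic coefficient per
#'   active factor, in response units per (factor unit)^2.
#' @param interactions Optional tibble/data.frame with columns `f1`,
#'   `f2`, `beta` for pairwise interaction coefficients.
#' @param base Response value at the optimum (e.g. mg/L).
#' @param noise_sd Measurement/biological noise SD used by
#'   [simulate_round()] (response units).
#' @return A `landscape_spec`.
#' @export
landscape_spec <- function(grid, optimum, curvature, interactions = NULL,
                           base = 65, noise_sd = 3) {
  active <- names(optimum)
  if (!setequal(active, names(curvature))) {
    stop("`optimum` and `curvature` must name the same active factors")
  }
  unknown <- setdiff(active, grid$factor)
  if (length(unknown)) stop("unknown factor in active set: ", unknown[1])
  if (any(curvature >= 0)) {
    stop("curvature must be negative for every active factor")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  H <- diag(2 * curvature[active], nrow = length(active))
  rownames(H) <- colnames(H) <- active
  if (!is.null(interactions) && nrow(interactions) > 0) {
    stopifnot(all(c("f1", "f2", "beta") %in% names(interactions)))
    for (i in seq_len(nrow(interactions))) {
      f1 <- interactions$f1[i]
      f2 <- interactions$f2[i]
      if (!all(c(f1, f2) %in% active)) {
        stop("interaction references a non-active factor")
      }
      H[f1, f2] <- H[f1, f2] + interactions$beta[i]
      H[f2, f1] <- H[f2, f1] + interactions$beta[i]
    }
  }
  if (max(eigen(H, symmetric = TRUE, only.values = TRUE)$values) >= 0) {
    stop("landscape is not concave: reduce interaction strength ",
         "relative to the curvatures")
  }
  structure(list(
    grid = grid, active = active,
    inert = setdiff(grid$factor, active),
    optimum = optimum, curvature = curvature,
    interactions = if (is.null(interactions)) {
      tibble::tibble(f1 = character(), f2 = character(), beta = numeric())
    } else {
      tibble::as_tibble(interactions)
    },
    base = base, noise_sd = noise_sd),
    class = "landscape_spec")
}

#' Build the deterministic response function of a landscape
#'
#' @param spec A [landscape_spec()].
#' @return A `ud_landscape`: a function taking a data frame with the
#'   active factor columns (inert columns may be present or absent —
#'   they never change the value) and returning the noiseless
#'   response.
#' @export
make_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  f <- function(X) {
    missing <- setdiff(spec$active, names(X))
    if (length(missing)) stop("missing active factor column: ", missing[1])
    y <- rep(spec$base, nrow(X))
    centered <- lapply(spec$active,
                       function(a) X[[a]] - spec$optimum[[a]])
    names(centered) <- spec$active
    for (a in spec$active) {
      y <- y + spec$curvature[[a]] * centered[[a]]^2
    }
    if (nrow(spec$interactions)) {
      for (i in seq_len(nrow(spec$interactions))) {
        y <- y + spec$interactions$beta[i] *
          centered[[spec$interactions$f1[i]]] *
          centered[[spec$interactions$f2[i]]]
      }
    }
    y
  }
  structure(f, class = c("ud_landscape", "function"), spec = spec)
}

#' Simulate measuring one experimental round
#'
#' Evaluates the noiseless landscape at each design run and adds
#' seeded Gaussian noise (SD = the spec's `noise_sd`). Yields are
#' truncated at zero: a fermentation cannot produce a negative titer.
#'
#' @param design A `ud_design` (or any data frame of physical values
#'   covering the landscape's active factors).
#' @param landscape A [make_landscape()] function.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param response Name for the simulated response column.
#' @return The design tibble with the response column appended.
#' @export
simulate_round <- function(design, landscape, seed = 1,
                           response = "pqq") {
  spec <- attr(landscape, "spec")
  f <- landscape(design)
  y <- with_seed(seed, f + stats::rnorm(length(f), 0, spec$noise_sd))
  out <- tibble::as_tibble(as.data.frame(design))
  out[[response]] <- pmax(y, 0)
  out
}

#' Default eight-factor PQQ-like landscape
#'
#' The in-silico stand-in for the fermentation study conditions: eight
#' candidate factors on the first-round level grid, six of them active
#' (yeast powder, ammonium sulfate, glutamic acid, tyrosine,
#' temperature, pH) and two inert (calcium chloride, inoculum volume).
#' Tyrosine and temperature have their optima above the tested range
#' (so the extrapolation rule has something to find), yeast powder
#' below it, and pH an interior optimum at 6.5. The surface is
#' additive (no interaction terms): with 40 runs over 8 factors an
#' interaction structure is not identifiable and would only inject
#' surrogate bias; curvatures are scaled so each active factor swings
#' the response by roughly 8-16 mg/L over its range and grid
#' responses span about 10-60 mg/L. Noise defaults to 3 mg/L.
#'
#' @param noise_sd Noise SD in mg/L.
#' @return A `landscape_spec`.
#' @export
default_pqq_landscape <- function(noise_sd = 3) {
  fx <- pqq_study()
  landscape_spec(
    grid = fx$round1_grid,
    optimum = c(yeast_powder = 6, ammonium_sulfate = 1.0,
                glutamic_acid = 0.8, tyrosine = 3.0,
                temperature = 30, pH = 6.5),
    curvature = c(yeast_powder = -0.06, ammonium_sulfate = -2.2,
                  glutamic_acid = -3.0, tyrosine = -2.0,
                  temperature = -1.0, pH = -50),
    base = 60, noise_sd = noise_sd)
}

#' Generic synthetic landscape over an arbitrary grid
#'
#' A quick concave test surface for any factor grid: every factor is
#' active with its optimum at the midpoint of its tested range and a
#' curvature scaled so each factor swings `swing` response units
#' between its range midpoint and either end. Useful for exercising a
#' pipeline on a user-supplied factor file without hand-tuning
#' coefficients.
#'
#' @param grid A [ud_grid()].
#' @param base Response at the optimum.
#' @param swing Per-factor response drop from the midpoint to the
#'   range boundary (response units).
#' @param noise_sd Simulated noise SD.
#' @return A `landscape_spec`.
#' @export
generic_landscape <- function(grid, base = 60, swing = 8,
                              noise_sd = 3) {
  rng <- vapply(grid$levels, range, numeric(2))
  mid <- colMeans(rng)
  half <- (rng[2, ] - rng[1, ]) / 2
  names(mid) <- names(half) <- grid$factor
  landscape_spec(grid, optimum = mid,
                 curvature = -swing / half^2,
                 base = base, noise_sd = noise_sd)
}

#' Level grids and headline numbers of the PQQ fermentation case study
#'
#' The worked example shipped with the package: an eight-factor
#' first-round grid (five media components in g/L, temperature in
#' degrees C, inoculum volume in %, and pH; level counts
#' 5,5,5,5,5,4,5,5), the five-factor second-round grid (3,2,2,3,3),
#' and the printed summary record of both experimental rounds
#' (baseline yield 43.65 mg/L, best measured yields, counts of
#' treatments above the 50 and 43 mg/L marks, and the validated final
#' yield 73.40 mg/L).
#'
#' @return A list: `round1_grid`, `round2_grid` ([ud_grid()]s),
#'   `baseline_yield`, `validated_yield`, and `round1` / `round2`
#'   summary lists (`n`, `best`, `lowest`, `n_above_50`, `n_above_43`).
#' @export
pqq_study <- function() {
  round1_grid <- ud_grid(
    levels = list(
      yeast_powder = c(7, 10, 13, 16, 19),
      ammonium_sulfate = c(1.0, 1.5, 2.0, 2.5, 3.0),
      glutamic_acid = c(0.5, 1.0, 1.5, 2.0, 2.5),
      tyrosine = c(0.5, 1.0, 1.5, 2.0, 2.5),
      calcium_chloride = c(0.2, 0.3, 0.4, 0.5, 0.6),
      temperature = c(26, 27, 28, 29),
      inoculum = c(0.1, 0.3, 0.5, 0.7, 0.9),
      pH = c(6.1, 6.3, 6.5, 6.7, 6.9)),
    units = c(yeast_powder = "g/L", ammonium_sulfate = "g/L",
              glutamic_acid = "g/L", tyrosine = "g/L",
              calcium_chloride = "g/L", temperature = "degC",
              inoculum = "%", pH = ""),
    roles = c(temperature = "process_parameter",
              inoculum = "process_parameter",
              pH = "process_parameter"))
  round2_grid <- ud_grid(
    levels = list(
      yeast_powder = c(5, 7, 9),
      ammonium_sulfate = c(0.5, 1.0),
      glutamic_acid = c(0.5, 1.0),
      tyrosine = c(2.0, 2.5, 3.0),
      temperature = c(28, 29, 30)),
    units = c(yeast_powder = "g/L", ammonium_sulfate = "g/L",
              glutamic_acid = "g/L", tyrosine = "g/L",
              temperature = "degC"),
    roles = c(temperature = "process_parameter"))
  list(
    round1_grid = round1_grid,
    round2_grid = round2_grid,
    retained_round1 = c("yeast_powder", "ammonium_sulfate",
                        "glutamic_acid", "tyrosine", "temperature",
                        "pH"),
    baseline_yield = 43.65,
    validated_yield = 73.40,
    round1 = list(n = 40L, best = 65.56, lowest = 10.12,
                  n_above_50 = 5L, n_above_43 = 13L),
    round2 = list(n = 26L, best = 71.42, lowest = 30.81,
                  n_above_50 = 15L, n_above_43 = 22L))
}
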