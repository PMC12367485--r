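#' Squared centered L2-discrepancy of a U-type design
#'
#' Measures how uniformly the design's runs cover the level lattice.
#' Level index l of a q-level column is mapped to the centered point
#' u = (l - 0.5)/q in (0, 1); the statistic is the closed-form CD2^2
#' double sum over runs. Lower values mean a more uniform design. The
#' value is invariant under row permutation and under reflecting any
#' column (l -> q + 1 - l).
#'
#' @param design A `ud_design` (from [ud_design()] or
#'   [generate_uniform_design()]), or an integer matrix of 1-based
#'   level indices if `q` is given.
#' @param q Per-column level counts, required when `design` is a bare
#'   index matrix.
#' @return Non-negative scalar, the squared centered L2-discrepancy.
#' @references Hickernell's centered L2-discrepancy; the standard
#'   uniformity criterion for U-type designs.
#' @export
centered_l2_discrepancy <- function(design, q = NULL) {
  u <- design_unit_points(design, q)
  cd2_from_unit(u)
}

design_unit_points <- function(design, q = NULL) {
  if (inherits(design, "ud_design")) {
    idx <- attr(design, "indices")
    q <- level_counts(attr(design, "grid"))
  } else {
    idx <- as.matrix(design)
    if (is.null(q)) stop("`q` (level counts) required for a bare index matrix")
  }
  if (nrow(idx) < 1 || ncol(idx) < 1) stop("empty design")
  sweep(idx - 0.5, 2, as.numeric(q), "/")
}

# closed-form CD2^2, vectorized over the n x n pair matrix
cd2_from_unit <- function(u) {
  n <- nrow(u)
  m <- ncol(u)
  a <- abs(u - 0.5)
  term1 <- (13 / 12)^m
  f <- exp(rowSums(log1p(0.5 * a - 0.5 * a^2)))
  term2 <- (2 / n) * sum(f)
  pairprod <- matrix(1, n, n)
  for (k in seq_len(m)) {
    ak <- a[, k]
    pairprod <- pairprod *
      (1 + 0.5 * outer(ak, ak, "+") - 0.5 * abs(outer(u[, k], u[, k], "-")))
  }
  term3 <- sum(pairprod) / n^2
  term1 - term2 + term3
}

# per-column balanced occupancy targets: counts differ by <= 1
balanced_counts <- function(n, q) {
  base <- n %/% q
  extra <- n %% q
  counts <- rep(base, q)
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  counts
}

# good-lattice-point base column on n levels, collapsed to q pseudo-levels
glp_column <- function(n, h, q) {
  base <- ((seq_len(n) - 1) * h) %% n + 1   # 1..n, a permutation when gcd(h,n)=1
  as.integer(ceiling(base * q / n))          # near-balanced collapse
}

coprimes <- function(n) {
  h <- seq_len(n - 1)
  h[vapply(h, function(x) gcd_int(x, n) == 1L, logical(1))]
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# rebalance a collapsed column to the exact target occupancy by
# reassigning surplus entries (deterministic: first-come order)
rebalance_column <- function(col, q, n) {
  target <- balanced_counts(n, q)
  tab <- tabulate(col, nbins = q)
  for (lv in seq_len(q)) {
    while (tab[lv] > target[lv]) {
      deficit <- which(tab < target)
      i <- which(col == lv)[1]
      col[i] <- as.integer(deficit[which.min(abs(deficit - lv))])
      tab <- tabulate(col, nbins = q)
    }
  }
  as.integer(col)
}

#' Construct a mixed-level uniform design
#'
#' Builds an n-run U-type design over a (possibly mixed-level) grid:
#' a good-lattice-point design on n base levels is collapsed to each
#' factor's level count (pseudo-level collapsing, occupancy within
#' +/-1 of n/q), then improved by a seeded threshold-accepting search
#' over within-column level swaps that minimizes the squared centered
#' L2-discrepancy. The returned design never scores worse than the
#' initial good-lattice-point candidate.
#'
#' @param grid A [ud_grid()].
#' @param n Number of runs; must be at least the largest level count.
#' @param budget Search iterations (default 10000).
#' @param seed Integer seed; the same (grid, n, budget, seed) always
#'   returns the identical design.
#' @return A `ud_design` with attributes `discrepancy` (CD2^2 of the
#'   returned design) and `construction` (generator vector, initial
#'   and final discrepancy, accepted-move count).
#' @examples
#' g <- ud_grid(list(a = c(1, 2, 3), b = c(10, 20, 30)))
#' d <- generate_uniform_design(g, n = 9, budget = 500, seed = 1)
#' attr(d, "discrepancy")
#' @export
generate_uniform_design <- function(grid, n, budget = 10000, seed = 1) {
  q <- level_counts(grid)
  m <- length(q)
  if (n < max(q)) {
    stop("n = ", n, " is smaller than the largest level count (", max(q), ")")
  }
  with_seed(seed, {
    hs <- coprimes(n)
    # initial candidate: sample a few generator subsets, keep the best
    n_try <- min(20L, max(1L, length(hs) - m + 1L))
    best_init <- NULL
    best_init_cd <- Inf
    gen_best <- NULL
    for (t in seq_len(n_try)) {
      gen <- if (length(hs) >= m) sample(hs, m) else sample(hs, m, replace = TRUE)
      idx <- vapply(seq_len(m),
                    function(j) rebalance_column(glp_column(n, gen[j], q[j]), q[j], n),
                    integer(n))
      idx <- matrix(as.integer(idx), nrow = n)
      cd <- centered_l2_discrepancy(idx, q)
      if (cd < best_init_cd) {
        best_init_cd <- cd
        best_init <- idx
        gen_best <- gen
      }
    }
    idx <- best_init
    state <- cd2_state(idx, q)
    cur <- state$cd2
    best <- idx
    best_cd <- cur
    accepted <- 0L
    thresholds <- best_init_cd * 0.02 * (1 - seq_len(budget) / budget)
    for (it in seq_len(budget)) {
      k <- sample.int(m, 1)
      rs <- sample.int(n, 2)
      if (idx[rs[1], k] == idx[rs[2], k]) next
      delta <- cd2_swap_delta(state, idx, q, k, rs[1], rs[2])
      if (delta <= thresholds[it]) {
        state <- cd2_apply_swap(state, idx, q, k, rs[1], rs[2])
        tmp <- idx[rs[1], k]
        idx[rs[1], k] <- idx[rs[2], k]
        idx[rs[2], k] <- tmp
        cur <- state$cd2
        accepted <- accepted + 1L
        if (cur < best_cd) {
          best_cd <- cur
          best <- idx
        }
      }
    }
    if (prod(as.numeric(q)) >= n) best <- dedupe_design(best, q)
    out <- ud_design(best, grid)
    attr(out, "discrepancy") <- centered_l2_discrepancy(out)
    attr(out, "construction") <- list(
      generators = gen_best, n_runs = n, seed = seed, budget = budget,
      initial_discrepancy = best_init_cd, accepted_moves = accepted)
    out
  })
}

# ---- incremental CD2^2 bookkeeping for the swap search ----------------
# state: f (length-n row factors of the single sum), P (n x n pair
# matrix), cd2 (current value). A swap of rows r, s in column k only
# touches f[r], f[s] and rows/columns r, s of P.

cd2_state <- function(idx, q) {
  u <- sweep(idx - 0.5, 2, as.numeric(q), "/")
  n <- nrow(u)
  m <- ncol(u)
  a <- abs(u - 0.5)
  f <- exp(rowSums(log1p(0.5 * a - 0.5 * a^2)))
  P <- matrix(1, n, n)
  for (k in seq_len(m)) {
    ak <- a[, k]
    P <- P * (1 + 0.5 * outer(ak, ak, "+") - 0.5 * abs(outer(u[, k], u[, k], "-")))
  }
  cd2 <- (13 / 12)^m - (2 / n) * sum(f) + sum(P) / n^2
  list(f = f, P = P, cd2 = cd2, m = m, n = n)
}

col_factor1 <- function(u) 1 + 0.5 * abs(u - 0.5) - 0.5 * abs(u - 0.5)^2
col_factor2 <- function(u1, u2) {
  1 + 0.5 * abs(u1 - 0.5) + 0.5 * abs(u2 - 0.5) - 0.5 * abs(u1 - u2)
}

# recompute state after swapping rows r,s in column k (exact, O(n))
cd2_apply_swap <- function(state, idx, q, k, r, s) {
  uk <- (idx[, k] - 0.5) / q[k]
  new_uk <- uk
  new_uk[c(r, s)] <- uk[c(s, r)]
  f <- state$f
  P <- state$P
  n <- state$n
  for (row in c(r, s)) {
    f[row] <- f[row] / col_factor1(uk[row]) * col_factor1(new_uk[row])
    oldrow <- col_factor2(uk[row], uk)
    newrow <- col_factor2(new_uk[row], new_uk)
    ratio <- newrow / oldrow
    P[row, ] <- P[row, ] * ratio
    P[, row] <- P[, row] * ratio
    # the (r,s) and diagonal cells get touched twice via both rows;
    # fix them explicitly afterwards
    uk[row] <- new_uk[row]
  }
  for (row in c(r, s)) {
    # rebuild the doubly-updated cells exactly from column products
    P[row, row] <- pair_cell(idx, q, k, new_uk, row, row, state$m)
  }
  P[r, s] <- pair_cell(idx, q, k, new_uk, r, s, state$m)
  P[s, r] <- P[r, s]
  cd2 <- (13 / 12)^state$m - (2 / n) * sum(f) + sum(P) / n^2
  list(f = f, P = P, cd2 = cd2, m = state$m, n = n)
}

# exact pair-product cell (i,j) given column k carries new_uk values
pair_cell <- function(idx, q, k, new_uk, i, j, m) {
  val <- 1
  for (kk in seq_len(m)) {
    if (kk == k) {
      val <- val * col_factor2(new_uk[i], new_uk[j])
    } else {
      ui <- (idx[i, kk] - 0.5) / q[kk]
      uj <- (idx[j, kk] - 0.5) / q[kk]
      val <- val * col_factor2(ui, uj)
    }
  }
  val
}

cd2_swap_delta <- function(state, idx, q, k, r, s) {
  cd2_apply_swap(state, idx, q, k, r, s)$cd2 - state$cd2
}

# repair duplicated runs by balance-preserving within-column swaps,
# greedily choosing the swap with the lowest CD2^2 among those that
# reduce the duplicate count; only called when distinct rows exist
dedupe_design <- function(idx, q) {
  repeat {
    key <- apply(idx, 1, paste, collapse = "/")
    nd <- sum(duplicated(key))
    if (nd == 0) return(idx)
    r <- which(duplicated(key))[1]
    best_cd <- Inf
    best_idx <- NULL
    for (k in seq_len(ncol(idx))) {
      for (s in seq_len(nrow(idx))[-r]) {
        if (idx[s, k] == idx[r, k]) next
        cand <- idx
        tmp <- cand[r, k]
        cand[r, k] <- cand[s, k]
        cand[s, k] <- tmp
        if (sum(duplicated(apply(cand, 1, paste, collapse = "/"))) >= nd) {
          next
        }
        cd <- centered_l2_discrepancy(cand, q)
        if (cd < best_cd) {
          best_cd <- cd
          best_idx <- cand
        }
      }
    }
    if (is.null(best_idx)) return(idx)
    idx <- best_idx
  }
}

#' Per-level occupancy of each design column
#'
#' @param design A `ud_design`.
#' @return Tibble with `factor`, `level_index`, `level_value`, `count`.
#' @export
design_balance <- function(design) {
  grid <- attr(design, "grid")
  idx <- attr(design, "indices")
  purrr::map_dfr(seq_len(nrow(grid)), function(j) {
    q <- length(grid$levels[[j]])
    tibble::tibble(
      factor = grid$factor[j],
      level_index = seq_len(q),
      level_value = grid$levels[[j]],
      count = tabulate(idx[, j], nbins = q))
  })
}
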