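test_that("enumeration is lexicographic, complete and duplicate-free", {
  g <- ud_grid(list(a = c(1, 2), b = c(5, 9)))
  idx <- enumerate_combinations(g, values = FALSE)
  expect_identical(as.matrix(idx),
                   matrix(c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 2L), 4, 2,
                          dimnames = list(NULL, c("a", "b"))))
  vals <- enumerate_combinations(g)
  expect_identical(vals$a, c(1, 1, 2, 2))
  expect_identical(vals$b, c(5, 9, 5, 9))
  fx <- pqq_study()
  r2 <- enumerate_combinations(fx$round2_grid)
  expect_identical(nrow(r2), 108L)
  expect_identical(anyDuplicated(r2), 0L)
  expect_error(enumerate_combinations(g, character(0)), "non-empty")
})

test_that("predict_grid on one combination equals a direct prediction", {
  dat <- tiny_table(noise_sd = 1, seed = 2)
  fit <- svr_grid_search(dat, "pqq", c("a", "b"),
                         harness_grid_coarse(), cv_config(3, seed = 1))
  g1 <- ud_grid(list(a = c(2, 3), b = c(1, 2)))
  pg <- predict_grid(fit, g1)
  direct <- predict(fit, enumerate_combinations(g1))
  expect_equal(pg$yhat, direct, tolerance = 1e-12)
})

test_that("chunked prediction equals the one-shot computation", {
  land <- make_landscape(boundary_landscape(noise_sd = 1))
  g <- attr(land, "spec")$grid
  d <- generate_uniform_design(g, 16, budget = 150, seed = 2)
  dat <- simulate_round(d, land, seed = 22)
  fit <- svr_grid_search(dat, "pqq", g$factor, harness_grid_coarse(),
                         cv_config(4, seed = 2))
  chunked <- predict_grid(fit, g, chunk_size = 7)
  oneshot <- predict_grid(fit, g, chunk_size = 1e6)
  expect_identical(chunked$yhat, oneshot$yhat)
  two_pass <- c(mean(oneshot$yhat), max(oneshot$yhat), min(oneshot$yhat))
  expect_equal(unlist(chunked$stats, use.names = FALSE), two_pass)
})

test_that("hand-built 2x2 grid frequencies match the brute-force count", {
  g <- ud_grid(list(A = c(0, 1), B = c(0, 1)))
  pg <- structure(list(grid = g, subset = g$factor,
                       yhat = c(12, 3, 7, 9),  # (0,0),(0,1),(1,0),(1,1)
                       fixed = NULL, n = 4,
                       stats = list(mean = 7.75, max = 12, min = 3),
                       best_combo = tibble::tibble(A = 0, B = 0)),
                  class = "prediction_grid")
  rep <- frequency_statistics(pg, threshold = 8)
  # selected: 12 at (A=0,B=0) and 9 at (A=1,B=1) -> each factor splits
  # its two selected counts one per level
  expect_identical(rep$n_selected, 2L)
  a <- rep$per_factor[rep$per_factor$factor == "A", ]
  expect_identical(a$count, c(1L, 1L))
  b <- rep$per_factor[rep$per_factor$factor == "B", ]
  expect_identical(b$count, c(1L, 1L))
})

test_that("threshold extremes give the forced counts and the empty warning", {
  land <- make_landscape(boundary_landscape(noise_sd = 1))
  g <- attr(land, "spec")$grid
  d <- generate_uniform_design(g, 16, budget = 150, seed = 3)
  dat <- simulate_round(d, land, seed = 33)
  fit <- svr_grid_search(dat, "pqq", g$factor, harness_grid_coarse(),
                         cv_config(4, seed = 3))
  pg <- predict_grid(fit, g)
  lo <- frequency_statistics(pg, threshold = min(pg$yhat) - 1)
  expect_identical(lo$n_selected, as.integer(pg$n))
  # full factorial symmetry: every level of a q-level factor appears
  # n_total / q times
  for (f in g$factor) {
    counts <- lo$per_factor$count[lo$per_factor$factor == f]
    expect_true(all(counts == pg$n / length(counts)))
  }
  hi <- frequency_statistics(pg, threshold = max(pg$yhat) + 1)
  expect_identical(hi$n_selected, 0L)
  expect_true(hi$warning_empty)
  expect_true(all(hi$per_factor$count == 0L))
})

test_that("frequency counts always conserve the selected total", {
  land <- make_landscape(boundary_landscape(noise_sd = 1))
  g <- attr(land, "spec")$grid
  for (s in 1:5) {
    d <- generate_uniform_design(g, 16, budget = 100, seed = s)
    dat <- simulate_round(d, land, seed = 40 + s)
    fit <- svr_grid_search(dat, "pqq", g$factor, harness_grid_coarse(),
                           cv_config(4, seed = s))
    pg <- predict_grid(fit, g)
    rep <- frequency_statistics(pg)  # default 85th-percentile threshold
    sums <- tapply(rep$per_factor$count, rep$per_factor$factor, sum)
    expect_true(all(sums == rep$n_selected))
  }
})

test_that("the study-shaped frequency report reproduces the published plan shape", {
  fx <- pqq_study()
  g <- fx$round1_grid
  # published per-level frequencies among predictions above 50 mg/L:
  # yeast powder peaked at its lower bound (318 vs 306 vs 95),
  # ammonium sulfate mirrored it, glutamic acid peaked interior but
  # not dominantly (235 vs 224), tyrosine and temperature peaked at
  # their upper bounds, pH peaked sharply (dominantly) at 6.5
  counts <- list(
    yeast_powder = c(318, 306, 95, 0, 0),
    ammonium_sulfate = c(300, 250, 100, 45, 24),
    glutamic_acid = c(224, 235, 150, 80, 30),
    tyrosine = c(10, 40, 112, 251, 306),
    temperature = c(40, 120, 259, 300),
    pH = c(20, 100, 400, 150, 49))
  per_factor <- purrr::map_dfr(names(counts), function(f) {
    lv <- g$levels[[match(f, g$factor)]]
    tibble::tibble(factor = f, level_index = seq_along(lv),
                   level_value = lv, count = as.integer(counts[[f]]))
  })
  best <- tibble::tibble(yeast_powder = 7, ammonium_sulfate = 1.0,
                         glutamic_acid = 1.0, tyrosine = 2.0,
                         temperature = 29, pH = 6.5)
  rep <- frequency_report(per_factor, g, threshold = 50,
                          best_combo = best)
  plan <- recommend(rep, g,
                    screened_out = c("calcium_chloride", "inoculum"))

  # screened-out factors anchored at the median tested level
  expect_equal(
    plan$fixed$value[plan$fixed$factor == "calcium_chloride"], 0.4)
  expect_equal(plan$fixed$value[plan$fixed$factor == "inoculum"], 0.5)
  expect_identical(
    unique(plan$fixed$reason[plan$fixed$factor %in%
                               c("calcium_chloride", "inoculum")]),
    "screened_out_median")
  # dominant interior pH mode is frozen at 6.5
  expect_equal(plan$fixed$value[plan$fixed$factor == "pH"], 6.5)
  # boundary modes extrapolate in the indicated direction
  dirs <- tibble::deframe(plan$directions)
  expect_identical(dirs[["yeast_powder"]], "extend_down")
  expect_identical(dirs[["tyrosine"]], "extend_up")
  expect_identical(dirs[["temperature"]], "extend_up")
  # tyrosine next-round levels carry the mode, the best-combination
  # level, and one inter-level step beyond the upper bound
  expect_equal(plan$active$levels[[match("tyrosine",
                                         plan$active$factor)]],
               c(2.0, 2.5, 3.0))
  expect_equal(plan$active$levels[[match("temperature",
                                         plan$active$factor)]],
               c(28, 29, 30))
  # non-dominant interior glutamic acid keeps its two top levels
  glu <- plan$active$levels[[match("glutamic_acid",
                                   plan$active$factor)]]
  expect_true(all(c(0.5, 1.0) %in% glu))
  # every factor accounted for exactly once
  expect_setequal(c(plan$fixed$factor, plan$active$factor), g$factor)
  expect_length(intersect(plan$fixed$factor, plan$active$factor), 0)
})

test_that("recommend is idempotent for a fixed report", {
  fx <- pqq_study()
  g <- fx$round2_grid
  per_factor <- purrr::map_dfr(seq_len(nrow(g)), function(j) {
    lv <- g$levels[[j]]
    q <- length(lv)
    count <- if (q == 2) c(5L, 7L) else c(2L, 4L, 6L)
    tibble::tibble(factor = g$factor[j], level_index = seq_along(lv),
                   level_value = lv, count = count)
  })
  rep <- frequency_report(per_factor, g, threshold = 50)
  p1 <- recommend(rep, g)
  p2 <- recommend(rep, g)
  expect_identical(p1$fixed, p2$fixed)
  expect_identical(p1$directions, p2$directions)
})

test_that("interior dominant modes everywhere converge the plan", {
  g <- ud_grid(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  per_factor <- tibble::tibble(
    factor = rep(c("a", "b"), each = 3),
    level_index = rep(1:3, 2),
    level_value = c(1, 2, 3, 4, 5, 6),
    count = as.integer(c(10, 80, 10, 5, 90, 5)))
  rep <- frequency_report(per_factor, g, threshold = 1)
  plan <- recommend(rep, g)
  expect_true(plan$converged)
  expect_identical(nrow(plan$fixed), 2L)
  expect_equal(plan$fixed$value, c(2, 5))
})

test_that("percent improvements and threshold proportions reproduce the published arithmetic", {
  # 100 * (73.40 - 43.65) / 43.65 = 68.1558 -> 68.16 at 2 decimals
  expect_equal(percent_improvement(73.40, 43.65), 68.16)
  expect_equal(percent_improvement(71.42, 43.65), 63.62)
  expect_equal(percent_improvement(5, 5), 0)
  expect_error(percent_improvement(10, 0), "positive")

  # synthetic yield vectors with exactly the published exceedance
  # counts: 15/26 and 22/26 in round two, 5/40 and 13/40 in round one
  y2 <- c(rep(55, 15), rep(47, 7), rep(35, 4))
  p2 <- threshold_proportions(y2, c(50, 43))
  expect_identical(p2$count, c(15L, 22L))
  expect_equal(p2$percent, c(57.69, 84.62))
  y1 <- c(rep(52, 5), rep(45, 8), rep(20, 27))
  p1 <- threshold_proportions(y1, c(50, 43))
  expect_identical(p1$count, c(5L, 13L))
  expect_equal(p1$percent, c(12.5, 32.5))
  expect_equal(threshold_proportions(c(1, 2), 5)$percent, 0)
})
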