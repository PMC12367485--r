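test_that("CV MSE equals the hand-recomputed error of the out-of-fold predictions", {
  dat <- tiny_table(noise_sd = 1, seed = 3)
  res <- svr_cv_mse(dat, "pqq", c("a", "b"), kernel = "rbf", C = 4,
                    gamma = 0.5, cv = cv_config(3, seed = 9),
                    return_predictions = TRUE)
  expect_equal(res$mse, mean((dat$pqq - res$predictions)^2),
               tolerance = 1e-12)
  expect_identical(sort(unique(res$fold)), 1:3)
  expect_lte(max(table(res$fold)) - min(table(res$fold)), 1)
})

test_that("a constant response is re-predicted within the epsilon tube", {
  g <- ud_grid(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  dat <- enumerate_combinations(g)
  dat$y <- 7
  for (k in c("linear", "rbf")) {
    mse <- svr_cv_mse(dat, "y", c("a", "b"), kernel = k, C = 1,
                      gamma = 0.5, cv = cv_config(3, seed = 1),
                      epsilon = 0.1)
    expect_lte(mse, 0.1^2 + 1e-8)
  }
})

test_that("CV MSE is deterministic given the fold seed", {
  dat <- tiny_table(noise_sd = 2, seed = 5)
  a <- svr_cv_mse(dat, "pqq", c("a", "b"), cv = cv_config(5, seed = 4))
  b <- svr_cv_mse(dat, "pqq", c("a", "b"), cv = cv_config(5, seed = 4))
  expect_identical(a, b)
  c <- svr_cv_mse(dat, "pqq", c("a", "b"), cv = cv_config(5, seed = 5))
  expect_false(identical(a, c))
})

test_that("n below the fold count errors", {
  dat <- tiny_table()[1:3, ]
  expect_error(svr_cv_mse(dat, "pqq", c("a", "b"),
                          cv = cv_config(5, seed = 1)), "n >= k")
})

test_that("a one-cell grid search returns that cell with its own CV MSE", {
  dat <- tiny_table(noise_sd = 1, seed = 2)
  g <- svr_grid("rbf", log2_C = 3, log2_gamma = -1)
  cv <- cv_config(3, seed = 2)
  fit <- svr_grid_search(dat, "pqq", c("a", "b"), g, cv)
  expect_identical(fit$kernel, "rbf")
  expect_equal(fit$C, 2^3)
  expect_equal(fit$gamma, 2^-1)
  expect_equal(fit$cv_mse,
               svr_cv_mse(dat, "pqq", c("a", "b"), "rbf", 2^3, 2^-1, cv))
})

test_that("grid search is reproducible and its table covers the grid", {
  dat <- tiny_table(noise_sd = 1, seed = 8)
  g <- svr_grid(c("linear", "rbf"), log2_C = seq(-5, 7, 4),
                log2_gamma = seq(-9, 3, 4))
  cv <- cv_config(3, seed = 3)
  f1 <- svr_grid_search(dat, "pqq", c("a", "b"), g, cv)
  f2 <- svr_grid_search(dat, "pqq", c("a", "b"), g, cv)
  expect_identical(glance(f1), glance(f2))
  cells <- tidy(f1)
  # linear evaluated only at the smallest gamma; rbf over the full grid
  expect_identical(nrow(cells[cells$kernel == "linear", ]), 4L)
  expect_identical(nrow(cells[cells$kernel == "rbf", ]), 16L)
  expect_equal(min(cells$cv_mse, na.rm = TRUE), f1$cv_mse)
})

test_that("the RBF kernel wins on a smooth nonlinear landscape", {
  land <- make_landscape(tiny_landscape(noise_sd = 0.5))
  g <- attr(land, "spec")$grid
  grid <- svr_grid(c("linear", "polynomial", "rbf", "sigmoid"),
                   log2_C = seq(-5, 7, 4), log2_gamma = seq(-9, 3, 4))
  wins <- 0
  for (s in 1:20) {
    d <- generate_uniform_design(g, 15, budget = 150, seed = s)
    dat <- simulate_round(d, land, seed = 50 + s)
    fit <- svr_grid_search(dat, "pqq", g$factor, grid,
                           cv_config(5, seed = s))
    if (fit$kernel == "rbf") wins <- wins + 1
  }
  expect_gte(wins, 16)
})

test_that("predictions are row-wise and near-interpolating on a tight fit", {
  dat <- tiny_table(noise_sd = 0, seed = 1)
  fit <- svr_grid_search(dat, "pqq", c("a", "b"),
                         svr_grid("rbf", log2_C = seq(5, 15, 2),
                                  log2_gamma = seq(-3, 3, 2),
                                  epsilon = 0.01),
                         cv_config(3, seed = 1))
  p <- predict(fit, dat)
  # residuals bounded by the tube width (response sd units) + slack
  tube <- 0.01 * stats::sd(dat$pqq)
  expect_lt(max(abs(p - dat$pqq)), tube + 0.5)
  perm <- c(4, 1, 9, 2, 3, 8, 5, 7, 6)
  expect_equal(predict(fit, dat[perm, ]), p[perm], tolerance = 1e-12)
  expect_error(predict(fit, dat[, "a", drop = FALSE]), "lacks")
})

test_that("shifting the response shifts predictions by the same constant", {
  dat <- tiny_table(noise_sd = 1, seed = 6)
  g <- svr_grid("rbf", log2_C = 5, log2_gamma = -1)
  cv <- cv_config(3, seed = 1)
  f0 <- svr_grid_search(dat, "pqq", c("a", "b"), g, cv)
  dat10 <- dat
  dat10$pqq <- dat10$pqq + 10
  f10 <- svr_grid_search(dat10, "pqq", c("a", "b"), g, cv)
  expect_equal(predict(f10, dat), predict(f0, dat) + 10,
               tolerance = 1e-6)
})

test_that("tiny C collapses predictions toward the response mean", {
  dat <- tiny_table(noise_sd = 1, seed = 7)
  fit <- svr_grid_search(dat, "pqq", c("a", "b"),
                         svr_grid("rbf", log2_C = -5, log2_gamma = -1),
                         cv_config(3, seed = 1))
  p <- predict(fit, dat)
  # standardized weights bounded by C = 2^-5 -> predictions hug the mean
  expect_lt(max(abs(p - mean(dat$pqq))),
            0.5 * stats::sd(dat$pqq))
})
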