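#' Cross-validation settings
#'
#' @param folds Fold count k (default 5, the usual choice for small
#'   treatment tables).
#' @param seed Integer seed for the fold shuffle; recorded in every
#'   downstream report so fold assignment is auditable.
#' @param shuffle Shuffle rows before the contiguous k-way split?
#' @return A `cv_config` list.
#' @export
cv_config <- function(folds = 5L, seed = 1L, shuffle = TRUE) {
  folds <- as.integer(folds)
  if (folds < 2) stop("need at least 2 folds")
  structure(list(folds = folds, seed = as.integer(seed),
                 shuffle = isTRUE(shuffle)),
            class = "cv_config")
}

#' Hyperparameter grid for the epsilon-SVR search
#'
#' Defaults follow the conventional libsvm-style search: all four
#' kernels, C on powers of two from 2^-5 to 2^15 and gamma from 2^-15
#' to 2^3, exponent step 2. `epsilon` (tube width on the standardized
#' response) and the polynomial `degree` are fixed per grid.
#'
#' @param kernels Subset of `c("linear", "polynomial", "rbf",
#'   "sigmoid")`.
#' @param log2_C,log2_gamma Exponent sequences for C and gamma.
#' @param epsilon Epsilon-insensitive tube width (standardized units).
#' @param degree Polynomial kernel degree.
#' @return A `svr_grid_spec` list.
#' @export
svr_grid <- function(kernels = c("linear", "polynomial", "rbf", "sigmoid"),
                     log2_C = seq(-5, 15, by = 2),
                     log2_gamma = seq(-15, 3, by = 2),
                     epsilon = 0.1, degree = 3) {
  kernels <- match.arg(kernels, c("linear", "polynomial", "rbf", "sigmoid"),
                       several.ok = TRUE)
  if (length(log2_C) == 0 || length(log2_gamma) == 0) {
    stop("empty hyperparameter range")
  }
  structure(list(kernels = kernels, log2_C = sort(log2_C),
                 log2_gamma = sort(log2_gamma),
                 epsilon = epsilon, degree = degree),
            class = "svr_grid_spec")
}

kernel_to_e1071 <- function(kernel) {
  switch(kernel, rbf = "radial", kernel)
}

# seeded shuffle then contiguous k-way split; sizes differ by <= 1
fold_assignments <- function(n, cv) {
  if (n < cv$folds) {
    stop("cross-validation needs n >= k folds (n = ", n, ", k = ",
         cv$folds, ")")
  }
  order <- if (cv$shuffle) with_seed(cv$seed, sample.int(n)) else seq_len(n)
  sizes <- rep(n %/% cv$folds, cv$folds)
  extra <- n %% cv$folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold <- integer(n)
  fold[order] <- rep(seq_len(cv$folds), times = sizes)
  fold
}

standardizer <- function(X, y = NULL) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  out <- list(x_center = center, x_scale = scale)
  if (!is.null(y)) {
    out$y_center <- mean(y)
    out$y_scale <- stats::sd(y)
    if (!is.finite(out$y_scale) || out$y_scale == 0) out$y_scale <- 1
  }
  out
}

apply_x_scale <- function(X, sc) {
  sweep(sweep(X, 2, sc$x_center, "-"), 2, sc$x_scale, "/")
}

fit_svm_scaled <- function(X, y, kernel, C, gamma, epsilon, degree) {
  sc <- standardizer(X, y)
  Xs <- apply_x_scale(X, sc)
  ys <- (y - sc$y_center) / sc$y_scale
  model <- e1071::svm(Xs, ys, type = "eps-regression",
                      kernel = kernel_to_e1071(kernel),
                      cost = C, gamma = gamma, epsilon = epsilon,
                      degree = degree, scale = FALSE, fitted = FALSE)
  # every training point inside the epsilon tube leaves no support
  # vectors (e.g. a constant response); the SVR solution is then the
  # flat function f = 0 on the standardized scale
  if (model$tot.nSV == 0) model <- NULL
  list(model = model, scaler = sc)
}

predict_svm_scaled <- function(fit, Xnew) {
  p <- if (is.null(fit$model)) {
    rep(0, nrow(Xnew))
  } else {
    as.numeric(stats::predict(fit$model, apply_x_scale(Xnew, fit$scaler)))
  }
  p * fit$scaler$y_scale + fit$scaler$y_center
}

response_matrix <- function(data, response, factors) {
  missing <- setdiff(c(factors, response), names(data))
  if (length(missing)) stop("missing column: ", missing[1])
  X <- as.matrix(as.data.frame(data)[, factors, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = as.numeric(data[[response]]))
}

#' Cross-validated mean squared error of one SVR cell
#'
#' MSE = (1/n) * sum over runs of (y_i - yhat_i)^2 where each yhat_i is
#' the out-of-fold prediction of an epsilon-SVR with the stated kernel,
#' C and gamma. Inputs and response are standardized on the training
#' fold only and predictions back-transformed, so factors measured in
#' g/L, degrees C and pH units are commensurable inside the kernel.
#'
#' @param data Treatment table (one row per run, physical values).
#' @param response Name of the response column (e.g. PQQ yield, mg/L).
#' @param factors Factor column names; defaults to every numeric
#'   column except the response.
#' @param kernel,C,gamma Hyperparameters of the cell.
#' @param cv A [cv_config()].
#' @param epsilon,degree Tube width and polynomial degree.
#' @param return_predictions Also return the out-of-fold predictions?
#' @return The CV MSE (scalar), or a list `(mse, predictions, fold)`
#'   when `return_predictions = TRUE`.
#' @export
svr_cv_mse <- function(data, response, factors = NULL,
                       kernel = "rbf", C = 1, gamma = 0.1,
                       cv = cv_config(), epsilon = 0.1, degree = 3,
                       return_predictions = FALSE) {
  factors <- factors %||% setdiff(names(data)[vapply(data, is.numeric,
                                                     logical(1))], response)
  dm <- response_matrix(data, response, factors)
  n <- nrow(dm$X)
  fold <- fold_assignments(n, cv)
  yhat <- numeric(n)
  for (f in seq_len(cv$folds)) {
    train <- fold != f
    fit <- fit_svm_scaled(dm$X[train, , drop = FALSE], dm$y[train],
                          kernel, C, gamma, epsilon, degree)
    yhat[!train] <- predict_svm_scaled(fit, dm$X[!train, , drop = FALSE])
  }
  mse <- mean((dm$y - yhat)^2)
  if (return_predictions) {
    return(list(mse = mse, predictions = yhat, fold = fold))
  }
  mse
}

#' Grid search for the best epsilon-SVR surrogate
#'
#' Evaluates the cross-validated MSE of every (kernel, C, gamma) cell
#' of the grid, picks the minimizer and refits it on the full table.
#' Ties are broken deterministically: smaller C, then smaller gamma,
#' then kernel order linear < polynomial < rbf < sigmoid (prefer the
#' flatter model). For the linear kernel, gamma does not enter the
#' kernel, so only the smallest grid gamma is evaluated.
#'
#' @inheritParams svr_cv_mse
#' @param grid A [svr_grid()].
#' @return An `svr_fit`: the winning cell, its CV MSE, the refit model
#'   with its scaler state, in-sample and cross-validated R^2, and the
#'   full cell table (see [tidy.svr_fit()]).
#' @export
svr_grid_search <- function(data, response, factors = NULL,
                            grid = svr_grid(), cv = cv_config()) {
  factors <- factors %||% setdiff(names(data)[vapply(data, is.numeric,
                                                     logical(1))], response)
  kernel_order <- c("linear", "polynomial", "rbf", "sigmoid")
  cells <- purrr::map_dfr(grid$kernels, function(k) {
    gammas <- if (k == "linear") grid$log2_gamma[1] else grid$log2_gamma
    tidyr::expand_grid(kernel = k, log2_C = grid$log2_C,
                       log2_gamma = gammas)
  })
  cells$cv_mse <- purrr::pmap_dbl(
    cells, function(kernel, log2_C, log2_gamma) {
      tryCatch(
        svr_cv_mse(data, response, factors, kernel,
                   C = 2^log2_C, gamma = 2^log2_gamma, cv = cv,
                   epsilon = grid$epsilon, degree = grid$degree),
        error = function(e) NA_real_)
    })
  if (all(is.na(cells$cv_mse))) {
    stop("every grid cell failed to fit; cells evaluated: ",
         nrow(cells))
  }
  ranked <- dplyr::arrange(
    dplyr::filter(cells, is.finite(.data$cv_mse)),
    .data$cv_mse, .data$log2_C, .data$log2_gamma,
    match(.data$kernel, kernel_order))
  best <- ranked[1, ]
  dm <- response_matrix(data, response, factors)
  refit <- fit_svm_scaled(dm$X, dm$y, best$kernel, 2^best$log2_C,
                          2^best$log2_gamma, grid$epsilon, grid$degree)
  insample <- predict_svm_scaled(refit, dm$X)
  ss_tot <- sum((dm$y - mean(dm$y))^2)
  out <- list(
    kernel = best$kernel,
    C = 2^best$log2_C,
    gamma = 2^best$log2_gamma,
    cv_mse = best$cv_mse,
    model = refit$model,
    scaler = refit$scaler,
    factors = factors,
    response = response,
    n = nrow(dm$X),
    cv = cv,
    grid = grid,
    cells = tibble::as_tibble(cells),
    r2_insample = 1 - sum((dm$y - insample)^2) / ss_tot,
    r2_cv = 1 - nrow(dm$X) * best$cv_mse / ss_tot)
  class(out) <- "svr_fit"
  out
}

#' @export
print.svr_fit <- function(x, ...) {
  cat("<svr_fit> epsilon-SVR surrogate on ", x$n, " runs, ",
      length(x$factors), " factors\n", sep = "")
  cat(sprintf("  kernel = %s, C = 2^%g, gamma = 2^%g\n",
              x$kernel, log2(x$C), log2(x$gamma)))
  cat(sprintf("  5-CV MSE = %.4g  (R2 cv = %.3f, R2 in-sample = %.3f)\n",
              x$cv_mse, x$r2_cv, x$r2_insample))
  invisible(x)
}

#' Predict from a fitted SVR surrogate
#'
#' @param object An `svr_fit`.
#' @param newdata Data frame containing the training factor columns
#'   (physical values); extra columns are ignored.
#' @param ... Unused.
#' @return Numeric vector of predicted responses (original units).
#' @export
predict.svr_fit <- function(object, newdata, ...) {
  missing <- setdiff(object$factors, names(newdata))
  if (length(missing)) {
    stop("newdata lacks training factor column: ", missing[1])
  }
  X <- as.matrix(as.data.frame(newdata)[, object$factors, drop = FALSE])
  storage.mode(X) <- "double"
  p <- predict_svm_scaled(list(model = object$model, scaler = object$scaler),
                          X)
  if (!all(is.finite(p))) stop("non-finite prediction")
  p
}

#' Tidy the grid-search cell table
#'
#' @param x An `svr_fit`.
#' @param ... Unused.
#' @return Tibble with one row per evaluated (kernel, C, gamma) cell
#'   and its cross-validated MSE.
#' @method tidy svr_fit
#' @export
tidy.svr_fit <- function(x, ...) x$cells

#' One-row model summary
#'
#' @param x An `svr_fit`.
#' @param ... Unused.
#' @method glance svr_fit
#' @export
glance.svr_fit <- function(x, ...) {
  tibble::tibble(kernel = x$kernel, C = x$C, gamma = x$gamma,
                 cv_mse = x$cv_mse, r2_cv = x$r2_cv,
                 r2_insample = x$r2_insample, n = x$n,
                 n_factors = length(x$factors),
                 cv_folds = x$cv$folds, cv_seed = x$cv$seed)
}
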