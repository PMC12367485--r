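#' Backward nonlinear feature screening
#'
#' Greedy backward elimination on cross-validated SVR error. Each round
#' computes the baseline CV MSE of the current factor set (MSE_0), then
#' for every factor j the CV MSE with that factor removed (MSE_j). If
#' the smallest MSE_j beats the baseline, the corresponding factor is
#' dropped and the round's minimum becomes the next baseline; otherwise
#' screening stops. Baselines therefore decrease strictly across
#' rounds, and the surviving set is never empty.
#'
#' By default hyperparameters are re-optimized by a full grid search
#' for every candidate subset, so each MSE is the best its subset can
#' achieve and comparisons are fair; `reoptimize = FALSE` instead
#' fixes (kernel, C, gamma) from one initial search and reuses them,
#' which is faster but can understate a subset's merit.
#'
#' @inheritParams svr_grid_search
#' @param min_features Floor on the retained set size (default 1).
#' @param reoptimize Re-run the grid search per candidate subset?
#' @return A `screening_trace`: per-round baselines, per-factor MSEs
#'   and exclusions (the shape of a screening table: rows = rounds,
#'   columns = factors), the retained factor set, and the final fit.
#' @export
backward_screen <- function(data, response, factors = NULL,
                            grid = svr_grid(), cv = cv_config(),
                            min_features = 1, reoptimize = TRUE) {
  factors <- factors %||% setdiff(names(data)[vapply(data, is.numeric,
                                                     logical(1))], response)
  if (length(factors) < min_features) {
    stop("fewer factors (", length(factors), ") than min_features (",
         min_features, ")")
  }
  fixed_hp <- NULL
  subset_fit <- function(subset) {
    if (reoptimize || is.null(fixed_hp)) {
      fit <- svr_grid_search(data, response, subset, grid, cv)
      if (!reoptimize && is.null(fixed_hp)) {
        fixed_hp <<- fit[c("kernel", "C", "gamma")]
      }
      return(fit)
    }
    mse <- svr_cv_mse(data, response, subset, fixed_hp$kernel,
                      fixed_hp$C, fixed_hp$gamma, cv,
                      grid$epsilon, grid$degree)
    list(kernel = fixed_hp$kernel, C = fixed_hp$C,
         gamma = fixed_hp$gamma, cv_mse = mse)
  }

  current <- factors
  fit <- subset_fit(current)
  baseline <- fit$cv_mse
  rounds <- list()
  repeat {
    if (length(current) <= min_features) {
      rounds[[length(rounds) + 1]] <- list(
        baseline_mse = baseline,
        per_feature_mse = stats::setNames(numeric(0), character(0)),
        excluded = NA_character_)
      break
    }
    cand <- lapply(current, function(f) subset_fit(setdiff(current, f)))
    mse_j <- stats::setNames(vapply(cand, `[[`, numeric(1), "cv_mse"),
                             current)
    round <- list(baseline_mse = baseline, per_feature_mse = mse_j,
                  excluded = NA_character_)
    jmin <- which(mse_j == min(mse_j))[1]   # tie: lowest column index
    if (mse_j[jmin] < baseline) {
      round$excluded <- current[jmin]
      rounds[[length(rounds) + 1]] <- round
      fit <- cand[[jmin]]
      baseline <- mse_j[[jmin]]
      current <- setdiff(current, current[jmin])
    } else {
      rounds[[length(rounds) + 1]] <- round
      break
    }
  }
  final_fit <- if (inherits(fit, "svr_fit") || !reoptimize) {
    if (inherits(fit, "svr_fit")) fit
    else svr_grid_search(data, response, current, grid, cv)
  } else {
    fit
  }
  structure(list(rounds = rounds, retained = current,
                 excluded = setdiff(factors, current),
                 factors = factors, final_fit = final_fit,
                 cv = cv, reoptimize = reoptimize),
            class = "screening_trace")
}

#' @export
print.screening_trace <- function(x, ...) {
  cat("<screening_trace> ", length(x$rounds), " rounds; retained: ",
      paste(x$retained, collapse = ", "), "\n", sep = "")
  wide <- tidyr::pivot_wider(tidy(x), names_from = "factor",
                             values_from = "mse")
  print(wide, ...)
  invisible(x)
}

#' Long-format screening table
#'
#' @param x A `screening_trace`.
#' @param ... Unused.
#' @return Tibble with one row per (round, candidate factor): the
#'   round's baseline MSE, the MSE with that factor removed, and the
#'   factor excluded at the end of the round (`NA` in the final round).
#' @method tidy screening_trace
#' @export
tidy.screening_trace <- function(x, ...) {
  purrr::imap_dfr(x$rounds, function(r, i) {
    if (length(r$per_feature_mse) == 0) {
      return(tibble::tibble(round = i, baseline_mse = r$baseline_mse,
                            factor = NA_character_, mse = NA_real_,
                            excluded = r$excluded))
    }
    tibble::tibble(round = i, baseline_mse = r$baseline_mse,
                   factor = names(r$per_feature_mse),
                   mse = unname(r$per_feature_mse),
                   excluded = r$excluded)
  })
}

#' One-row screening summary
#'
#' @param x A `screening_trace`.
#' @param ... Unused.
#' @method glance screening_trace
#' @export
glance.screening_trace <- function(x, ...) {
  tibble::tibble(
    n_rounds = length(x$rounds),
    n_factors = length(x$factors),
    n_retained = length(x$retained),
    retained = paste(x$retained, collapse = ","),
    excluded = paste(x$excluded, collapse = ","),
    initial_mse = x$rounds[[1]]$baseline_mse,
    final_mse = x$rounds[[length(x$rounds)]]$baseline_mse)
}

#' Plot the screening trajectory
#'
#' Baseline CV MSE per round (line) with each round's leave-one-factor
#' -out MSEs (points); the excluded factor is highlighted.
#'
#' @param object A `screening_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screening_trace
#' @export
autoplot.screening_trace <- function(object, ...) {
  long <- tidy(object)
  long$is_excluded <- !is.na(long$excluded) & long$factor == long$excluded
  ggplot2::ggplot(long, ggplot2::aes(x = .data$round)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$baseline_mse),
                       linewidth = 0.8, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mse,
                                     colour = .data$is_excluded),
                        na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#D55E00", `FALSE` = "grey60"),
      labels = c(`TRUE` = "excluded", `FALSE` = "kept"),
      name = NULL) +
    ggplot2::scale_x_continuous(breaks = unique(long$round)) +
    ggplot2::labs(x = "screening round",
                  y = "cross-validated MSE",
                  title = "Backward nonlinear feature screening") +
    ggplot2::theme_minimal()
}
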