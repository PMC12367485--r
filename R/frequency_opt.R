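# mixed-radix bookkeeping: combination g (1-based, lexicographic with
# the first factor most significant) has digit
#   idx_j = ((g-1) %/% radix_j) %% q_j + 1,  radix_j = prod(q[(j+1):m])
combo_radix <- function(q) {
  m <- length(q)
  rev(cumprod(rev(c(q[-1], 1))))
}

combo_indices <- function(g, q) {
  radix <- combo_radix(q)
  idx <- vapply(seq_along(q),
                function(j) ((g - 1) %/% radix[j]) %% q[j] + 1,
                numeric(length(g)))
  idx <- matrix(as.integer(idx), nrow = length(g))
  colnames(idx) <- names(q)
  idx
}

#' Enumerate all level combinations of a factor subset
#'
#' Deterministic lexicographic order (first factor most significant,
#' last factor varying fastest), no duplicates, exactly
#' [enumeration_size()] rows.
#'
#' @param grid A [ud_grid()].
#' @param subset Factor names to enumerate; `NULL` for all.
#' @param values Return physical values (default) or 1-based level
#'   indices?
#' @return Tibble with one column per factor in `subset`.
#' @export
enumerate_combinations <- function(grid, subset = NULL, values = TRUE) {
  g <- subset_grid(grid, subset)
  q <- level_counts(g)
  total <- prod(as.numeric(q))
  if (total > 5e6) {
    stop("enumeration of ", format(total, big.mark = ","),
         " combinations is too large to materialize; use predict_grid()")
  }
  idx <- combo_indices(seq_len(total), q)
  if (!values) return(tibble::as_tibble(as.data.frame(idx)))
  tibble::as_tibble(as.data.frame(index_to_values(idx, g)))
}

index_to_values <- function(idx, grid) {
  vals <- vapply(seq_len(ncol(idx)),
                 function(j) grid$levels[[j]][idx[, j]],
                 numeric(nrow(idx)))
  vals <- matrix(vals, nrow = nrow(idx))
  colnames(vals) <- grid$factor
  vals
}

#' Predict the surrogate over the full combination grid
#'
#' Evaluates a fitted surrogate on every level combination of the
#' retained factors, in chunks, so memory stays bounded however large
#' the enumeration is. Summary statistics (mean / max / min and the
#' best combination) are accumulated in the same single pass.
#'
#' @param fit An `svr_fit` trained on exactly `subset`.
#' @param grid A [ud_grid()] covering at least `subset`.
#' @param subset Factor names; defaults to the fit's training factors.
#' @param fixed Named numeric vector of values held constant for
#'   factors outside `subset` (bookkeeping only; they do not enter the
#'   model).
#' @param chunk_size Combinations evaluated per chunk.
#' @return A `prediction_grid`: predictions `yhat` in enumeration
#'   order plus the grid/subset and one-pass summary statistics.
#' @export
predict_grid <- function(fit, grid, subset = NULL, fixed = NULL,
                         chunk_size = 10000) {
  subset <- subset %||% fit$factors
  if (!setequal(subset, fit$factors)) {
    stop("surrogate was trained on {",
         paste(fit$factors, collapse = ", "),
         "} but subset is {", paste(subset, collapse = ", "), "}")
  }
  g <- subset_grid(grid, subset)
  q <- level_counts(g)
  total <- prod(as.numeric(q))
  yhat <- numeric(total)
  start <- 1
  while (start <= total) {
    end <- min(start + chunk_size - 1, total)
    idx <- combo_indices(seq(start, end), q)
    X <- tibble::as_tibble(as.data.frame(index_to_values(idx, g)))
    yhat[start:end] <- predict(fit, X)
    start <- end + 1
  }
  best <- which.max(yhat)
  best_combo <- tibble::as_tibble(
    as.data.frame(index_to_values(combo_indices(best, q), g)))
  structure(list(
    grid = g, subset = g$factor, yhat = yhat, fixed = fixed,
    n = total,
    stats = list(mean = mean(yhat), max = max(yhat), min = min(yhat)),
    best_combo = best_combo),
    class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat("<prediction_grid> ", format(x$n, big.mark = ","),
      " combinations of ", length(x$subset), " factors\n", sep = "")
  cat(sprintf("  predicted response: mean %.2f, max %.2f, min %.2f\n",
              x$stats$mean, x$stats$max, x$stats$min))
  invisible(x)
}

#' Histogram of full-grid predictions
#'
#' @param object A `prediction_grid`.
#' @param threshold Optional vertical reference line (response units).
#' @param ... Unused.
#' @method autoplot prediction_grid
#' @export
autoplot.prediction_grid <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(tibble::tibble(yhat = object$yhat),
                       ggplot2::aes(x = .data$yhat)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "predicted response",
                  y = "combinations",
                  title = "Full-combination surrogate predictions") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold,
                                 linetype = "dashed", colour = "#D55E00")
  }
  p
}

#' Level-frequency statistics of high-predicted combinations
#'
#' Selects the combinations whose prediction strictly exceeds
#' `threshold` and counts, for every factor, how often each level
#' occurs among them. A level that dominates suggests fixing the
#' factor there; a modal level sitting on the boundary of its tested
#' range suggests the optimum lies beyond it (extrapolation).
#'
#' @param pg A [predict_grid()] result.
#' @param threshold Selection threshold in response units (e.g. the 50
#'   mg/L used for a PQQ yield surface). `NULL` uses the 85th
#'   percentile of the predictions.
#' @return A `frequency_report`; see [frequency_report()] for fields.
#' @export
frequency_statistics <- function(pg, threshold = NULL) {
  threshold <- threshold %||%
    unname(stats::quantile(pg$yhat, 0.85, names = FALSE))
  if (!is.finite(threshold)) stop("threshold must be finite")
  sel <- which(pg$yhat > threshold)
  q <- level_counts(pg$grid)
  radix <- combo_radix(q)
  per_factor <- purrr::map_dfr(seq_along(q), function(j) {
    digits <- ((sel - 1) %/% radix[j]) %% q[j] + 1
    tibble::tibble(
      factor = names(q)[j],
      level_index = seq_len(q[j]),
      level_value = pg$grid$levels[[j]],
      count = tabulate(digits, nbins = q[j]))
  })
  frequency_report(per_factor, pg$grid, threshold = threshold,
                   n_total = pg$n, yhat_stats = pg$stats,
                   best_combo = pg$best_combo)
}

#' Assemble a frequency report from per-level counts
#'
#' Low-level constructor behind [frequency_statistics()]; also usable
#' directly when the per-level counts come from elsewhere (e.g. a
#' published frequency figure).
#'
#' @param per_factor Tibble with columns `factor`, `level_index`,
#'   `level_value`, `count` covering every level of every factor.
#' @param grid The [ud_grid()] the counts refer to.
#' @param threshold Selection threshold used (response units).
#' @param n_total Total combinations scored (optional).
#' @param yhat_stats Optional list(mean, max, min) of the predictions.
#' @param best_combo Optional one-row tibble: the combination with the
#'   highest prediction (its levels are always carried into the next
#'   round's grid).
#' @return A `frequency_report`: the counts plus, per factor, the
#'   modal and runner-up levels and a flag marking modes that sit on
#'   the boundary of the tested range.
#' @export
frequency_report <- function(per_factor, grid, threshold,
                             n_total = NA_real_, yhat_stats = NULL,
                             best_combo = NULL) {
  stopifnot(all(c("factor", "level_index", "level_value", "count")
                %in% names(per_factor)))
  sums <- dplyr::summarise(dplyr::group_by(per_factor, .data$factor),
                           total = sum(.data$count))
  if (length(unique(sums$total)) > 1) {
    stop("per-factor counts are inconsistent: every factor must sum ",
         "to the same number of selected combinations")
  }
  n_selected <- sums$total[1]
  modal <- dplyr::group_modify(
    dplyr::group_by(per_factor, .data$factor), function(d, key) {
      ord <- order(-d$count, d$level_index)   # tie: lower level
      q <- nrow(d)
      mi <- d$level_index[ord[1]]
      tibble::tibble(
        modal_value = d$level_value[ord[1]],
        modal_count = d$count[ord[1]],
        runner_up_value = if (q >= 2) d$level_value[ord[2]] else NA_real_,
        runner_up_count = if (q >= 2) d$count[ord[2]] else NA_real_,
        at_boundary = mi == 1L || mi == q,
        boundary_side = if (mi == 1L) "lower"
                        else if (mi == q) "upper" else NA_character_)
    })
  modal <- dplyr::ungroup(modal)
  modal <- modal[match(unique(per_factor$factor), modal$factor), ]
  structure(list(
    threshold = threshold,
    n_selected = as.integer(n_selected),
    n_total = n_total,
    per_factor = tibble::as_tibble(per_factor),
    modal = modal,
    yhat_stats = yhat_stats,
    best_combo = best_combo,
    grid = grid,
    warning_empty = n_selected == 0),
    class = "frequency_report")
}

#' @export
print.frequency_report <- function(x, ...) {
  cat("<frequency_report> ", x$n_selected, " combinations above ",
      format(x$threshold, digits = 4), sep = "")
  if (is.finite(x$n_total)) cat(" (of ", format(x$n_total, big.mark = ","),
                                ")", sep = "")
  cat("\n")
  if (x$warning_empty) {
    cat("  ! no combination exceeds the threshold\n")
  }
  print(x$modal, ...)
  invisible(x)
}

#' Tidy per-level frequency counts
#'
#' @param x A `frequency_report`.
#' @param ... Unused.
#' @method tidy frequency_report
#' @export
tidy.frequency_report <- function(x, ...) x$per_factor

#' Plot level frequencies among high-predicted combinations
#'
#' One panel per factor: frequency of each tested level among the
#' combinations above threshold; boundary modal levels signal
#' extrapolation.
#'
#' @param object A `frequency_report`.
#' @param ... Unused.
#' @method autoplot frequency_report
#' @export
autoplot.frequency_report <- function(object, ...) {
  d <- object$per_factor
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$level_value),
                                  y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(
      x = "tested level",
      y = sprintf("frequency above threshold (n = %d)",
                  object$n_selected),
      title = "Level frequencies among high-predicted combinations") +
    ggplot2::theme_minimal()
}

# lower median of a level vector (even counts take the lower of the two)
lower_median <- function(levels) levels[floor((length(levels) + 1) / 2)]

#' Plan the next experimental round
#'
#' Turns a frequency report into fix / extrapolate recommendations:
#' \itemize{
#'   \item screened-out factors are fixed at the (lower) median of
#'     their tested levels;
#'   \item a factor whose modal level is interior and dominant
#'     (modal count at least `dominance_ratio` times the runner-up)
#'     is fixed at that level;
#'   \item otherwise the factor stays active: its next-round levels
#'     keep the modal level, the runner-up when the mode is not
#'     dominant, the level carried by the single best-predicted
#'     combination, and — when the mode sits on a boundary of the
#'     tested range — one inter-level step beyond that boundary
#'     (direction `extend_up` / `extend_down`).
#' }
#' Active grids are trimmed to at most `max_levels` levels with
#' priority extension > mode > best-combination level > runner-up.
#'
#' @param report A [frequency_statistics()] report.
#' @param grid The round's full [ud_grid()] (screened-out factors
#'   included).
#' @param screened_out Names of factors dropped by screening.
#' @param dominance_ratio Mode/runner-up count ratio above which an
#'   interior mode fixes its factor (default 1.25).
#' @param max_levels Maximum levels per active factor next round.
#' @return A `round_plan`: `fixed` (factor, value, reason), `active`
#'   (a [ud_grid()] for the next round, possibly empty) and
#'   `directions` (factor, direction in keep / shrink / extend_up /
#'   extend_down). An empty active set means the optimization has
#'   converged.
#' @export
recommend <- function(report, grid, screened_out = character(),
                      dominance_ratio = 1.25, max_levels = 3) {
  retained <- report$modal$factor
  stopifnot(length(intersect(retained, screened_out)) == 0)
  fixed <- purrr::map_dfr(screened_out, function(f) {
    tibble::tibble(factor = f,
                   value = lower_median(grid_levels(grid, f)[[1]]),
                   reason = "screened_out_median")
  })
  active_levels <- list()
  directions <- list()
  for (f in retained) {
    mrow <- report$modal[report$modal$factor == f, ]
    lv <- grid_levels(grid, f)[[1]]
    dominant <- is.na(mrow$runner_up_count) ||
      mrow$modal_count >= dominance_ratio * max(mrow$runner_up_count, 1)
    if (!mrow$at_boundary && dominant) {
      fixed <- dplyr::bind_rows(fixed, tibble::tibble(
        factor = f, value = mrow$modal_value, reason = "frequency_fixed"))
      next
    }
    best_lv <- if (!is.null(report$best_combo) &&
                   f %in% names(report$best_combo)) {
      report$best_combo[[f]][1]
    } else {
      NA_real_
    }
    ext <- NA_real_
    dir <- "keep"
    if (mrow$at_boundary && mrow$boundary_side == "lower") {
      ext <- mrow$modal_value - (lv[2] - lv[1])
      dir <- "extend_down"
    } else if (mrow$at_boundary && mrow$boundary_side == "upper") {
      ext <- mrow$modal_value + (lv[length(lv)] - lv[length(lv) - 1])
      dir <- "extend_up"
    }
    cand <- c(ext, mrow$modal_value,
              best_lv, if (!dominant) mrow$runner_up_value)
    cand <- cand[is.finite(cand)]
    cand <- cand[!duplicated(cand)][seq_len(min(max_levels,
                                                sum(!duplicated(cand))))]
    new_lv <- sort(cand)
    if (dir == "keep" && length(new_lv) < length(lv)) dir <- "shrink"
    active_levels[[f]] <- new_lv
    directions[[f]] <- dir
  }
  active <- if (length(active_levels)) {
    keep <- names(active_levels)
    ud_grid(active_levels,
            units = stats::setNames(grid$unit[match(keep, grid$factor)],
                                    keep),
            roles = stats::setNames(grid$role[match(keep, grid$factor)],
                                    keep))
  } else {
    NULL
  }
  structure(list(
    fixed = fixed,
    active = active,
    directions = tibble::tibble(
      factor = names(directions),
      direction = unlist(directions) %||% character(0)),
    converged = is.null(active)),
    class = "round_plan")
}

#' @export
print.round_plan <- function(x, ...) {
  cat("<round_plan>", if (x$converged) "converged" else
    paste(nrow(x$active), "factors active next round"), "\n")
  if (nrow(x$fixed)) {
    cat("fixed:\n")
    print(x$fixed, ...)
  }
  if (!x$converged) {
    cat("active (with direction):\n")
    print(dplyr::left_join(
      tibble::tibble(factor = x$active$factor,
                     levels = vapply(x$active$levels, paste,
                                     character(1), collapse = ", ")),
      x$directions, by = "factor"), ...)
  }
  invisible(x)
}

#' Percent improvement of a new response over a baseline
#'
#' 100 * (y_new - y_base) / y_base, rounded to 2 decimals.
#'
#' @param y_new,y_base Response values; `y_base` must be positive.
#' @export
percent_improvement <- function(y_new, y_base) {
  if (any(y_base <= 0)) stop("baseline response must be positive")
  round(100 * (y_new - y_base) / y_base, 2)
}

#' Counts and proportions of responses above cutoffs
#'
#' @param y Numeric responses (one per treatment).
#' @param cutoffs Numeric vector of thresholds; strict inequality.
#' @return Tibble with `cutoff`, `count` (of y > cutoff) and `percent`
#'   (to 2 decimals).
#' @export
threshold_proportions <- function(y, cutoffs) {
  if (length(y) == 0) stop("empty response vector")
  purrr::map_dfr(cutoffs, function(ct) {
    n <- sum(y > ct)
    tibble::tibble(cutoff = ct, count = n,
                   percent = round(100 * n / length(y), 2))
  })
}
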