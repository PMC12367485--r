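#' Run one complete optimization round
#'
#' The full per-round pipeline on a measured treatment table:
#' validate, backward-screen the factors, refit the surrogate on the
#' retained set, predict every level combination of the retained
#' factors, compute level-frequency statistics above the threshold,
#' and derive the next-round plan. Convergence is declared when the
#' plan leaves no factor active.
#'
#' @param data Treatment table: one row per run, physical factor
#'   values plus the measured response.
#' @param grid The round's [ud_grid()].
#' @param response Response column name.
#' @param svr A [svr_grid()] hyperparameter grid.
#' @param cv A [cv_config()]; its seed is recorded in the report.
#' @param threshold Selection threshold in response units (`NULL`:
#'   85th percentile of the predictions).
#' @param min_features,reoptimize Passed to [backward_screen()].
#' @param dominance_ratio,max_levels Passed to [recommend()].
#' @param chunk_size Passed to [predict_grid()].
#' @return A `ud_round` holding every stage artifact: `trace`
#'   (screening), `fit`, `predictions`, `report`, `plan`, `converged`.
#' @export
run_round <- function(data, grid, response, svr = svr_grid(),
                      cv = cv_config(), threshold = NULL,
                      min_features = 1, reoptimize = TRUE,
                      dominance_ratio = 1.25, max_levels = 3,
                      chunk_size = 10000) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  stage("validate", {
    v <- validate_response_table(data, grid, response)
    if (nrow(v) > 0) {
      stop("treatment table invalid: ",
           paste(v$message, collapse = "; "))
    }
  })
  trace <- stage("screen", backward_screen(
    data, response, factors = grid$factor, grid = svr, cv = cv,
    min_features = min_features, reoptimize = reoptimize))
  fixed_assignment <- stats::setNames(
    vapply(trace$excluded,
           function(f) lower_median(grid_levels(grid, f)[[1]]),
           numeric(1)),
    trace$excluded)
  pg <- stage("predict", predict_grid(
    trace$final_fit, grid, subset = trace$retained,
    fixed = fixed_assignment, chunk_size = chunk_size))
  report <- stage("frequency", frequency_statistics(pg, threshold))
  plan <- stage("recommend", recommend(
    report, grid, screened_out = trace$excluded,
    dominance_ratio = dominance_ratio, max_levels = max_levels))
  structure(list(
    trace = trace, fit = trace$final_fit, predictions = pg,
    report = report, plan = plan, converged = plan$converged,
    response = response, grid = grid,
    config = list(cv = cv, svr = svr, threshold = report$threshold,
                  min_features = min_features,
                  reoptimize = reoptimize,
                  dominance_ratio = dominance_ratio,
                  max_levels = max_levels)),
    class = "ud_round")
}

#' @export
print.ud_round <- function(x, ...) {
  cat("<ud_round> ", if (x$converged) "converged" else "continue", "\n",
      sep = "")
  cat("  retained: ", paste(x$trace$retained, collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  surrogate: %s kernel, 5-CV MSE %.3f\n",
              x$fit$kernel, x$fit$cv_mse))
  cat(sprintf("  predictions: %s combos, %d above %.4g\n",
              format(x$predictions$n, big.mark = ","),
              x$report$n_selected, x$report$threshold))
  invisible(x)
}

#' One-row round summary
#'
#' @param x A `ud_round`.
#' @param ... Unused.
#' @method glance ud_round
#' @export
glance.ud_round <- function(x, ...) {
  tibble::tibble(
    n_runs = x$fit$n,
    n_factors = length(x$trace$factors),
    n_retained = length(x$trace$retained),
    kernel = x$fit$kernel, cv_mse = x$fit$cv_mse,
    n_combos = x$predictions$n,
    threshold = x$report$threshold,
    n_selected = x$report$n_selected,
    yhat_max = x$predictions$stats$max,
    converged = x$converged)
}

round_report_list <- function(x) {
  list(
    config = list(
      response = x$response,
      cv = unclass(x$config$cv),
      svr_grid = unclass(x$config$svr),
      threshold = x$config$threshold,
      min_features = x$config$min_features,
      reoptimize = x$config$reoptimize,
      dominance_ratio = x$config$dominance_ratio,
      max_levels = x$config$max_levels),
    grid = stats::setNames(x$grid$levels, x$grid$factor),
    screening = as.data.frame(tidy(x$trace)),
    retained = x$trace$retained,
    excluded = x$trace$excluded,
    fit = list(kernel = x$fit$kernel, C = x$fit$C,
               gamma = x$fit$gamma, cv_mse = x$fit$cv_mse,
               r2_cv = x$fit$r2_cv, r2_insample = x$fit$r2_insample,
               scaler = lapply(x$fit$scaler, as.list)),
    predictions = list(n = x$predictions$n,
                       stats = x$predictions$stats,
                       best_combo = as.data.frame(x$predictions$best_combo),
                       fixed_assignment = as.list(x$predictions$fixed)),
    frequency = list(threshold = x$report$threshold,
                     n_selected = x$report$n_selected,
                     per_factor = as.data.frame(x$report$per_factor),
                     modal = as.data.frame(x$report$modal),
                     empty_selection = x$report$warning_empty),
    plan = list(fixed = as.data.frame(x$plan$fixed),
                active = if (x$plan$converged) NULL else
                  stats::setNames(x$plan$active$levels,
                                  x$plan$active$factor),
                directions = as.data.frame(x$plan$directions),
                converged = x$plan$converged))
}

#' Write a machine-readable round report
#'
#' Serializes every stage artifact of a round (screening table, chosen
#' hyperparameters and scaler state, prediction summaries, frequency
#' counts, next-round plan, and all seeds) as JSON. Identical inputs
#' and configuration produce byte-identical reports: nothing
#' time-dependent is written.
#'
#' @param x A [run_round()] result.
#' @param path Output file path.
#' @export
write_round_report <- function(x, path) {
  stopifnot(inherits(x, "ud_round"))
  jsonlite::write_json(round_report_list(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Simulate a full two-round optimization campaign in silico
#'
#' Wires the synthetic landscape in as the oracle the wet lab would
#' be: generate a uniform design, "measure" it by sampling the
#' landscape, run the round pipeline, build the recommended next-round
#' design (screened-out and frequency-fixed factors held at their
#' planned values), measure and model again. Used to check that the
#' loop moves the best measured response toward the landscape optimum.
#'
#' @param spec A [landscape_spec()].
#' @param n1,n2 Run counts of the two rounds.
#' @param seed Master seed; the design searches, simulated noise and
#'   CV folds all derive from it (seed, seed+1, seed+2).
#' @param svr,cv_folds,threshold,budget Stage settings; `budget` is
#'   the design-search budget.
#' @param ... Further arguments passed to [run_round()].
#' @return A list: `round1`, `round2` (`ud_round`s; `round2` is `NULL`
#'   when round 1 converged), `data1`, `data2`, `best_y1`, `best_y2`.
#' @export
simulate_campaign <- function(spec, n1 = 40, n2 = 26, seed = 1,
                              svr = svr_grid(), cv_folds = 5,
                              threshold = NULL, budget = 2000, ...) {
  landscape <- make_landscape(spec)
  design1 <- generate_uniform_design(spec$grid, n1, budget = budget,
                                     seed = seed)
  data1 <- simulate_round(design1, landscape, seed = seed + 1)
  r1 <- run_round(data1, spec$grid, "pqq", svr = svr,
                  cv = cv_config(cv_folds, seed = seed),
                  threshold = threshold, ...)
  best_y1 <- max(data1$pqq)
  if (r1$converged) {
    return(list(round1 = r1, round2 = NULL, data1 = data1,
                data2 = NULL, best_y1 = best_y1, best_y2 = NA_real_))
  }
  grid2 <- r1$plan$active
  # a recommended grid smaller than the round budget is measured as a
  # full factorial instead (no point duplicating treatments)
  n2_eff <- min(n2, enumeration_size(grid2))
  design2 <- generate_uniform_design(grid2, n2_eff, budget = budget,
                                     seed = seed + 1)
  data2 <- tibble::as_tibble(as.data.frame(design2))
  for (i in seq_len(nrow(r1$plan$fixed))) {
    data2[[r1$plan$fixed$factor[i]]] <- r1$plan$fixed$value[i]
  }
  data2 <- simulate_round(data2, landscape, seed = seed + 2)
  r2 <- run_round(data2[, c("run", grid2$factor, "pqq")], grid2, "pqq",
                  svr = svr,
                  cv = cv_config(min(cv_folds, n2_eff), seed = seed + 1),
                  threshold = threshold, ...)
  list(round1 = r1, round2 = r2, data1 = data1, data2 = data2,
       best_y1 = best_y1, best_y2 = max(data2$pqq))
}
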