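#' Define a multi-factor level grid
#'
#' A level grid names the experimental factors and the ordered numeric
#' levels each may take (physical values: g/L, degrees C, pH units, ...).
#' It is the shared vocabulary of every stage: design construction,
#' surrogate fitting, exhaustive prediction and round planning.
#'
#' @param levels Named list; one entry per factor, each a strictly
#'   increasing numeric vector of at least 2 finite values.
#' @param units Optional named character vector of unit strings.
#' @param roles Optional named character vector, each either
#'   `"medium_component"` or `"process_parameter"`.
#' @return A `ud_grid`: a tibble with columns `factor`, `unit`, `role`
#'   and a `levels` list-column.
#' @examples
#' ud_grid(list(glucose = c(5, 10, 15), temperature = c(28, 30)),
#'         units = c(glucose = "g/L", temperature = "degC"))
#' @export
ud_grid <- function(levels, units = NULL, roles = NULL) {
  if (!is.list(levels) || length(levels) == 0 || is.null(names(levels)) ||
      any(names(levels) == "")) {
    stop("`levels` must be a non-empty named list of numeric vectors")
  }
  nm <- names(levels)
  if (anyDuplicated(nm)) {
    stop("duplicate factor name: ", nm[duplicated(nm)][1])
  }
  for (f in nm) {
    lv <- levels[[f]]
    if (!is.numeric(lv) || length(lv) < 2) {
      stop("factor '", f, "' needs at least 2 numeric levels")
    }
    if (!all(is.finite(lv))) stop("factor '", f, "' has non-finite levels")
    if (any(diff(lv) <= 0)) {
      stop("levels of factor '", f, "' must be strictly increasing")
    }
  }
  unit <- rep("", length(nm))
  names(unit) <- nm
  if (!is.null(units)) unit[names(units)] <- units
  role <- rep("medium_component", length(nm))
  names(role) <- nm
  if (!is.null(roles)) {
    bad <- setdiff(roles, c("medium_component", "process_parameter"))
    if (length(bad)) stop("unknown role: ", bad[1])
    role[names(roles)] <- roles
  }
  out <- tibble::tibble(
    factor = nm,
    unit = unname(unit),
    role = unname(role),
    levels = lapply(levels, as.numeric)
  )
  class(out) <- c("ud_grid", class(out))
  out
}

#' @export
print.ud_grid <- function(x, ...) {
  cat("<ud_grid> ", nrow(x), " factors, ",
      format(enumeration_size(x), big.mark = ","),
      " full-grid combinations\n", sep = "")
  desc <- tibble::tibble(
    factor = x$factor,
    unit = x$unit,
    role = x$role,
    n_levels = vapply(x$levels, length, integer(1)),
    levels = vapply(x$levels, function(l) paste(l, collapse = ", "),
                    character(1))
  )
  print(desc, ...)
  invisible(x)
}

grid_levels <- function(grid, factor) {
  i <- match(factor, grid$factor)
  if (anyNA(i)) stop("unknown factor name: ", factor[is.na(i)][1])
  grid$levels[i]
}

level_counts <- function(grid, subset = NULL) {
  g <- subset_grid(grid, subset)
  stats::setNames(vapply(g$levels, length, integer(1)), g$factor)
}

subset_grid <- function(grid, subset = NULL) {
  if (is.null(subset)) return(grid)
  if (length(subset) == 0) stop("factor subset must be non-empty")
  i <- match(subset, grid$factor)
  if (anyNA(i)) stop("unknown factor name: ", subset[is.na(i)][1])
  grid[i, ]
}

#' Number of full-grid combinations
#'
#' Product of the per-factor level counts over `subset` (all factors by
#' default), computed without materializing the enumeration.
#'
#' @param grid A [ud_grid()].
#' @param subset Character vector of factor names, or `NULL` for all.
#' @return A single number (exact for any grid whose size fits in a
#'   double).
#' @examples
#' g <- ud_grid(list(a = 1:5, b = 1:4))
#' enumeration_size(g)            # 20
#' enumeration_size(g, "b")       # 4
#' @export
enumeration_size <- function(grid, subset = NULL) {
  prod(as.numeric(level_counts(grid, subset)))
}

#' Build a design table from level indices
#'
#' @param indices Integer matrix (runs by factors) of 1-based level
#'   indices; displayed as L1, L2, ... in reports.
#' @param grid The [ud_grid()] the indices refer to.
#' @return A `ud_design`: a tibble with a `run` id column and one column
#'   of physical values per factor; the index matrix is kept in the
#'   `indices` attribute.
#' @export
ud_design <- function(indices, grid) {
  indices <- as.matrix(indices)
  storage.mode(indices) <- "integer"
  if (ncol(indices) != nrow(grid)) {
    stop("design has ", ncol(indices), " columns but grid has ",
         nrow(grid), " factors")
  }
  colnames(indices) <- grid$factor
  q <- level_counts(grid)
  for (j in seq_along(q)) {
    bad <- which(indices[, j] < 1L | indices[, j] > q[j])
    if (length(bad)) {
      stop("level index out of range in run ", bad[1], ", factor '",
           grid$factor[j], "'")
    }
  }
  vals <- vapply(seq_along(q),
                 function(j) grid$levels[[j]][indices[, j]],
                 numeric(nrow(indices)))
  vals <- matrix(vals, nrow = nrow(indices))
  colnames(vals) <- grid$factor
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- tibble::add_column(out, run = paste0("N", seq_len(nrow(out))),
                            .before = 1)
  attr(out, "grid") <- grid
  attr(out, "indices") <- indices
  class(out) <- c("ud_design", class(out))
  out
}

#' Recover 1-based level indices from physical values
#'
#' @param data Data frame holding one column of physical values per
#'   factor of `grid`.
#' @param grid A [ud_grid()].
#' @param tol Absolute tolerance when matching values to levels.
#' @return Integer matrix of level indices; `NA` where a value matches
#'   no level.
#' @export
level_index <- function(data, grid, tol = 1e-8) {
  missing <- setdiff(grid$factor, names(data))
  if (length(missing)) stop("missing factor column: ", missing[1])
  idx <- vapply(seq_len(nrow(grid)), function(j) {
    lv <- grid$levels[[j]]
    x <- data[[grid$factor[j]]]
    i <- vapply(x, function(v) {
      d <- abs(lv - v)
      k <- which.min(d)
      if (length(k) && d[k] <= tol) k else NA_integer_
    }, integer(1))
    i
  }, integer(nrow(data)))
  idx <- matrix(idx, nrow = nrow(data))
  colnames(idx) <- grid$factor
  idx
}

#' Validate a design/response table against its grid
#'
#' Checks, without raising, every structural invariant a treatment
#' table must satisfy before modeling: all factor columns present,
#' every value on the factor's level lattice, no duplicated runs
#' (compared on level indices), and — when a response column is named —
#' one finite non-negative response per run.
#'
#' @param data Data frame of treatments (physical values).
#' @param grid A [ud_grid()].
#' @param response Optional name of the response column.
#' @return A tibble of violations (`row`, `column`, `rule`, `message`);
#'   zero rows when the table is well formed.
#' @export
validate_response_table <- function(data, grid, response = NULL) {
  v <- list()
  add <- function(row, column, rule, message) {
    v[[length(v) + 1]] <<- tibble::tibble(
      row = as.integer(row), column = column, rule = rule,
      message = message)
  }
  missing <- setdiff(grid$factor, names(data))
  for (f in missing) {
    add(NA, f, "missing_factor_column",
        paste0("factor column '", f, "' not found"))
  }
  present <- intersect(grid$factor, names(data))
  if (length(present)) {
    idx <- level_index(data, grid[match(present, grid$factor), ])
    for (j in seq_along(present)) {
      bad <- which(is.na(idx[, j]))
      for (r in bad) {
        add(r, present[j], "value_off_lattice",
            paste0("row ", r, ", factor '", present[j], "': value ",
                   data[[present[j]]][r], " matches no tested level"))
      }
    }
    if (length(present) == nrow(grid) && !anyNA(idx)) {
      key <- apply(idx, 1, paste, collapse = "/")
      dup <- which(duplicated(key))
      for (r in dup) {
        add(r, NA_character_, "duplicate_run",
            paste0("row ", r, " duplicates an earlier treatment"))
      }
    }
  }
  if (!is.null(response)) {
    if (!response %in% names(data)) {
      add(NA, response, "missing_response_column",
          paste0("response column '", response, "' not found"))
    } else {
      y <- data[[response]]
      for (r in which(!is.finite(y))) {
        add(r, response, "non_finite_response",
            paste0("row ", r, ": response is not finite"))
      }
      for (r in which(is.finite(y) & y < 0)) {
        add(r, response, "negative_response",
            paste0("row ", r, ": response ", y[r], " is negative"))
      }
    }
  }
  if (length(v) == 0) {
    return(tibble::tibble(row = integer(), column = character(),
                          rule = character(), message = character()))
  }
  dplyr::bind_rows(v)
}

#' Read / write treatment tables
#'
#' Plain-CSV round trip for designs and design+response tables: one
#' column per factor holding physical values, an optional run-id
#' column, and any response columns as-is.
#'
#' @param data Data frame to write.
#' @param path File path.
#' @return `read_design_csv()` returns a tibble; `write_design_csv()`
#'   returns `path` invisibly.
#' @export
write_design_csv <- function(data, path) {
  readr::write_csv(as.data.frame(data), path)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read / write factor definitions as YAML
#'
#' The on-disk factor config is a YAML map: one entry per factor with
#' `levels` (required), `unit` and `role` (optional), in grid order.
#'
#' @param grid A [ud_grid()].
#' @param path File path.
#' @export
write_factor_yaml <- function(grid, path) {
  cfg <- lapply(seq_len(nrow(grid)), function(i) {
    list(unit = grid$unit[i], role = grid$role[i],
         levels = grid$levels[[i]])
  })
  names(cfg) <- grid$factor
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_factor_yaml
#' @export
read_factor_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  ud_grid(
    levels = lapply(cfg, function(x) as.numeric(x$levels)),
    units = vapply(cfg, function(x) x$unit %||% "", character(1)),
    roles = vapply(cfg, function(x) x$role %||% "medium_component",
                   character(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run a block with a private RNG stream; global .Random.seed untouched
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
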