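#' One-way sensitivity of the ICER to a single parameter
#'
#' Recomputes the incremental result with the chosen parameter set to
#' its minimum and then to its maximum (its 95%-interval bounds in the
#' packaged table), all other parameters held at base.  Ends where one
#' strategy dominates are reported as statuses, not coerced to numbers;
#' the spread is the absolute ICER difference and is only defined when
#' both ends yield a ratio.
#'
#' @param model a `cea_model`.
#' @param params a `cea_parameters` tibble.
#' @param parameter name of the parameter to vary.
#' @return one-row tibble: `parameter`, `icer_at_min`, `status_at_min`,
#'   `icer_at_max`, `status_at_max`, `spread`.
#' @export
one_way <- function(model, params, parameter) {
  if (!parameter %in% params$name) {
    stop("parameter '", parameter, "' not in the parameter table",
         call. = FALSE)
  }
  base <- base_assignment(params)
  row <- params[params$name == parameter, ]
  at_value <- function(value) {
    assignment <- base
    assignment[[parameter]] <- value
    incremental(rollback(model, assignment))
  }
  lo <- at_value(row$min)
  hi <- at_value(row$max)
  spread <- if (lo$status == "icer" && hi$status == "icer") {
    abs(lo$icer - hi$icer)
  } else {
    NA_real_
  }
  tibble::tibble(
    parameter = parameter,
    icer_at_min = lo$icer, status_at_min = lo$status,
    icer_at_max = hi$icer, status_at_max = hi$status,
    spread = spread
  )
}

#' Tornado-diagram table
#'
#' Runs [one_way()] for every parameter and orders the entries for a
#' tornado diagram: finite spreads descending, ties broken by parameter
#' name, and entries whose spread is undefined (a dominance status at
#' either end) after all finite-spread entries.  The ordering is a pure
#' function of the model and parameter table, so it is identical across
#' runs and input permutations.
#'
#' @param model a `cea_model`.
#' @param params a `cea_parameters` tibble.
#' @return a tibble of [one_way()] rows, sorted; carries attribute
#'   `n_varying` (parameters with `min < max`).  If no parameter
#'   varies, the result is empty with `n_varying = 0`.
#' @export
tornado <- function(model, params) {
  entries <- do.call(rbind, lapply(sort(params$name), function(nm) {
    one_way(model, params, nm)
  }))
  varying <- params$min < params$max
  if (!any(varying)) {
    out <- entries[0, ]
    attr(out, "n_varying") <- 0L
    return(out)
  }
  finite <- !is.na(entries$spread)
  fin <- entries[finite, , drop = FALSE]
  fin <- fin[order(-fin$spread, fin$parameter), , drop = FALSE]
  inf <- entries[!finite, , drop = FALSE]
  inf <- inf[order(inf$parameter), , drop = FALSE]
  out <- rbind(fin, inf)
  attr(out, "n_varying") <- sum(varying)
  out
}

#' Write a tornado table to CSV
#'
#' @param entries output of [tornado()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(entries, path) {
  utils::write.csv(as.data.frame(entries), path, row.names = FALSE)
  invisible(path)
}
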