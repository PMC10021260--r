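#' @noRd
PARAM_COLUMNS <- c("name", "role", "arm", "base", "min", "max", "sd",
                   "distribution", "source")

#' Load a model parameter table
#'
#' Reads a parameter table (CSV, or a JSON array of row objects) holding
#' one row per model input: arm-specific average costs per diagnosed
#' case, proportions diagnosed severe, and the sensitivity/specificity
#' of each diagnostic strategy.  Every row is validated against the
#' parameter invariants before it is returned (see
#' [validate_parameters()]).
#'
#' @param path path to a CSV file with header
#'   `name,role,arm,base,min,max,sd,distribution,source`, or a JSON file
#'   holding an array of objects with the same fields.
#' @return a `cea_parameters` tibble, one validated row per parameter.
#' @seealso [default_parameters()] for the packaged base-case table.
#' @examples
#' params <- default_parameters()
#' nrow(params)  # 10
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("parameter file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validate_parameters(df)
}

#' Packaged base-case parameter table
#'
#' The ten base-case model inputs shipped with the package: four
#' arm-specific average costs per diagnosed case (gamma), two
#' proportions diagnosed severe (beta), and the sensitivity and
#' specificity of each strategy (beta).  The combined-strategy
#' specificity is assumed equal to that of IMCI alone and by default
#' shares one draw with it in the probabilistic analysis (see
#' [psa_config()]).
#'
#' @return a validated `cea_parameters` tibble with 10 rows.
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "model_parameters.csv",
                              package = "oxicea", mustWork = TRUE))
}

#' Validate a parameter table
#'
#' Checks structure and per-row invariants:
#' * `min <= base <= max`;
#' * `sd >= 0`, and `sd = 0` only for `distribution = "fixed"`;
#' * probabilities lie in \[0, 1\] and use a beta or fixed distribution;
#' * costs are non-negative and use a gamma or fixed distribution.
#'
#' @param df a data frame with the columns listed in [load_parameters()].
#' @return the table as a `cea_parameters` tibble.
#' @export
validate_parameters <- function(df) {
  missing_cols <- setdiff(PARAM_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("parameter table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[PARAM_COLUMNS]
  for (col in c("base", "min", "max", "sd")) {
    vals <- df[[col]]
    if (is.character(vals)) {
      suppressWarnings(vals <- as.numeric(vals))
    }
    if (!is.numeric(vals) || anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("parameter '%s': column '%s' is not numeric",
                   df$name[bad], col), call. = FALSE)
    }
    df[[col]] <- as.numeric(vals)
  }
  if (anyDuplicated(df$name)) {
    stop("duplicated parameter name: ",
         df$name[anyDuplicated(df$name)], call. = FALSE)
  }
  fail <- function(row, rule) {
    stop(sprintf("parameter '%s' violates rule: %s", row$name, rule),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!row$role %in% c("cost", "probability")) {
      fail(row, "role must be 'cost' or 'probability'")
    }
    if (!row$arm %in% c("intervention", "control", "shared")) {
      fail(row, "arm must be 'intervention', 'control' or 'shared'")
    }
    if (!row$distribution %in% c("gamma", "beta", "fixed")) {
      fail(row, "distribution must be 'gamma', 'beta' or 'fixed'")
    }
    if (!(row$min <= row$base && row$base <= row$max)) {
      fail(row, "min <= base <= max")
    }
    if (row$sd < 0) fail(row, "sd >= 0")
    if (row$sd == 0 && row$distribution != "fixed") {
      fail(row, "sd = 0 only allowed with distribution = 'fixed'")
    }
    if (row$role == "probability") {
      if (row$min < 0 || row$max > 1) {
        fail(row, "probability bounds must lie in [0, 1]")
      }
      if (!row$distribution %in% c("beta", "fixed")) {
        fail(row, "probability parameters use beta or fixed distributions")
      }
    } else {
      if (row$base < 0) fail(row, "cost must be non-negative")
      if (!row$distribution %in% c("gamma", "fixed")) {
        fail(row, "cost parameters use gamma or fixed distributions")
      }
    }
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("cea_parameters", class(out))
  out
}

#' Write a parameter table
#'
#' Serializes a parameter table back to CSV or JSON, the two formats
#' accepted by [load_parameters()].  A load/write/load round trip is
#' value-identical.
#'
#' @param params a `cea_parameters` tibble.
#' @param path output path; the extension (`.csv` or `.json`) selects
#'   the format.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  df <- as.data.frame(params)[PARAM_COLUMNS]
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Fit a gamma distribution by method of moments
#'
#' Returns the gamma shape and scale whose mean and standard deviation
#' equal the supplied values: `shape = (mean/sd)^2`,
#' `scale = sd^2/mean`.  Used to propagate the uncertainty of cost
#' parameters in the probabilistic sensitivity analysis.
#'
#' @param mean distribution mean (USD), strictly positive.
#' @param sd distribution standard deviation (USD), strictly positive.
#' @return a `cea_dist` object with fields `family`, `shape_a` (shape)
#'   and `shape_b` (scale).
#' @examples
#' gamma_from_mean_sd(25.74, 3.62)
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) || mean <= 0 || sd <= 0) {
    stop("gamma_from_mean_sd() requires mean > 0 and sd > 0", call. = FALSE)
  }
  structure(
    list(family = "gamma", shape_a = (mean / sd)^2, shape_b = sd^2 / mean),
    class = "cea_dist"
  )
}

#' Fit a beta distribution by method of moments
#'
#' Returns the beta shape parameters whose mean and standard deviation
#' equal the supplied values:
#' `alpha = mean * nu`, `beta = (1 - mean) * nu` with
#' `nu = mean(1 - mean)/sd^2 - 1`.  A valid beta requires
#' `sd^2 < mean(1 - mean)`; values at or beyond that bound (within a
#' small tolerance guarding `nu > 0`) are rejected.
#'
#' @param mean distribution mean (a proportion strictly inside (0, 1)).
#' @param sd distribution standard deviation, strictly positive.
#' @return a `cea_dist` object with fields `family`, `shape_a` (alpha)
#'   and `shape_b` (beta).
#' @examples
#' beta_from_mean_sd(0.16, 0.03)
#' @export
beta_from_mean_sd <- function(mean, sd) {
  if (!is.numeric(mean) || !is.numeric(sd) ||
      mean <= 0 || mean >= 1 || sd <= 0) {
    stop("beta_from_mean_sd() requires 0 < mean < 1 and sd > 0",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  if (nu <= 1e-9) {
    stop("beta_from_mean_sd(): sd^2 must be strictly below mean*(1-mean)",
         call. = FALSE)
  }
  structure(
    list(family = "beta", shape_a = mean * nu, shape_b = (1 - mean) * nu),
    class = "cea_dist"
  )
}

#' Analytic mean and SD of a fitted distribution
#'
#' @param dist a `cea_dist` from [gamma_from_mean_sd()] or
#'   [beta_from_mean_sd()].
#' @return list with `mean` and `sd`.
#' @export
dist_moments <- function(dist) {
  stopifnot(inherits(dist, "cea_dist"))
  if (dist$family == "gamma") {
    list(mean = dist$shape_a * dist$shape_b,
         sd = sqrt(dist$shape_a) * dist$shape_b)
  } else {
    a <- dist$shape_a
    b <- dist$shape_b
    list(mean = a / (a + b),
         sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
  }
}

#' Distribution parameters for every non-fixed model parameter
#'
#' Fits, by method of moments, the sampling distribution of each row of
#' a parameter table: gamma for costs, beta for proportions; rows with
#' `distribution = "fixed"` map to `NULL`.
#'
#' @param params a `cea_parameters` tibble.
#' @return named list of `cea_dist` objects (or `NULL` for fixed rows).
#' @export
dist_params <- function(params) {
  out <- lapply(seq_len(nrow(params)), function(i) {
    row <- params[i, ]
    switch(row$distribution,
      fixed = NULL,
      gamma = gamma_from_mean_sd(row$base, row$sd),
      beta  = beta_from_mean_sd(row$base, row$sd)
    )
  })
  setNames(out, params$name)
}

#' Base-value assignment from a parameter table
#'
#' @param params a `cea_parameters` tibble.
#' @return named list mapping each parameter name to its base value.
#' @export
base_assignment <- function(params) {
  as.list(setNames(params$base, params$name))
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Model parameter table:", nrow(x), "parameters (",
      sum(x$role == "cost"), "costs,",
      sum(x$role == "probability"), "probabilities )\n")
  NextMethod()
}
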