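#' Pipeline run configuration
#'
#' Resolves the inputs shared by the pipeline entry points: a parameter
#' table and a unit-cost table (paths or in-memory tables; packaged
#' defaults when `NULL`), the effect definition, the PSA configuration,
#' and an optional output directory into which the entry points write
#' their CSV/JSON artefacts.
#'
#' @param parameters path to a parameter table, a `cea_parameters`
#'   tibble, or `NULL` for the packaged defaults.
#' @param unit_costs path, `cea_unit_costs` tibble, or `NULL`.
#' @param effect_definition passed to [build_model()].
#' @param psa a [psa_config()].
#' @param out_dir output directory (created if needed), or `NULL` to
#'   return results without writing files.
#' @param verbose print progress messages.
#' @return a `cea_run_config` list with resolved tables.
#' @export
run_config <- function(parameters = NULL, unit_costs = NULL,
                       effect_definition = c("true_positive",
                                             "any_severe_diagnosis"),
                       psa = psa_config(), out_dir = NULL,
                       verbose = FALSE) {
  effect_definition <- match.arg(effect_definition)
  parameters_path <- NA_character_
  if (is.null(parameters)) {
    params <- default_parameters()
    parameters_path <- system.file("extdata", "model_parameters.csv",
                                   package = "oxicea")
  } else if (is.character(parameters)) {
    parameters_path <- parameters
    params <- load_parameters(parameters)
  } else {
    params <- validate_parameters(parameters)
  }
  uc <- if (is.null(unit_costs)) {
    default_unit_costs()
  } else if (is.character(unit_costs)) {
    load_unit_costs(unit_costs)
  } else {
    unit_costs
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  structure(
    list(parameters = params, parameters_path = parameters_path,
         unit_costs = uc, effect_definition = effect_definition,
         psa = psa, out_dir = out_dir, verbose = verbose),
    class = "cea_run_config"
  )
}

write_run_log <- function(config, command, seed = NA) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  checksum <- if (!is.na(config$parameters_path) &&
                  file.exists(config$parameters_path)) {
    unname(tools::md5sum(config$parameters_path))
  } else {
    NA_character_
  }
  line <- sprintf(
    "command=%s seed=%s parameter_table_md5=%s oxicea_version=%s",
    command, as.character(seed), checksum,
    as.character(utils::packageVersion("oxicea"))
  )
  cat(line, "\n", file = file.path(config$out_dir, "run.log"),
      append = TRUE, sep = "")
  if (isTRUE(config$verbose)) message(line)
  invisible(line)
}

#' Base-case analysis
#'
#' Builds the decision tree, rolls it back at the base parameter
#' values, and computes the incremental result of the combined strategy
#' over IMCI alone.  With an output directory configured, writes
#' `basecase.json` and `basecase.csv`.
#'
#' @param config a [run_config()].
#' @return a `cea_basecase` list: `strategies` (rollback tibble),
#'   `incremental`, `effect_definition`.
#' @examples
#' cea_basecase(run_config())
#' @export
cea_basecase <- function(config = run_config()) {
  stopifnot(inherits(config, "cea_run_config"))
  model <- build_model(config$parameters, config$effect_definition)
  outcomes <- rollback(model, base_assignment(config$parameters))
  inc <- incremental(outcomes)
  result <- structure(
    list(strategies = outcomes, incremental = inc,
         effect_definition = config$effect_definition),
    class = "cea_basecase"
  )
  if (!is.null(config$out_dir)) {
    utils::write.csv(as.data.frame(outcomes),
                     file.path(config$out_dir, "basecase.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(effect_definition = config$effect_definition,
           strategies = outcomes,
           incremental = unclass(inc)),
      file.path(config$out_dir, "basecase.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_run_log(config, "basecase")
  }
  result
}

#' @export
print.cea_basecase <- function(x, ...) {
  cat("Base-case analysis (effect definition:", x$effect_definition, ")\n")
  for (i in seq_len(nrow(x$strategies))) {
    cat(sprintf("  %-13s expected cost %7.4f USD, expected effect %6.4f\n",
                x$strategies$strategy[i], x$strategies$cost[i],
                x$strategies$effect[i]))
  }
  print(x$incremental)
  invisible(x)
}

#' Tornado analysis entry point
#'
#' @param config a [run_config()].
#' @return the [tornado()] tibble; written to `tornado.csv` when an
#'   output directory is configured.
#' @export
cea_tornado <- function(config = run_config()) {
  stopifnot(inherits(config, "cea_run_config"))
  model <- build_model(config$parameters, config$effect_definition)
  entries <- tornado(model, config$parameters)
  if (!is.null(config$out_dir)) {
    write_tornado(entries, file.path(config$out_dir, "tornado.csv"))
    write_run_log(config, "tornado")
  }
  entries
}

#' PSA entry point
#'
#' Runs the full probabilistic sensitivity analysis and derives the
#' CEAC, crossover WTP and draw summaries.  With an output directory,
#' writes `psa_samples.csv`, `ceac.csv` and `psa_summary.json`.
#'
#' @param config a [run_config()] whose `psa` carries a seed.
#' @return list: `draws`, `ceac`, `crossover`, `summary`.
#' @export
cea_psa <- function(config = run_config()) {
  stopifnot(inherits(config, "cea_run_config"))
  model <- build_model(config$parameters, config$effect_definition)
  draws <- run_psa(model, config$parameters, config$psa)
  curve <- ceac(draws, config$psa$wtp_grid)
  cross <- crossover_wtp(curve)
  summ <- psa_summary(draws)
  if (!is.null(config$out_dir)) {
    utils::write.csv(as.data.frame(draws),
                     file.path(config$out_dir, "psa_samples.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(curve),
                     file.path(config$out_dir, "ceac.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(crossover = cross, summary = summ),
      file.path(config$out_dir, "psa_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_run_log(config, "psa", seed = config$psa$seed)
  }
  list(draws = draws, ceac = curve, crossover = cross, summary = summ)
}

#' Simulate a synthetic trial and run the costing pipeline on it
#'
#' Generates a patient-level cohort, accumulates its cost ledgers,
#' recovers the trial estimators, and rebuilds a parameter table fit
#' for [cea_basecase()] — the full costing-to-model chain with no
#' external data.
#'
#' @param config a [run_config()].
#' @param synth a [synth_config()].
#' @return list: `records`, `ledgers`, `recovered`, `parameters`.
#' @export
cea_simulate <- function(config = run_config(), synth = synth_config()) {
  stopifnot(inherits(config, "cea_run_config"))
  records <- generate_trial(synth)
  ledgers <- patient_level_totals(records, config$unit_costs)
  recovered <- recover_parameters(records, config$unit_costs)
  params <- parameters_from_trial(recovered, template = config$parameters)
  if (!is.null(config$out_dir)) {
    write_trial(records, file.path(config$out_dir, "records.csv"))
    write_parameters(params,
                     file.path(config$out_dir, "recovered_parameters.csv"))
    write_run_log(config, "simulate", seed = synth$seed)
  }
  list(records = records, ledgers = ledgers, recovered = recovered,
       parameters = params)
}

format_usd <- function(x) sprintf("%.2f", x)

#' Display a trial proportion as a percentage
#'
#' Trial effect proportions are reported to the nearest whole
#' percentage point and displayed with one decimal place, the
#' convention of the source cost tables (148/928 displays as `16.0%`,
#' 34/876 as `4.0%`).
#'
#' @param p proportion in \[0, 1\].
#' @return character percentage label.
#' @examples
#' format_percent(148 / 928)
#' @export
format_percent <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0), all(p <= 1))
  sprintf("%.1f%%", round(100 * p))
}

#' Cost-summary tables for a ledger set
#'
#' Renders the two standard cost tables of a trial-based costing: the
#' per-class totals and averages per diagnosed case, and the itemized
#' severe-case costs with integer-percent shares.  USD values are
#' displayed at 2 decimals; arithmetic underneath is full precision, so
#' reruns on the same ledgers are byte-identical.
#'
#' @param ledgers a `cea_ledger_set` (e.g. from
#'   [patient_level_totals()] or [default_itemized_ledgers()]).
#' @return a `cea_report` list: `class_costs` tibble (per arm/class:
#'   `n_diagnosed`, `total_usd`, `average_usd` — `NA` with a
#'   `"no cases"` note when a class is empty) and `itemized` tibble
#'   (severe ledger items with `share_pct`).
#' @export
cea_report <- function(ledgers) {
  stopifnot(inherits(ledgers, "cea_ledger_set"))
  class_rows <- lapply(ledgers, function(ledger) {
    total <- sum(ledger$entries)
    tibble::tibble(
      arm = ledger$arm,
      diagnosis_class = ledger$diagnosis_class,
      n_diagnosed = ledger$n_cases,
      total_usd = total,
      average_usd = if (ledger$n_cases > 0) {
        as.numeric(format_usd(average_cost(total, ledger$n_cases)))
      } else {
        NA_real_
      },
      note = if (ledger$n_cases > 0) "" else "no cases"
    )
  })
  itemized_rows <- lapply(ledgers, function(ledger) {
    if (ledger$diagnosis_class != "severe" || length(ledger$entries) == 0 ||
        sum(ledger$entries) == 0) {
      return(NULL)
    }
    tab <- itemize(ledger)
    tab$arm <- ledger$arm
    tab$grand_total <- attr(tab, "grand_total")
    tab[c("arm", "item", "total_usd", "share_pct", "grand_total")]
  })
  structure(
    list(class_costs = do.call(rbind, unname(class_rows)),
         itemized = do.call(rbind, unname(itemized_rows))),
    class = "cea_report"
  )
}

#' @export
print.cea_report <- function(x, ...) {
  cat("Total and average cost per diagnosed case (USD)\n")
  cc <- x$class_costs
  for (i in seq_len(nrow(cc))) {
    if (cc$note[i] == "no cases") {
      cat(sprintf("  %-12s %-10s  no cases\n", cc$arm[i],
                  cc$diagnosis_class[i]))
    } else {
      cat(sprintf("  %-12s %-10s  n=%4d  total %8s  average %6s\n",
                  cc$arm[i], cc$diagnosis_class[i], cc$n_diagnosed[i],
                  format_usd(cc$total_usd[i]), format_usd(cc$average_usd[i])))
    }
  }
  if (!is.null(x$itemized)) {
    cat("Itemized severe-case costs (USD, % share)\n")
    it <- x$itemized
    for (i in seq_len(nrow(it))) {
      cat(sprintf("  %-12s %-18s %8s (%d%%)\n", it$arm[i], it$item[i],
                  format_usd(it$total_usd[i]), it$share_pct[i]))
    }
  }
  invisible(x)
}

#' Render a report deterministically to text
#'
#' @param report a `cea_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  txt <- utils::capture.output(print(report))
  writeLines(txt, path)
  invisible(path)
}
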