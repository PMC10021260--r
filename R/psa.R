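#' Configuration for the probabilistic sensitivity analysis
#'
#' @param iterations Monte Carlo iterations (default 10,000).
#' @param seed integer RNG seed; required before sampling.
#' @param wtp_grid strictly increasing non-negative willingness-to-pay
#'   grid, USD per diagnosed severe case.  The default 0--100 in steps
#'   of 1 brackets every threshold of practical interest here.
#' @param shared_draw_groups list of character vectors; the parameters
#'   in each group share a single draw per iteration.  The default ties
#'   the two specificities together, since the combined strategy's
#'   specificity is assumed equal to that of IMCI alone; pass `list()`
#'   for fully independent draws.
#' @return a `cea_psa_config` list.
#' @export
psa_config <- function(iterations = 10000L, seed = NULL, wtp_grid = 0:100,
                       shared_draw_groups = list(
                         specificity = c("spec_intervention", "spec_control")
                       )) {
  stopifnot(
    is.numeric(iterations), iterations >= 1,
    is.numeric(wtp_grid), all(wtp_grid >= 0),
    all(diff(wtp_grid) > 0)
  )
  structure(
    list(iterations = as.integer(iterations), seed = seed,
         wtp_grid = wtp_grid, shared_draw_groups = shared_draw_groups),
    class = "cea_psa_config"
  )
}

#' Sample parameter values for the PSA
#'
#' Draws `iterations` values for every parameter from its
#' method-of-moments distribution (gamma for costs, beta for
#' proportions; fixed parameters repeat their base value).  Draws are
#' independent across parameters except within shared-draw groups,
#' whose members — validated to have identical distribution parameters
#' — reuse the group's single draw vector.  A single seeded generator
#' is used, consuming parameters in table order, so output is
#' bit-reproducible for a given seed.
#'
#' @param params a `cea_parameters` tibble.
#' @param config a [psa_config()] with a non-`NULL` seed.
#' @return tibble with column `iteration` plus one column per parameter.
#' @export
sample_parameters <- function(params, config) {
  stopifnot(inherits(config, "cea_psa_config"))
  if (is.null(config$seed)) {
    stop("psa_config() needs an explicit seed before sampling",
         call. = FALSE)
  }
  dists <- dist_params(params)  # errors on any invalid distribution
  group_of <- rep(NA_integer_, nrow(params))
  for (g in seq_along(config$shared_draw_groups)) {
    members <- config$shared_draw_groups[[g]]
    missing_members <- setdiff(members, params$name)
    if (length(missing_members) > 0) {
      stop("shared-draw group names unknown parameter(s): ",
           paste(missing_members, collapse = ", "), call. = FALSE)
    }
    idx <- match(members, params$name)
    specs <- params[idx, c("base", "sd", "distribution")]
    if (nrow(unique(specs)) != 1) {
      stop("shared-draw group members must have identical distributions: ",
           paste(members, collapse = ", "), call. = FALSE)
    }
    group_of[idx] <- g
  }
  n <- config$iterations
  set.seed(config$seed)
  draws <- vector("list", nrow(params))
  names(draws) <- params$name
  group_draws <- list()
  for (i in seq_len(nrow(params))) {
    nm <- params$name[i]
    g <- group_of[i]
    if (!is.na(g) && length(group_draws) >= g &&
        !is.null(group_draws[[g]])) {
      draws[[nm]] <- group_draws[[g]]
      next
    }
    d <- dists[[nm]]
    x <- if (is.null(d)) {
      rep(params$base[i], n)
    } else if (d$family == "gamma") {
      rgamma(n, shape = d$shape_a, scale = d$shape_b)
    } else {
      rbeta(n, shape1 = d$shape_a, shape2 = d$shape_b)
    }
    draws[[nm]] <- x
    if (!is.na(g)) group_draws[[g]] <- x
  }
  tibble::as_tibble(c(list(iteration = seq_len(n)), draws))
}

#' Run the probabilistic sensitivity analysis
#'
#' Samples all parameters via [sample_parameters()] and rolls each draw
#' back through the decision tree, yielding the Monte Carlo cloud of
#' per-strategy costs and effects and their increments.
#'
#' @param model a `cea_model`.
#' @param params a `cea_parameters` tibble.
#' @param config a [psa_config()] with a seed.
#' @return a `cea_psa` tibble: `iteration`, one column per parameter,
#'   `cost_intervention`, `effect_intervention`, `cost_control`,
#'   `effect_control`, `delta_cost`, `delta_effect`.
#' @export
run_psa <- function(model, params, config) {
  stopifnot(inherits(model, "cea_model"))
  samples <- sample_parameters(params, config)
  assignment <- as.list(samples[params$name])
  res <- lapply(model$strategies, roll_node, assignment = assignment)
  out <- samples
  out$cost_intervention <- res$intervention$cost
  out$effect_intervention <- res$intervention$effect
  out$cost_control <- res$control$cost
  out$effect_control <- res$control$effect
  out$delta_cost <- out$cost_intervention - out$cost_control
  out$delta_effect <- out$effect_intervention - out$effect_control
  class(out) <- c("cea_psa", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value `lambda`, scores every strategy's
#' net monetary benefit `NMB = lambda * effect - cost` in each draw and
#' reports the fraction of draws in which each strategy has the
#' strictly highest NMB (exact ties split equally).  For two
#' strategies this is equivalent to preferring the intervention in a
#' draw exactly when `lambda * delta_effect - delta_cost > 0`.
#'
#' @param draws a `cea_psa` tibble.
#' @param wtp_grid strictly increasing non-negative WTP values.
#' @return tibble with columns `wtp`, `p_intervention`, `p_control`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (nrow(draws) == 0) stop("ceac() needs at least one draw", call. = FALSE)
  if (length(wtp_grid) == 0) stop("empty WTP grid", call. = FALSE)
  stopifnot(all(wtp_grid >= 0), all(diff(wtp_grid) > 0))
  p_int <- vapply(wtp_grid, function(lambda) {
    inb <- lambda * draws$delta_effect - draws$delta_cost
    mean(inb > 0) + 0.5 * mean(inb == 0)
  }, numeric(1))
  tibble::tibble(wtp = wtp_grid, p_intervention = p_int,
                 p_control = 1 - p_int)
}

#' Willingness-to-pay at which the CEAC rank order swaps
#'
#' Finds the smallest grid WTP at which the intervention's probability
#' of highest net monetary benefit is at least the comparator's
#' (i.e. reaches 0.5 for two strategies), together with the linear
#' interpolation of the crossing between the bracketing grid points.
#'
#' @param ceac_points output of [ceac()].
#' @return list: `wtp` (grid value of the swap, `NA` if none on the
#'   grid), `wtp_interpolated` (`NA` at the grid edge or if absent),
#'   `status` (`"crossed"` or `"out_of_range"`).
#' @export
crossover_wtp <- function(ceac_points) {
  d <- ceac_points$p_intervention - ceac_points$p_control
  idx <- which(d >= 0)
  if (length(idx) == 0) {
    return(list(wtp = NA_real_, wtp_interpolated = NA_real_,
                status = "out_of_range"))
  }
  i <- idx[1]
  interp <- if (i == 1) {
    NA_real_
  } else {
    w0 <- ceac_points$wtp[i - 1]
    w1 <- ceac_points$wtp[i]
    d0 <- d[i - 1]
    d1 <- d[i]
    if (d1 == d0) w1 else w0 + (0 - d0) / (d1 - d0) * (w1 - w0)
  }
  list(wtp = ceac_points$wtp[i], wtp_interpolated = interp,
       status = "crossed")
}

#' Summarize a PSA draw table
#'
#' Reports means and percentiles of the incremental cost and effect,
#' and ratio statistics of the per-draw ICER over draws with a
#' non-zero effect difference; draws with `delta_effect == 0` are
#' excluded from the ratio and counted.
#'
#' @param draws a `cea_psa` tibble.
#' @param probs percentiles to report.
#' @return list: `n`, `n_zero_delta_effect`, `delta_cost` and
#'   `delta_effect` summaries (mean + percentiles), and `icer` stats
#'   (`min`, `max`, `mean`, `median`, percentiles).
#' @export
psa_summary <- function(draws, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  if (nrow(draws) == 0) stop("empty draw table", call. = FALSE)
  summarize_vec <- function(x) {
    c(mean = mean(x), quantile(x, probs = probs))
  }
  nonzero <- draws$delta_effect != 0
  ratios <- draws$delta_cost[nonzero] / draws$delta_effect[nonzero]
  icer_stats <- if (length(ratios) > 0) {
    c(min = min(ratios), max = max(ratios), mean = mean(ratios),
      median = stats::median(ratios), quantile(ratios, probs = probs))
  } else {
    NULL
  }
  list(
    n = nrow(draws),
    n_zero_delta_effect = sum(!nonzero),
    delta_cost = summarize_vec(draws$delta_cost),
    delta_effect = summarize_vec(draws$delta_effect),
    icer = icer_stats
  )
}
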