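#' Default item-quantity means for the synthetic trial
#'
#' Mean per-child quantities of each costed item, by arm and diagnosis
#' class, calibrated so that the expected per-case itemized costs of a
#' generated cohort reproduce the study-level class averages: the
#' variable (non-fixed) severe-case means are the per-case shares of
#' the itemized severe-cost ledgers ([default_itemized_ledgers()])
#' divided by their unit costs, and the non-severe means are an assumed
#' mix (one consultation, one drug dose, the remainder as transport)
#' whose expected cost equals the class averages of 3.58 USD
#' (intervention) and 2.14 USD (control).  Oxygen and hospital days are
#' severe-only items and have mean 0 for non-severe children.
#'
#' @return nested list `[[arm]][[class]]` of named quantity means.
#' @export
default_item_means <- function() {
  uc <- default_unit_costs()
  usd <- setNames(uc$usd, uc$item)
  severe_means <- function(oxygen, hospital, transport, drugs_supplies,
                           fluids, cannulae, n_cases) {
    per_case <- function(total) total / n_cases
    ds <- per_case(drugs_supplies)
    list(
      consultations = 1,
      km_travelled = per_case(transport) / usd[["transport"]],
      hospital_days = per_case(hospital) / usd[["hospital_stay"]],
      oxygen_m3 = per_case(oxygen) / usd[["oxygen"]],
      iv_fluids = fluids,
      iv_cannulae = cannulae,
      drug_doses = (ds - fluids * usd[["iv_fluids"]] -
                      cannulae * usd[["iv_cannula"]]) / usd[["drugs"]]
    )
  }
  nonsevere_means <- function(avg_cost) {
    list(
      consultations = 1,
      km_travelled = (avg_cost - usd[["consultation"]] - usd[["drugs"]]) /
        usd[["transport"]],
      hospital_days = 0,
      oxygen_m3 = 0,
      iv_fluids = 0,
      iv_cannulae = 0,
      drug_doses = 1
    )
  }
  list(
    intervention = list(
      severe = severe_means(oxygen = 743, hospital = 873, transport = 559,
                            drugs_supplies = 1221, fluids = 2, cannulae = 2,
                            n_cases = 148),
      non_severe = nonsevere_means(3.58)
    ),
    control = list(
      severe = severe_means(oxygen = 171, hospital = 89, transport = 139,
                            drugs_supplies = 181, fluids = 1.5,
                            cannulae = 1.5, n_cases = 34),
      non_severe = nonsevere_means(2.14)
    )
  )
}

#' Configuration for the synthetic cluster-randomized trial
#'
#' Defaults emulate the study conditions the costing analysis assumes:
#' 24 health-centre clusters randomized 12:12, around 1,804 children in
#' total (negative-binomial cluster sizes with mean 1804/24), and
#' arm-specific probabilities of a severe-pneumonia diagnosis of
#' 148/928 (intervention) and 34/876 (control).  Item quantities are
#' drawn from right-skewed non-negative distributions (gamma for
#' continuous quantities, Poisson for counts) with means from
#' [default_item_means()].
#'
#' @param seed integer RNG seed.
#' @param n_clusters total clusters, split equally between arms (even).
#' @param cluster_size_mean mean children per cluster.
#' @param cluster_size_dispersion negative-binomial size parameter for
#'   cluster-size overdispersion.
#' @param p_severe named vector of severe-diagnosis probabilities per
#'   arm.
#' @param item_means nested list as from [default_item_means()].
#' @param cluster_sd standard deviation (log scale) of an optional
#'   lognormal cluster random effect multiplying quantity means;
#'   0 (default) disables within-cluster cost correlation.
#' @param deterministic_quantities if `TRUE`, every child receives the
#'   class mean quantities exactly (point masses) instead of random
#'   draws; diagnosis assignment stays random.
#' @return a `cea_synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_clusters = 24L,
                         cluster_size_mean = 1804 / 24,
                         cluster_size_dispersion = 8,
                         p_severe = c(intervention = 148 / 928,
                                      control = 34 / 876),
                         item_means = default_item_means(),
                         cluster_sd = 0,
                         deterministic_quantities = FALSE) {
  stopifnot(
    n_clusters >= 2, n_clusters %% 2 == 0,
    cluster_size_mean > 0, cluster_size_dispersion > 0,
    all(p_severe >= 0), all(p_severe <= 1),
    all(c("intervention", "control") %in% names(p_severe)),
    cluster_sd >= 0
  )
  for (arm in c("intervention", "control")) {
    for (cls in c("severe", "non_severe")) {
      means <- unlist(item_means[[arm]][[cls]])
      if (any(!is.finite(means)) || any(means < 0)) {
        stop("item-quantity means must be finite and non-negative (",
             arm, "/", cls, ")", call. = FALSE)
      }
    }
  }
  structure(
    list(seed = as.integer(seed), n_clusters = as.integer(n_clusters),
         cluster_size_mean = cluster_size_mean,
         cluster_size_dispersion = cluster_size_dispersion,
         p_severe = p_severe, item_means = item_means,
         cluster_sd = cluster_sd,
         deterministic_quantities = deterministic_quantities),
    class = "cea_synth_config"
  )
}

# continuous items use gamma draws (shape 2); count items use Poisson
CONTINUOUS_ITEMS <- c("km_travelled", "oxygen_m3")
COUNT_ITEMS <- c("hospital_days", "drug_doses", "iv_fluids", "iv_cannulae")
SEVERE_ONLY_ITEMS <- c("oxygen_m3", "hospital_days")

#' Generate a synthetic trial cohort
#'
#' Draws one patient-level record per child: cluster, arm, diagnosis
#' class (Bernoulli with the arm's severe probability), and item
#' quantities conditioned on the class.  Severe-only items (oxygen,
#' hospital days) are identically zero for non-severe children.
#' Output is bit-reproducible for a given config seed.
#'
#' @param config a [synth_config()].
#' @return a `cea_trial` tibble: `cluster_id`, `arm`, `child_id`,
#'   `diagnosis`, `consultations`, `km_travelled`, `hospital_days`,
#'   `oxygen_m3`, `drug_doses`, `iv_fluids`, `iv_cannulae`.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "cea_synth_config"))
  set.seed(config$seed)
  n_per_arm <- config$n_clusters / 2
  arms <- rep(c("intervention", "control"), each = n_per_arm)
  sizes <- pmax(1L, rnbinom(config$n_clusters,
                            mu = config$cluster_size_mean,
                            size = config$cluster_size_dispersion))
  cluster_effect <- if (config$cluster_sd > 0) {
    exp(stats::rnorm(config$n_clusters, mean = -config$cluster_sd^2 / 2,
                     sd = config$cluster_sd))
  } else {
    rep(1, config$n_clusters)
  }
  records <- vector("list", config$n_clusters)
  for (k in seq_len(config$n_clusters)) {
    n <- sizes[k]
    arm <- arms[k]
    severe <- rbinom(n, 1, config$p_severe[[arm]]) == 1
    diagnosis <- ifelse(severe, "severe", "non_severe")
    qty <- lapply(names(QUANTITY_ITEMS), function(item) numeric(n))
    names(qty) <- names(QUANTITY_ITEMS)
    for (cls in c("severe", "non_severe")) {
      sel <- diagnosis == cls
      m <- sum(sel)
      if (m == 0) next
      means <- config$item_means[[arm]][[cls]]
      for (item in names(QUANTITY_ITEMS)) {
        mu <- means[[item]] * cluster_effect[k]
        qty[[item]][sel] <- if (mu == 0) {
          0
        } else if (config$deterministic_quantities ||
                   item == "consultations") {
          mu
        } else if (item %in% CONTINUOUS_ITEMS) {
          rgamma(m, shape = 2, scale = mu / 2)
        } else {
          rpois(m, lambda = mu)
        }
      }
    }
    records[[k]] <- tibble::tibble(
      cluster_id = k, arm = arm, child_id = seq_len(n),
      diagnosis = diagnosis,
      consultations = qty$consultations,
      km_travelled = qty$km_travelled,
      hospital_days = qty$hospital_days,
      oxygen_m3 = qty$oxygen_m3,
      drug_doses = qty$drug_doses,
      iv_fluids = qty$iv_fluids,
      iv_cannulae = qty$iv_cannulae
    )
  }
  out <- do.call(rbind, records)
  class(out) <- c("cea_trial", class(out))
  out
}

#' Recover model parameters from a trial cohort
#'
#' Applies the trial's estimators to patient-level records: the
#' proportion diagnosed severe per arm (with its binomial standard
#' error) and the average cost per diagnosed case per arm and class via
#' the costing module.  The variable (per-child) cost average is
#' reported separately from the total average, which additionally
#' spreads the arm's fixed provider costs over its realized severe case
#' count.  Classes with no diagnosed case are flagged and excluded from
#' averages.
#'
#' @param records a `cea_trial` tibble.
#' @param unit_costs a `cea_unit_costs` tibble.
#' @param fixed_costs per-arm fixed-cost tibble, or `NULL`.
#' @return tibble with columns `name`, `role`, `arm`, `diagnosis_class`,
#'   `estimate`, `se`, `variable_estimate`, `n`.
#' @export
recover_parameters <- function(records, unit_costs = default_unit_costs(),
                               fixed_costs = default_fixed_costs()) {
  rows <- list()
  for (arm in c("intervention", "control")) {
    sub <- records[records$arm == arm, , drop = FALSE]
    n <- nrow(sub)
    n_severe <- sum(sub$diagnosis == "severe")
    p <- n_severe / n
    rows[[length(rows) + 1]] <- tibble::tibble(
      name = paste0("p_severe_", arm), role = "probability", arm = arm,
      diagnosis_class = NA_character_, estimate = p,
      se = sqrt(p * (1 - p) / n), variable_estimate = p, n = n
    )
  }
  ledgers <- patient_level_totals(records, unit_costs, fixed_costs)
  per_child_cost <- function(sub, arm) {
    cost <- numeric(nrow(sub))
    for (col in names(QUANTITY_ITEMS)) {
      cost <- cost + sub[[col]] *
        resolve_unit_cost(QUANTITY_ITEMS[[col]], arm, unit_costs)
    }
    cost
  }
  for (arm in c("intervention", "control")) {
    for (cls in c("severe", "non_severe")) {
      sub <- records[records$arm == arm &
                       records$diagnosis ==
                       (if (cls == "severe") "severe" else "non_severe"), ,
                     drop = FALSE]
      nm <- paste0("cost_", if (cls == "severe") "severe" else "nonsevere",
                   "_", arm)
      n_cls <- nrow(sub)
      if (n_cls == 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          name = nm, role = "cost", arm = arm, diagnosis_class = cls,
          estimate = NA_real_, se = NA_real_,
          variable_estimate = NA_real_, n = 0L
        )
        next
      }
      ledger <- ledgers[[paste(arm, cls, sep = "_")]]
      costs <- per_child_cost(sub, arm)
      rows[[length(rows) + 1]] <- tibble::tibble(
        name = nm, role = "cost", arm = arm, diagnosis_class = cls,
        estimate = average_cost(sum(ledger$entries), ledger$n_cases),
        se = if (n_cls > 1) sd(costs) / sqrt(n_cls) else NA_real_,
        variable_estimate = mean(costs), n = n_cls
      )
    }
  }
  do.call(rbind, rows)
}

#' Parameter table from recovered trial estimates
#'
#' Rebuilds a full model parameter table by substituting the recovered
#' proportions and average costs into a template table (packaged
#' defaults by default), keeping the template's sensitivity and
#' specificity rows: those are external literature inputs the trial
#' itself does not estimate.  Recovered SDs replace the template SDs
#' and min/max are refreshed as estimate +/- 1.96 SE (clipped to the
#' parameter's domain).
#'
#' @param recovered output of [recover_parameters()].
#' @param template a `cea_parameters` tibble to update.
#' @return a validated `cea_parameters` tibble.
#' @export
parameters_from_trial <- function(recovered,
                                  template = default_parameters()) {
  df <- as.data.frame(template)
  for (i in seq_len(nrow(recovered))) {
    est <- recovered[i, ]
    j <- match(est$name, df$name)
    if (is.na(j) || is.na(est$estimate)) next
    se <- if (is.na(est$se)) 0 else est$se
    lo <- est$estimate - 1.96 * se
    hi <- est$estimate + 1.96 * se
    if (df$role[j] == "probability") {
      lo <- max(0, lo)
      hi <- min(1, hi)
    } else {
      lo <- max(0, lo)
    }
    df$base[j] <- est$estimate
    df$min[j] <- lo
    df$max[j] <- hi
    if (se > 0) {
      df$sd[j] <- se
    } else {
      df$sd[j] <- 0
      df$distribution[j] <- "fixed"
    }
    df$source[j] <- "Synthetic trial estimate"
  }
  validate_parameters(df)
}

#' Write a trial cohort to CSV
#'
#' @param records a `cea_trial` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
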