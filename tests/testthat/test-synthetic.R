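test_that("the generator is reproducible and structurally correct", {
  cfg <- synth_config(seed = 4)
  r1 <- generate_trial(cfg)
  r2 <- generate_trial(cfg)
  expect_identical(r1, r2)
  expect_equal(length(unique(r1$cluster_id)), 24)
  expect_setequal(unique(r1$arm), c("intervention", "control"))
  # 12 clusters per arm, exactly balanced
  arm_by_cluster <- unique(r1[c("cluster_id", "arm")])
  expect_equal(unname(table(arm_by_cluster$arm)["intervention"]), 12L)
  qty <- c("consultations", "km_travelled", "hospital_days", "oxygen_m3",
           "drug_doses", "iv_fluids", "iv_cannulae")
  for (col in qty) expect_true(all(r1[[col]] >= 0))
})

test_that("severe-only items are zero for every non-severe record", {
  for (s in c(1, 2, 3)) {
    r <- generate_trial(synth_config(seed = s))
    non <- r[r$diagnosis == "non_severe", ]
    expect_true(all(non$oxygen_m3 == 0))
    expect_true(all(non$hospital_days == 0))
  }
})

test_that("the severe fraction sits within 3 binomial SEs of its target", {
  r <- generate_trial(synth_config(seed = 8))
  for (arm in c("intervention", "control")) {
    sub <- r[r$arm == arm, ]
    p0 <- synth_config()$p_severe[[arm]]
    p_hat <- mean(sub$diagnosis == "severe")
    se <- sqrt(p0 * (1 - p0) / nrow(sub))
    expect_lt(abs(p_hat - p0), 3 * se)
  }
})

test_that("zero severe probability gives empty severe ledgers", {
  cfg <- synth_config(seed = 5, p_severe = c(intervention = 0, control = 0))
  r <- generate_trial(cfg)
  expect_equal(sum(r$diagnosis == "severe"), 0)
  ledgers <- patient_level_totals(r)
  expect_equal(sum(ledgers$intervention_severe$entries), 0)
  expect_equal(ledgers$intervention_severe$n_cases, 0)
  expect_equal(sum(ledgers$control_severe$entries), 0)
  expect_equal(ledgers$control_severe$n_cases, 0)
})

test_that("point-mass quantities recover the calibrated means exactly", {
  cfg <- synth_config(seed = 12, deterministic_quantities = TRUE)
  r <- generate_trial(cfg)
  rec <- recover_parameters(r)
  uc <- default_unit_costs()
  usd_of <- function(item, arm) {
    hit <- match(item, uc$item)
    if (is.na(hit)) hit <- match(paste(item, arm, sep = "_"), uc$item)
    uc$usd[hit]
  }
  expected_cost <- function(arm, cls) {
    means <- cfg$item_means[[arm]][[cls]]
    means$consultations * usd_of("consultation", arm) +
      means$km_travelled * usd_of("transport", arm) +
      means$hospital_days * usd_of("hospital_stay", arm) +
      means$oxygen_m3 * usd_of("oxygen", arm) +
      means$drug_doses * usd_of("drugs", arm) +
      means$iv_fluids * usd_of("iv_fluids", arm) +
      means$iv_cannulae * usd_of("iv_cannula", arm)
  }
  for (arm in c("intervention", "control")) {
    for (cls in c("severe", "non_severe")) {
      nm <- paste0("cost_", if (cls == "severe") "severe" else "nonsevere",
                   "_", arm)
      got <- rec$variable_estimate[rec$name == nm]
      expect_equal(got, expected_cost(arm, cls), tolerance = 1e-9)
    }
  }
  # calibration check: expected per-case class costs match the study's
  # class averages (the non-severe mixes are calibrated to them)
  expect_equal(expected_cost("intervention", "non_severe"), 3.58,
               tolerance = 1e-9)
  expect_equal(expected_cost("control", "non_severe"), 2.14,
               tolerance = 1e-9)
})

test_that("parameter recovery succeeds within 3 SEs across 100 seeds", {
  cfg0 <- synth_config()
  uc <- default_unit_costs()
  usd <- setNames(uc$usd, uc$item)
  target_variable <- function(arm, cls) {
    m <- cfg0$item_means[[arm]][[cls]]
    m$consultations * usd[["consultation"]] +
      m$km_travelled * usd[["transport"]] +
      m$hospital_days * usd[["hospital_stay"]] +
      m$oxygen_m3 * usd[["oxygen"]] +
      m$drug_doses * usd[["drugs"]] +
      m$iv_fluids * usd[["iv_fluids"]] +
      m$iv_cannulae * usd[["iv_cannula"]]
  }
  ok <- logical(100)
  for (s in seq_len(100)) {
    r <- generate_trial(synth_config(seed = s))
    rec <- recover_parameters(r)
    pass <- TRUE
    for (arm in c("intervention", "control")) {
      row <- rec[rec$name == paste0("p_severe_", arm), ]
      p0 <- cfg0$p_severe[[arm]]
      se <- sqrt(p0 * (1 - p0) / row$n)
      pass <- pass && abs(row$estimate - p0) < 3 * se
      for (cls in c("severe", "non_severe")) {
        nm <- paste0("cost_", if (cls == "severe") "severe" else "nonsevere",
                     "_", arm)
        row <- rec[rec$name == nm, ]
        if (is.na(row$estimate) || is.na(row$se)) {
          pass <- FALSE
          next
        }
        pass <- pass &&
          abs(row$variable_estimate - target_variable(arm, cls)) <
            3 * row$se
      }
    }
    ok[s] <- pass
  }
  expect_gte(sum(ok), 95)
})

test_that("generated cohort size scales linearly with cluster-size mean", {
  sizes <- c(40, 75, 150)
  n_seeds <- 10
  disp <- synth_config()$cluster_size_dispersion
  for (mu in sizes) {
    n_bar <- mean(vapply(seq_len(n_seeds), function(s) {
      nrow(generate_trial(synth_config(seed = 100 + s,
                                       cluster_size_mean = mu)))
    }, numeric(1)))
    # negative-binomial cluster sizes: var = mu + mu^2/dispersion
    se <- sqrt(24 * (mu + mu^2 / disp) / n_seeds)
    expect_lt(abs(n_bar - 24 * mu), 3 * se)
  }
})

test_that("an optional cluster random effect preserves the invariants", {
  r <- generate_trial(synth_config(seed = 6, cluster_sd = 0.3))
  expect_true(all(r$oxygen_m3[r$diagnosis == "non_severe"] == 0))
  expect_true(all(r$km_travelled >= 0))
  ledgers <- patient_level_totals(r)
  expect_s3_class(ledgers, "cea_ledger_set")
})

test_that("recovered estimates feed the model end to end", {
  sim <- cea_simulate(run_config(), synth_config(seed = 3))
  expect_s3_class(sim$parameters, "cea_parameters")
  bc <- cea_basecase(run_config(parameters = sim$parameters))
  expect_true(is.finite(bc$incremental$delta_cost))
  expect_true(bc$incremental$status %in%
                c("icer", "dominant", "dominated", "equal_effect"))
})

test_that("invalid generator configurations fail before sampling", {
  expect_error(synth_config(p_severe = c(intervention = 1.2, control = 0)))
  expect_error(synth_config(n_clusters = 3))
  bad_means <- default_item_means()
  bad_means$intervention$severe$km_travelled <- -5
  expect_error(synth_config(item_means = bad_means), "non-negative")
})
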