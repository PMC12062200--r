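test_that("sensitivity classification follows the three-level scale", {
  expect_identical(classify_sensitivity(0), "not sensitive")
  expect_identical(classify_sensitivity(4.99), "not sensitive")
  expect_identical(classify_sensitivity(5), "sensitive")
  expect_identical(classify_sensitivity(7), "sensitive")
  expect_identical(classify_sensitivity(14.99), "sensitive")
  expect_identical(classify_sensitivity(15), "very sensitive")
  expect_identical(classify_sensitivity(24.99), "very sensitive")
  expect_identical(classify_sensitivity(25), "highly sensitive")  # inclusive
  expect_identical(classify_sensitivity(95), "highly sensitive")
  expect_error(classify_sensitivity(-1), "nonnegative")
})

test_that("the scenario grid deduplicates configurations and rejects duplicate labels", {
  expect_error(
    run_scenario_grid(default_cfg(),
                      list(scenario_spec("a"), scenario_spec("a"))),
    "duplicate")
  grid <- run_scenario_grid(default_cfg())
  # 13 specs; the 75:25 share runs coincide with the schedule-only runs
  expect_identical(length(grid$trajectories), 11L)
  expect_identical(unname(grid$aliases[["share_75_25_on_time"]]),
                   "p4p_on_time")
  expect_identical(unname(grid$aliases[["share_75_25_delayed"]]),
                   "p4p_delayed")
  # determinism: rerunning a scenario reproduces it exactly
  again <- run_p4p(control_cfg())
  expect_identical(unclass(grid$trajectories[["control"]]),
                   unclass(again))
})

test_that("scenario orderings hold under the default calibration", {
  grid <- run_scenario_grid(default_cfg())
  s <- grid$summary
  g <- function(lab, col) s[[col]][s$scenario == lab]
  # P4P on does not fall below the control for either outcome
  expect_gte(g("p4p_on_time", "mean_ipt2"), g("control", "mean_ipt2"))
  expect_gte(g("p4p_on_time", "mean_fbd"), g("control", "mean_fbd"))
  # on-time payments do not fall below delayed payments
  expect_gte(g("p4p_on_time", "mean_ipt2"), g("p4p_delayed", "mean_ipt2"))
  expect_gte(g("p4p_on_time", "mean_fbd"), g("p4p_delayed", "mean_fbd"))
})

test_that("perturbing a parameter with no causal path leaves outcomes unchanged", {
  sens <- sensitivity_analysis(
    default_cfg(), parameters = "population.mortality.older_adults")
  expect_true(all(sens$change_pct == 0))
  expect_true(all(sens$classification == "not sensitive"))
})

test_that("reduced Medical Stores fulfilment elicits at least a sensitive IPT2 response", {
  sens <- sensitivity_analysis(default_cfg(),
                               parameters = "commodities.msd_fulfilment")
  down_ipt2 <- sens[sens$direction == "-10%" & sens$outcome == "ipt2_pct", ]
  expect_gte(down_ipt2$change_pct, 5)
  expect_true(down_ipt2$classification != "not sensitive")
})

test_that("awareness and distance reductions produce a transient IPT2 response", {
  base <- p4p_outcomes(run_p4p(default_cfg()))
  for (par in c("facility.awareness_init", "demand.distance_index")) {
    value <- config_get(default_cfg(), par)
    pert <- p4p_outcomes(run_p4p(config_set(default_cfg(), par,
                                            0.9 * value)))
    diff_early <- abs(pert$ipt2_pct - base$ipt2_pct)[1:24]
    expect_gt(max(diff_early), 0) # knock-on onto the IPT pathway exists
  }
})

test_that("perturbing a switch parameter is an error", {
  expect_error(sensitivity_analysis(default_cfg(),
                                    parameters = "p4p.enabled"),
               "switch|numeric")
})

test_that("the extreme-condition suite passes on the shipped model", {
  suite <- extreme_condition_suite(default_cfg())
  expect_true(all(suite$pass))
  expect_identical(nrow(suite), 2L)
})

test_that("the sensitivity metric options are all computed on the same runs", {
  for (metric in c("max", "mean", "endpoint")) {
    sens <- sensitivity_analysis(default_cfg(),
                                 parameters = "demand.distance_index",
                                 metric = metric)
    expect_identical(nrow(sens), 4L) # 2 directions x 2 outcomes
    expect_true(all(sens$change_pct >= 0))
  }
})
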