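test_that("provider readiness is the min of availability and the four-way mean", {
  expect_equal(provider_readiness_ipt(1, 1, 1, 1), 1)
  expect_equal(provider_readiness_ipt(0.8, 0.6, 0.4, 0.6), 0.4)
  expect_equal(provider_readiness_ipt(1, 1, 0, 1), 0) # min dominance
  # never exceeds drug availability
  set.seed(11)
  for (i in 1:20) {
    x <- runif(4)
    expect_lte(provider_readiness_ipt(x[1], x[2], x[3], x[4]), x[3])
  }
})

test_that("motivation averages three terms, joined by trust only under P4P", {
  expect_equal(health_worker_motivation(0.5, 0.5, 0.5), 0.5)
  expect_equal(health_worker_motivation(0.6, 0.8, 0.4), 0.6)
  expect_equal(health_worker_motivation(0.6, 0.8, 0.4, trust = 0.2,
                                        p4p_on = TRUE), 0.5)
  # trust outside the programme is a configuration error
  expect_error(health_worker_motivation(0.5, 0.5, 0.5, trust = 0.5),
               "P4P")
  expect_error(health_worker_motivation(0.5, 0.5, 0.5, p4p_on = TRUE),
               "trust")
})

test_that("motivation is monotone nondecreasing in each input", {
  set.seed(13)
  for (i in 1:10) {
    x <- runif(4)
    base <- health_worker_motivation(x[1], x[2], x[3], x[4], p4p_on = TRUE)
    for (j in 1:4) {
      y <- x
      y[j] <- min(1, y[j] + 0.1)
      expect_gte(health_worker_motivation(y[1], y[2], y[3], y[4],
                                          p4p_on = TRUE), base)
    }
  }
})

test_that("trust rises on payments, holds under short delays, decays under severe ones", {
  expect_equal(update_trust(0.5, TRUE, 0, delta_up = 0.1), 0.55)
  expect_equal(update_trust(0.5, FALSE, 2), 0.5) # short delay: suspended
  expect_equal(update_trust(0.5, FALSE, 5, delta_down = 0.1), 0.45)
  expect_equal(update_trust(0.5, TRUE, 0), 0.525) # default increment
  # saturating: trust never leaves [0, 1]
  tr <- 0.99
  for (i in 1:20) tr <- update_trust(tr, TRUE, 0)
  expect_lte(tr, 1)
})

test_that("outreach capacity is the mean of staffing and the funds index", {
  expect_equal(outreach_capacity(0, 0), 0)
  expect_equal(outreach_capacity(0.6, 0.4), 0.5)
})

test_that("awareness settles at inflow/decay in a constant environment", {
  m <- sf_model(
    stocks = list(aw = sf_stock(0.1, "index", soft = TRUE)),
    constants = list(inflow = sf_const(0.03, "index/month"),
                     lam = sf_const(0.1, "1/month")),
    flows = list(
      gain = sf_flow(function(v, t, hist) v$inflow, to = "aw",
                     unit = "index/month"),
      decay = sf_flow(function(v, t, hist) v$lam * v$aw, from = "aw",
                      unit = "index/month"))
  )
  traj <- sf_simulate(m, sim_config(horizon = 200))
  expect_equal(trajectory_value(traj, "aw")[200], 0.03 / 0.1,
               tolerance = 1e-4)
})

test_that("soft model variables stay inside [0, 1] across the scenario grid", {
  soft_vars <- c("trust", "mgr_motivation", "knowledge", "awareness",
                 "motivation", "provider_readiness", "ipt_availability",
                 "labour_availability", "drug_availability",
                 "perceived_quality", "outreach", "fbd_frac")
  for (cfg in list(default_cfg(), control_cfg())) {
    traj <- run_p4p(cfg)
    for (vn in soft_vars) {
      x <- trajectory_value(traj, vn)
      expect_true(all(x >= 0 & x <= 1), label = paste(vn, "in [0,1]"))
    }
  }
})

test_that("on-time payments give nondecreasing trust; delays erode it by horizon end", {
  on_time <- run_p4p(default_cfg())
  trust_on <- trajectory_value(on_time, "trust")
  expect_true(all(diff(trust_on) >= -1e-12))

  cfg <- default_cfg()
  cfg$p4p$schedule <- "actual_delayed"
  delayed <- run_p4p(cfg)
  trust_del <- trajectory_value(delayed, "trust")
  expect_lt(trust_del[54], trust_on[54])
  # severe-delay decay kicks in late in the delayed run
  expect_lt(trust_del[54], max(trust_del))
})
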