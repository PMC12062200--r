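test_that("a step with all flow rates zero leaves every stock unchanged", {
  m <- sf_model(
    stocks = list(a = sf_stock(7, "units"), b = sf_stock(0.5, "units")),
    flows = list(f = sf_flow(function(v, t, hist) 0, from = "a", to = "b",
                             unit = "units/month"))
  )
  res <- sf_step(m, list(a = 7, b = 0.5), t = 1)
  expect_identical(res$stocks, c(a = 7, b = 0.5))
})

test_that("single months of the medicine example follow the hand recurrence", {
  m <- medicine_toy_model()
  # delivery month: 0 on hand, 225 arrive, 100 demanded -> 125 left
  res <- sf_step(m, list(stock_of_medicine = 0), t = 1)
  expect_equal(unname(res$stocks), 125)
  expect_equal(unname(res$flows["depletion"]), 100)
  # stockout month: 25 on hand, no delivery, 100 demanded -> dispense 25
  res <- sf_step(m, list(stock_of_medicine = 25), t = 2)
  expect_equal(unname(res$stocks), 0)
  expect_equal(unname(res$flows["depletion"]), 25)
})

test_that("the medicine example matches an independent scalar recurrence over 54 months", {
  traj <- sf_simulate(medicine_toy_model(), sim_config(horizon = 54))
  oracle <- toy_recurrence(54)
  expect_equal(trajectory_value(traj, "stock_of_medicine"), oracle$stock)
  expect_equal(trajectory_value(traj, "depletion"), oracle$dispensed)
  # recurring stockouts: the stock is never fully replenished and hits
  # zero every third month
  expect_true(all(oracle$stock < 300))
  expect_equal(which(oracle$stock == 0), seq(3, 54, by = 3))
})

test_that("full fulfilment with an adequate buffer never leaves a shortfall", {
  m <- medicine_toy_model(fulfilment = 1, init = 300)
  traj <- sf_simulate(m, sim_config(horizon = 54))
  expect_true(all(trajectory_value(traj, "stock_of_medicine") >= 0))
  expect_true(all(trajectory_value(traj, "depletion") == 100))
})

test_that("horizon 1 yields a single time point", {
  traj <- sf_simulate(medicine_toy_model(), sim_config(horizon = 1))
  expect_identical(nrow(traj), 1L)
})

test_that("simulation is deterministic: identical runs are bit-identical", {
  cfg <- sim_config(horizon = 24, seed = 42)
  t1 <- sf_simulate(medicine_toy_model(), cfg)
  t2 <- sf_simulate(medicine_toy_model(), cfg)
  expect_identical(unclass(t1), unclass(t2))
})

test_that("stocks are conserved exactly: value = init + cum inflow - cum outflow", {
  traj <- sf_simulate(medicine_toy_model(), sim_config(horizon = 54))
  expect_conserved(traj, "stock_of_medicine", "replenishment", "depletion")
  traj2 <- sf_simulate(two_stock_model(), sim_config(horizon = 10))
  expect_conserved(traj2, "a", character(), "transfer")
  expect_conserved(traj2, "b", "transfer", character())
})

test_that("outflows from nonneg stocks are capped and capping propagates to sinks", {
  # a holds 10, transfer wants 3/month: months 1-3 full, month 4 only 1
  traj <- sf_simulate(two_stock_model(), sim_config(horizon = 6))
  expect_equal(trajectory_value(traj, "transfer"), c(3, 3, 3, 1, 0, 0))
  expect_equal(trajectory_value(traj, "a"), c(7, 4, 1, 0, 0, 0))
  expect_equal(trajectory_value(traj, "b"), c(3, 6, 9, 10, 10, 10))
})

test_that("soft stocks stay inside [0, 1]", {
  m <- sf_model(
    stocks = list(idx = sf_stock(0.9, "index", soft = TRUE)),
    flows = list(gain = sf_flow(function(v, t, hist) 0.2, to = "idx",
                                unit = "index/month"))
  )
  traj <- sf_simulate(m, sim_config(horizon = 5))
  expect_true(all(trajectory_value(traj, "idx") <= 1))
  expect_equal(trajectory_value(traj, "idx")[2:5], rep(1, 4))
})

test_that("cyclic auxiliary dependencies are a configuration error", {
  expect_error(
    sf_model(
      stocks = list(s = sf_stock(1, "u")),
      flows = list(f = sf_flow(function(v, t, hist) 0, from = "s",
                               unit = "u/month")),
      auxiliaries = list(
        x = sf_aux(function(v, t, hist) v$y + 1, deps = "y"),
        y = sf_aux(function(v, t, hist) v$x + 1, deps = "x"))
    ),
    "cyclic"
  )
})

test_that("unknown variable references are configuration errors", {
  expect_error(
    sf_model(
      stocks = list(s = sf_stock(1, "u")),
      flows = list(f = sf_flow(function(v, t, hist) 0, from = "s",
                               unit = "u/month")),
      auxiliaries = list(x = sf_aux(function(v, t, hist) v$ghost,
                                    deps = "ghost"))
    ),
    "unknown variable"
  )
  # undeclared missing reference surfaces at evaluation time, named
  m <- sf_model(
    stocks = list(s = sf_stock(1, "u")),
    flows = list(f = sf_flow(function(v, t, hist) 0, from = "s",
                             unit = "u/month")),
    auxiliaries = list(x = sf_aux(function(v, t, hist) v$ghost + 1))
  )
  expect_error(sf_simulate(m, sim_config(horizon = 1)), "'x'")
})

test_that("non-finite values abort with the variable and month named", {
  m <- sf_model(
    stocks = list(s = sf_stock(1, "u")),
    flows = list(f = sf_flow(function(v, t, hist) 0, from = "s",
                             unit = "u/month")),
    auxiliaries = list(bad = sf_aux(function(v, t, hist)
      if (t >= 3) NaN else 1))
  )
  expect_error(sf_simulate(m, sim_config(horizon = 5)), "month 3")
  expect_error(sf_simulate(m, sim_config(horizon = 5)), "bad")
})

test_that("check_units flags flows whose unit does not match stock unit per month", {
  expect_identical(nrow(check_units(medicine_toy_model())), 0L)
  m <- sf_model(
    stocks = list(doses = sf_stock(10, "doses")),
    flows = list(inflow = sf_flow(function(v, t, hist) 1, to = "doses",
                                  unit = "persons/month"))
  )
  viol <- check_units(m)
  expect_identical(nrow(viol), 1L)
  expect_identical(viol$expected, "doses/month")
})

test_that("sim_config rejects bad horizons and non-unit time steps", {
  expect_error(sim_config(horizon = 0), "horizon")
  expect_error(sim_config(dt = 0.5), "dt")
})

test_that("random small models conserve mass and respect nonnegativity", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(2:4, 1)
    stocks <- stats::setNames(
      lapply(seq_len(n), function(i) sf_stock(runif(1, 0, 20), "u")),
      paste0("s", seq_len(n)))
    flows <- list()
    for (k in seq_len(sample(2:5, 1))) {
      ends <- sample(c(NA, seq_len(n)), 2)
      if (all(is.na(ends))) ends[1] <- 1
      rate <- runif(1, 0, 5)
      flows[[paste0("f", k)]] <- sf_flow(
        local({ r <- rate; function(v, t, hist) r }),
        from = if (is.na(ends[1])) NULL else paste0("s", ends[1]),
        to = if (is.na(ends[2])) NULL else paste0("s", ends[2]),
        unit = "u/month")
    }
    m <- sf_model(stocks = stocks, flows = flows)
    traj <- sf_simulate(m, sim_config(horizon = 20))
    for (i in seq_len(n)) {
      sn <- paste0("s", i)
      expect_true(all(trajectory_value(traj, sn) >= 0))
      inf <- names(flows)[vapply(flows, function(f)
        identical(f$to, sn), logical(1))]
      outf <- names(flows)[vapply(flows, function(f)
        identical(f$from, sn), logical(1))]
      expect_conserved(traj, sn, inf, outf)
    }
  }
})
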