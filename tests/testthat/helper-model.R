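# Shared fixtures: all built in code at test time.

# Independent scalar recurrence for the single-stock medicine example:
# order `order_qty` every `interval` months, supplier fulfils `fulfilment`,
# steady demand `demand`/month, dispensing stops at stockout.
toy_recurrence <- function(horizon, order_qty = 300, interval = 3,
                           fulfilment = 0.75, demand = 100, init = 0) {
  stock <- init
  out <- numeric(horizon)
  dispensed <- numeric(horizon)
  for (t in seq_len(horizon)) {
    delivered <- if ((t - 1) %% interval == 0) order_qty * fulfilment else 0
    stock <- stock + delivered
    dispensed[t] <- min(demand, stock)
    stock <- stock - dispensed[t]
    out[t] <- stock
  }
  list(stock = out, dispensed = dispensed)
}

# A tiny two-stock model with a transfer flow, for conservation and
# capping behaviour.
two_stock_model <- function(init_a = 10, init_b = 0, rate = 3) {
  sf_model(
    stocks = list(a = sf_stock(init_a, "units"),
                  b = sf_stock(init_b, "units")),
    flows = list(transfer = sf_flow(function(v, t, hist) rate,
                                    from = "a", to = "b",
                                    unit = "units/month"))
  )
}

default_cfg <- function() default_config()

control_cfg <- function() {
  cfg <- default_config()
  cfg$p4p$enabled <- FALSE
  cfg
}

# conservation check for a stock given its in/out flow columns
expect_conserved <- function(traj, stock, inflows, outflows, tol = 1e-9) {
  series <- trajectory_value(traj, stock)
  init <- attr(traj, "init")[[stock]]
  net <- rep(0, nrow(traj))
  for (f in inflows) net <- net + trajectory_value(traj, f)
  for (f in outflows) net <- net - trajectory_value(traj, f)
  expect_equal(series, init + cumsum(net), tolerance = tol)
}
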