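#' Declarative discrete-time stock-and-flow models
#'
#' A stock-and-flow model is described by four kinds of named variables, the
#' standard vocabulary of system dynamics:
#'
#' * **stocks** — accumulating state ("a container which changes value over
#'   time"), updated each month by its in- and outflows;
#' * **flows** — rates of change (units of the stock per month) attached to a
#'   source and/or sink stock;
#' * **auxiliaries** — derived time-varying quantities, evaluated every month
#'   in topological order of their declared dependencies;
#' * **constants** — fixed parameters.
#'
#' A fifth kind, **states**, holds discrete level variables (counters,
#' previous-cycle performance, trust indices updated by assignment rules)
#' that are re-assigned at the end of each month rather than integrated.
#'
#' Rules are R functions `function(v, t, hist)` where `v` is an environment
#' holding every variable's current value (stocks and states at their
#' start-of-month values, constants, and any auxiliary already evaluated),
#' `t` is the month (1-based), and `hist` is the matrix of all recorded
#' variable values for months `1..t-1` (columns named by variable). State
#' rules take a fourth argument `nxt`, a named numeric vector of the
#' end-of-month stock values.
#'
#' @param stocks named list of [sf_stock()] entries.
#' @param flows named list of [sf_flow()] entries.
#' @param auxiliaries named list of [sf_aux()] entries.
#' @param constants named list of [sf_const()] entries.
#' @param states named list of [sf_state()] entries.
#' @return An object of class `sf_model`.
#' @seealso [sf_simulate()], [sf_step()], [check_units()]
#' @examples
#' m <- medicine_toy_model()
#' traj <- sf_simulate(m, sim_config(horizon = 12))
#' trajectory_value(traj, "stock_of_medicine")
#' @export
sf_model <- function(stocks, flows, auxiliaries = list(), constants = list(),
                     states = list()) {
  stopifnot(is.list(stocks), is.list(flows), is.list(auxiliaries),
            is.list(constants), is.list(states))
  model <- structure(
    list(stocks = stocks, flows = flows, auxiliaries = auxiliaries,
         constants = constants, states = states),
    class = "sf_model"
  )
  validate_sf_model(model)
  model
}

#' @param init initial value.
#' @param unit unit of the stock (e.g. `"doses"`, `"persons"`).
#' @param nonneg logical; if `TRUE` outflows are capped so the stock never
#'   goes below zero (physical stocks: drugs, people, money).
#' @param soft logical; if `TRUE` the stock is a dimensionless index kept in
#'   `[0, 1]` (inflows are additionally capped at the headroom to 1).
#' @rdname sf_model
#' @export
sf_stock <- function(init, unit, nonneg = TRUE, soft = FALSE) {
  stopifnot(is.numeric(init), length(init) == 1L, is.character(unit))
  if (nonneg && init < 0) stop("nonneg stock initialised below zero")
  if (soft && (init < 0 || init > 1)) stop("soft stock must start in [0, 1]")
  list(init = init, unit = unit, nonneg = isTRUE(nonneg), soft = isTRUE(soft))
}

#' @param rate rate rule `function(v, t, hist)` returning the flow in
#'   stock-units per month; negative results are floored at zero.
#' @param from name of the source stock, or `NULL` for a flow from outside
#'   the model boundary.
#' @param to name of the sink stock, or `NULL`.
#' @rdname sf_model
#' @export
sf_flow <- function(rate, from = NULL, to = NULL, unit) {
  stopifnot(is.function(rate))
  if (is.null(from) && is.null(to)) stop("a flow needs a source or a sink")
  list(rate = rate, from = from, to = to, unit = unit)
}

#' @param rule auxiliary rule `function(v, t, hist)` returning a finite
#'   scalar.
#' @param deps character vector naming the *auxiliaries* this rule reads
#'   (dependencies on stocks, states and constants need not be declared);
#'   used to order evaluation within a month and to reject cycles.
#' @rdname sf_model
#' @export
sf_aux <- function(rule, unit = "index", deps = character()) {
  stopifnot(is.function(rule), is.character(deps))
  list(rule = rule, unit = unit, deps = deps)
}

#' @param value value of the constant.
#' @rdname sf_model
#' @export
sf_const <- function(value, unit) {
  stopifnot(is.numeric(value), length(value) == 1L)
  list(value = value, unit = unit)
}

#' @rdname sf_model
#' @export
sf_state <- function(init, rule, unit = "index") {
  stopifnot(is.numeric(init), length(init) == 1L, is.function(rule))
  list(init = init, rule = rule, unit = unit)
}

# ---- validation -----------------------------------------------------------

validate_sf_model <- function(model) {
  nm <- sf_variable_names(model)
  if (anyDuplicated(nm))
    stop("duplicate variable names in model: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (kind in c("stocks", "flows", "auxiliaries", "constants", "states")) {
    part <- model[[kind]]
    if (length(part) && (is.null(names(part)) || any(names(part) == "")))
      stop("all ", kind, " must be named")
  }
  known <- nm
  for (an in names(model$auxiliaries)) {
    bad <- setdiff(model$auxiliaries[[an]]$deps, known)
    if (length(bad))
      stop("auxiliary '", an, "' references unknown variable(s): ",
           paste(bad, collapse = ", "))
  }
  for (fn in names(model$flows)) {
    fl <- model$flows[[fn]]
    for (end in c(fl$from, fl$to))
      if (!is.null(end) && !end %in% names(model$stocks))
        stop("flow '", fn, "' references unknown stock '", end, "'")
  }
  sf_aux_order(model) # errors on cyclic dependencies
  invisible(model)
}

sf_variable_names <- function(model) {
  c(names(model$stocks), names(model$constants), names(model$states),
    names(model$auxiliaries), names(model$flows))
}

# Topological order of auxiliaries (Kahn's algorithm restricted to
# aux-to-aux edges). Errors if the dependency graph has a cycle.
sf_aux_order <- function(model) {
  auxn <- names(model$auxiliaries)
  if (!length(auxn)) return(character())
  deps <- lapply(model$auxiliaries, function(a) intersect(a$deps, auxn))
  names(deps) <- auxn
  ordered <- character()
  remaining <- auxn
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(a)
      !any(deps[[a]] %in% remaining), logical(1))]
    if (!length(ready))
      stop("cyclic auxiliary dependency among: ",
           paste(remaining, collapse = ", "))
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

#' Simulation configuration
#'
#' @param horizon number of months to simulate (default 54, the programme
#'   window January 2011 to July 2015 at a monthly reporting step).
#' @param start calendar label of month 1 (default `"2011-01"`).
#' @param dt time step in months; fixed at 1 (the performance reporting
#'   unit). Euler integration, no sub-stepping.
#' @param seed integer random seed recorded with the run. The core engine is
#'   deterministic; the seed matters only for stochastic layers built on top
#'   (e.g. synthetic evaluation data).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(horizon = 54L, start = "2011-01", dt = 1, seed = NULL) {
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("horizon must be >= 1")
  if (!identical(as.numeric(dt), 1)) stop("dt is fixed at 1 month")
  structure(list(horizon = horizon, start = start, dt = 1, seed = seed),
            class = "sim_config")
}

# ---- stepping -------------------------------------------------------------

# Internal single-month update. `env` holds current stock/state/constant
# values and is modified in place with this month's auxiliaries and realized
# flows. Returns list(stocks = <end-of-month stocks>, states = <new states>,
# flows = <realized flow values>).
sf_flow_topology <- function(model) {
  flown <- names(model$flows)
  stockn <- names(model$stocks)
  inflows <- lapply(stockn, function(s)
    flown[vapply(model$flows, function(f) identical(f$to, s), logical(1))])
  outflows <- lapply(stockn, function(s)
    flown[vapply(model$flows, function(f) identical(f$from, s), logical(1))])
  names(inflows) <- names(outflows) <- stockn
  list(inflows = inflows, outflows = outflows)
}

sf_step_impl <- function(model, env, t, hist, aux_order, topo, dt = 1) {
  for (an in aux_order) {
    val <- model$auxiliaries[[an]]$rule(env, t, hist)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("auxiliary '", an, "' did not evaluate to a finite scalar at month ",
           t, " (unknown variable reference or bad rule)")
    env[[an]] <- val
  }

  flown <- names(model$flows)
  rates <- numeric(length(flown))
  names(rates) <- flown
  for (fn in flown) {
    r <- model$flows[[fn]]$rate(env, t, hist)
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r))
      stop("flow '", fn, "' did not evaluate to a finite scalar at month ", t,
           " (unknown variable reference or bad rule)")
    rates[[fn]] <- max(0, r)
  }

  # Cap realized flows so nonneg stocks never go below zero and soft stocks
  # never exceed one. Scaling a stock's outflows shrinks another stock's
  # inflows, so iterate to a fixed point (realized rates only ever shrink).
  stockn <- names(model$stocks)
  inflows <- topo$inflows
  outflows <- topo$outflows

  realized <- rates
  for (iter in seq_len(25L)) {
    changed <- FALSE
    for (s in stockn) {
      spec <- model$stocks[[s]]
      val <- env[[s]]
      inn <- sum(realized[inflows[[s]]])
      out <- sum(realized[outflows[[s]]])
      if (spec$nonneg && out > 0) {
        avail <- val + dt * inn
        if (dt * out > avail + 1e-12) {
          scale <- max(0, avail) / (dt * out)
          realized[outflows[[s]]] <- realized[outflows[[s]]] * scale
          changed <- TRUE
        }
      }
      if (spec$soft && inn > 0) {
        headroom <- 1 - val + dt * sum(realized[outflows[[s]]])
        if (dt * inn > headroom + 1e-12) {
          scale <- max(0, headroom) / (dt * inn)
          realized[inflows[[s]]] <- realized[inflows[[s]]] * scale
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  new_stocks <- numeric(length(stockn))
  names(new_stocks) <- stockn
  for (s in stockn) {
    val <- env[[s]] +
      dt * (sum(realized[inflows[[s]]]) - sum(realized[outflows[[s]]]))
    spec <- model$stocks[[s]]
    if (spec$nonneg && val < 0) val <- if (val > -1e-9) 0 else
      stop("stock '", s, "' went negative at month ", t)
    if (spec$soft) val <- min(1, max(0, val))
    new_stocks[[s]] <- val
  }

  for (fn in flown) env[[fn]] <- realized[[fn]]

  new_states <- numeric(length(model$states))
  names(new_states) <- names(model$states)
  for (sn in names(model$states)) {
    val <- model$states[[sn]]$rule(env, t, hist, new_stocks)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("state '", sn, "' did not evaluate to a finite scalar at month ", t)
    new_states[[sn]] <- val
  }

  list(stocks = new_stocks, states = new_states, flows = realized)
}

#' Advance a stock-and-flow model by one month
#'
#' Evaluates auxiliaries in topological order using month-`t` values, then
#' flow rates, then updates each stock by `stock + dt * (inflows - outflows)`
#' with outflows capped so that non-negative stocks never go below zero, and
#' finally re-assigns discrete state variables.
#'
#' @param model an [sf_model()].
#' @param values named list or vector giving current values for every stock
#'   (and optionally every state; missing states take their initial values).
#' @param t the month being computed (1-based).
#' @param hist optional matrix of previously recorded months (columns named
#'   by variable), available to rules.
#' @return A list with elements `stocks` (end-of-month values), `states`,
#'   `aux` and `flows` (realized flow values after capping).
#' @examples
#' m <- medicine_toy_model()
#' sf_step(m, list(stock_of_medicine = 0), t = 1)$stocks
#' @export
sf_step <- function(model, values, t, hist = NULL) {
  values <- as.list(values)
  missing_stocks <- setdiff(names(model$stocks), names(values))
  if (length(missing_stocks))
    stop("values must contain all stocks; missing: ",
         paste(missing_stocks, collapse = ", "))
  env <- new.env(parent = emptyenv())
  for (cn in names(model$constants)) env[[cn]] <- model$constants[[cn]]$value
  for (s in names(model$stocks)) env[[s]] <- values[[s]]
  for (sn in names(model$states))
    env[[sn]] <- if (sn %in% names(values)) values[[sn]] else
      model$states[[sn]]$init
  if (is.null(hist)) {
    hist <- matrix(numeric(0), nrow = 0,
                   ncol = length(sf_variable_names(model)),
                   dimnames = list(NULL, sf_variable_names(model)))
  }
  res <- sf_step_impl(model, env, t, hist, sf_aux_order(model),
                      sf_flow_topology(model))
  aux <- vapply(names(model$auxiliaries), function(a) env[[a]], numeric(1))
  list(stocks = res$stocks, states = res$states, aux = aux,
       flows = res$flows)
}

#' Simulate a stock-and-flow model over its horizon
#'
#' Applies [sf_step()] month by month and records every stock, state,
#' auxiliary and realized flow. Stocks are recorded at their end-of-month
#' values; the initial (month-0) values are kept as an attribute so that
#' conservation can be checked exactly.
#'
#' @inheritParams sf_step
#' @param config a [sim_config()].
#' @return An object of class `sf_trajectory`: a numeric matrix with one row
#'   per month and one column per variable, with attributes `init` (initial
#'   stock and state values) and `config`.
#' @examples
#' traj <- sf_simulate(medicine_toy_model(), sim_config(horizon = 12))
#' head(as_tibble(traj))
#' @export
sf_simulate <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "sf_model"), inherits(config, "sim_config"))
  horizon <- config$horizon
  aux_order <- sf_aux_order(model)
  topo <- sf_flow_topology(model)
  varn <- c(names(model$stocks), names(model$states),
            names(model$auxiliaries), names(model$flows))
  hist <- matrix(NA_real_, nrow = horizon, ncol = length(varn),
                 dimnames = list(NULL, varn))

  env <- new.env(parent = emptyenv())
  for (cn in names(model$constants)) env[[cn]] <- model$constants[[cn]]$value
  stocks <- vapply(model$stocks, function(s) s$init, numeric(1))
  states <- vapply(model$states, function(s) s$init, numeric(1))

  for (t in seq_len(horizon)) {
    for (s in names(stocks)) env[[s]] <- stocks[[s]]
    for (sn in names(states)) env[[sn]] <- states[[sn]]
    res <- sf_step_impl(model, env, t,
                        hist[seq_len(t - 1L), , drop = FALSE], aux_order,
                        topo)
    stocks <- res$stocks
    states <- res$states
    row <- c(stocks, states,
             vapply(names(model$auxiliaries), function(a) env[[a]],
                    numeric(1)),
             res$flows)
    if (any(!is.finite(row))) {
      bad <- names(row)[!is.finite(row)][1]
      stop("non-finite value for '", bad, "' at month ", t)
    }
    hist[t, names(row)] <- row
  }

  structure(hist,
            init = c(vapply(model$stocks, function(s) s$init, numeric(1)),
                     vapply(model$states, function(s) s$init, numeric(1))),
            config = config,
            class = c("sf_trajectory", "matrix", "array"))
}

#' @export
print.sf_trajectory <- function(x, ...) {
  cat("<sf_trajectory> ", nrow(x), " months x ", ncol(x), " variables\n",
      sep = "")
  cat("variables: ", paste(utils::head(colnames(x), 8), collapse = ", "),
      if (ncol(x) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Extract one variable's monthly series from a trajectory
#'
#' @param traj an `sf_trajectory`.
#' @param variable variable name.
#' @return Numeric vector of length `horizon`.
#' @export
trajectory_value <- function(traj, variable) {
  stopifnot(inherits(traj, "sf_trajectory"))
  if (!variable %in% colnames(traj))
    stop("unknown variable '", variable, "'")
  as.numeric(traj[, variable])
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a trajectory into long format
#'
#' @param x an `sf_trajectory`.
#' @param ... unused.
#' @return A tibble with columns `month`, `variable`, `value`.
#' @export
as_tibble.sf_trajectory <- function(x, ...) {
  tibble::tibble(
    month = rep(seq_len(nrow(x)), times = ncol(x)),
    variable = rep(colnames(x), each = nrow(x)),
    value = as.numeric(x)
  )
}

#' Check dimensional consistency of a model
#'
#' Every flow must carry the unit of its attached stock per month (a flow in
#' `"doses/month"` may only feed or drain a stock measured in `"doses"`).
#' Report-only: returns the violations rather than erroring.
#'
#' @param model an [sf_model()].
#' @return A tibble with columns `flow`, `stock`, `expected`, `actual`;
#'   zero rows when the model is dimensionally consistent.
#' @examples
#' nrow(check_units(medicine_toy_model())) # 0
#' @export
check_units <- function(model) {
  stopifnot(inherits(model, "sf_model"))
  rows <- list()
  for (fn in names(model$flows)) {
    fl <- model$flows[[fn]]
    for (end in c(fl$from, fl$to)) {
      if (is.null(end)) next
      expected <- paste0(model$stocks[[end]]$unit, "/month")
      if (!identical(fl$unit, expected))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          flow = fn, stock = end, expected = expected, actual = fl$unit)
    }
  }
  if (!length(rows))
    return(tibble::tibble(flow = character(), stock = character(),
                          expected = character(), actual = character()))
  do.call(rbind, rows)
}

# Convenience for rules: value of `var` at month t-1, or `default` at t = 1.
sf_lag <- function(hist, t, var, default) {
  if (t <= 1L || nrow(hist) < t - 1L) default else hist[t - 1L, var]
}

#' Worked replenishment-and-depletion example model
#'
#' The introductory single-stock medicine model: a facility requests
#' `order_qty` items every `interval` months, the supplier fulfils a fixed
#' fraction of the request, and medicine is dispensed at a steady demand
#' rate. With the defaults (300 items requested quarterly, 75 % fulfilment,
#' demand 100 items/month) the stock is never fully replenished and the
#' facility experiences a recurring stockout every third month.
#'
#' @param order_qty items requested per order.
#' @param interval months between orders; deliveries arrive in order months
#'   (months 1, 1 + interval, ...).
#' @param fulfilment fraction of the request the supplier provides.
#' @param demand steady depletion, items per month.
#' @param init initial stock of medicine.
#' @return An [sf_model()] with stock `stock_of_medicine`, flows
#'   `replenishment` and `depletion`, and auxiliary `medicine_procured`.
#' @export
medicine_toy_model <- function(order_qty = 300, interval = 3,
                               fulfilment = 0.75, demand = 100, init = 0) {
  sf_model(
    stocks = list(
      stock_of_medicine = sf_stock(init, unit = "items", nonneg = TRUE)
    ),
    constants = list(
      medicine_requested = sf_const(order_qty, "items"),
      supplier_availability = sf_const(fulfilment, "fraction"),
      medicine_used = sf_const(demand, "items/month")
    ),
    auxiliaries = list(
      medicine_procured = sf_aux(function(v, t, hist) {
        if ((t - 1L) %% interval == 0L)
          v$medicine_requested * v$supplier_availability else 0
      }, unit = "items/month")
    ),
    flows = list(
      replenishment = sf_flow(function(v, t, hist) v$medicine_procured,
                              to = "stock_of_medicine", unit = "items/month"),
      depletion = sf_flow(function(v, t, hist) v$medicine_used,
                          from = "stock_of_medicine", unit = "items/month")
    )
  )
}
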