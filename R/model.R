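#' Build the six-sector facility P4P model
#'
#' Assembles the full stock-and-flow model from a configuration: the
#' population ageing chain, the ANC/delivery demand-and-services cascade,
#' facility drug commodities (quarterly MSD orders with partial fulfilment
#' and fund-financed emergency purchases), facility operations (readiness,
#' motivation, trust, outreach, awareness), facility funding, district
#' manager operations (supervision, knowledge gains, district incentives)
#' and the P4P intervention layer (six-month cycles, targets, payment
#' calendar, staff:operations split).
#'
#' With `p4p$enabled = FALSE` the intervention layer is inert: no targets
#' are evaluated, no payments flow, trust is excluded from motivation, and
#' the model reproduces the control (baseline system) trajectory exactly.
#'
#' @param config a [default_config()]-style configuration (validated here).
#' @return An [sf_model()].
#' @export
build_p4p_model <- function(config = default_config()) {
  cfg <- validate_config(config)
  pop <- cfg$population
  dem <- cfg$demand
  com <- cfg$commodities
  fac <- cfg$facility
  dis <- cfg$district
  fnd <- cfg$funding
  p4p <- cfg$p4p
  horizon <- cfg$simulation$horizon

  p4p_on <- isTRUE(p4p$enabled)
  pay_months <- if (p4p_on)
    payment_calendar(p4p$schedule, horizon, p4p$cycle_length, p4p$lag,
                     p4p$actual_months) else integer()
  cyc <- p4p$cycle_length
  dropout <- dem$dropout
  weights <- unlist(dem$weights)
  weights <- weights / sum(weights) # FBD weights normalized at build time
  mean_visits <- anc_core(dropout, 1)$mean_visits
  anc1_frac <- 1 - dropout[1]
  doses_per_woman <- function(r) anc_core(dropout, r)$doses
  policy_ipt <- supply_policy(com$order_interval, com$msd_fulfilment,
                              com$emergency_threshold, com$emergency_cover,
                              com$ipt_price)
  policy_lab <- supply_policy(com$order_interval, com$msd_fulfilment,
                              com$emergency_threshold, com$emergency_cover,
                              com$labour_price)

  cohort_units <- "persons"
  res <- unlist(pop$residence)
  mort <- unlist(pop$mortality)

  # ---- population sector --------------------------------------------------
  stocks <- list()
  for (cn in COHORT_NAMES)
    stocks[[paste0("pop_", cn)]] <-
      sf_stock(pop$cohorts[[cn]], cohort_units)

  flows <- list(
    births = sf_flow(function(v, t, hist) v$new_pregnancies,
                     to = "pop_neonates", unit = "persons/month")
  )
  chain <- paste0("pop_", COHORT_NAMES)
  for (i in seq_along(res)) {
    from <- chain[i]; to <- chain[i + 1]; rt <- res[[i]]
    flows[[paste0("maturation_", COHORT_NAMES[i])]] <- sf_flow(
      local({
        from_ <- from; rt_ <- rt
        function(v, t, hist) v[[from_]] / rt_
      }),
      from = from, to = to, unit = "persons/month")
  }
  for (i in seq_along(chain)) {
    flows[[paste0("deaths_", COHORT_NAMES[i])]] <- sf_flow(
      local({
        s_ <- chain[i]; m_ <- mort[[COHORT_NAMES[i]]]
        function(v, t, hist) v[[s_]] * m_
      }),
      from = chain[i], unit = "persons/month")
  }

  # ---- other stocks -------------------------------------------------------
  stocks$ipt_stock <- sf_stock(com$ipt_stock_init, "doses")
  stocks$labour_stock <- sf_stock(com$labour_stock_init, "doses")
  stocks$facility_funds <- sf_stock(fnd$funds_init, "currency")
  stocks$awareness <- sf_stock(fac$awareness_init, "index", soft = TRUE)
  stocks$p4p_liability <- sf_stock(0, "currency")
  stocks$district_liability <- sf_stock(0, "currency")

  constants <- list(
    fertility = sf_const(pop$fertility, "1/month"),
    staffing = sf_const(fac$staffing, "fraction"),
    distance_index = sf_const(dem$distance_index, "index"),
    msd_fulfilment = sf_const(com$msd_fulfilment, "fraction"),
    baseline_inflow = sf_const(fnd$baseline_inflow, "currency/month"),
    funds_ref = sf_const(fac$funds_ref, "currency"),
    alpha_outreach = sf_const(fac$alpha_outreach, "1/month"),
    beta_anc = sf_const(fac$beta_anc, "1/month"),
    lambda_awareness = sf_const(fac$lambda_awareness, "1/month"),
    district_resources = sf_const(dis$resources, "index"),
    district_skill = sf_const(dis$skill, "index")
  )

  states <- list(
    trust = sf_state(fac$trust_init, function(v, t, hist, nxt) {
      if (!p4p_on) return(v$trust)
      update_trust(v$trust, v$p4p_payment_made > 0, v$p4p_overdue,
                   fac$delta_up, fac$delta_down, fac$severe_delay)
    }),
    mgr_motivation = sf_state(dis$mgr_motivation_init,
      function(v, t, hist, nxt) {
        if (!p4p_on) return(v$mgr_motivation)
        update_trust(v$mgr_motivation, v$district_payment_made > 0,
                     v$district_overdue, fac$delta_up, fac$delta_down,
                     fac$severe_delay)
      }),
    knowledge = sf_state(fac$knowledge_init, function(v, t, hist, nxt) {
      upd <- supervision_effect_on_knowledge(
        v$knowledge, v$supervision_visit > 0, v$supervision_quality,
        v$visits_count, dis$knowledge_threshold, dis$gamma, dis$n_min)
      upd$knowledge * (1 - fac$knowledge_decay)
    }),
    visits_count = sf_state(0, function(v, t, hist, nxt)
      v$visits_count + v$supervision_visit, unit = "visits"),
    cum_supervision = sf_state(0, function(v, t, hist, nxt)
      v$cum_supervision + v$supervision_quality * v$supervision_visit,
      unit = "visits")
  )

  aux <- list()

  # population coupling
  aux$new_pregnancies <- sf_aux(function(v, t, hist)
    v$fertility * v$pop_repro_adults, unit = "persons/month")

  # demand expectations used for ordering and availability.
  # Orders reflect the expected number of patients fed in from the demand
  # sector: last month's realized readiness and facility-delivery fraction.
  aux$expected_ipt_demand <- sf_aux(function(v, t, hist) {
    r <- if (t <= 1) com$expected_readiness_init else
      mean(hist[max(1, t - 3):(t - 1), "provider_readiness"])
    v$new_pregnancies * doses_per_woman(r)
  }, unit = "doses/month", deps = "new_pregnancies")
  aux$expected_labour_demand <- sf_aux(function(v, t, hist) {
    f <- sf_lag(hist, t, "fbd_frac", p4p$baseline_fbd / 100)
    v$new_pregnancies * f
  }, unit = "doses/month", deps = "new_pregnancies")

  # commodities: quarterly order, partial fulfilment, same-month delivery
  aux$ipt_delivery_qty <- sf_aux(function(v, t, hist)
    msd_delivery(place_quarterly_order(v$expected_ipt_demand, t,
                                       com$order_interval),
                 v$msd_fulfilment),
    unit = "doses/month", deps = "expected_ipt_demand")
  aux$labour_delivery_qty <- sf_aux(function(v, t, hist)
    msd_delivery(place_quarterly_order(v$expected_labour_demand, t,
                                       com$order_interval),
                 v$msd_fulfilment),
    unit = "doses/month", deps = "expected_labour_demand")

  # availability counts what can be dispensed this month: stock on hand
  # plus the same-month MSD delivery and any emergency purchase
  aux$ipt_availability <- sf_aux(function(v, t, hist)
    availability_index(v$ipt_stock + v$ipt_delivery_qty +
                         v$ipt_purchase_qty,
                       v$expected_ipt_demand, com$cover_months),
    unit = "index",
    deps = c("expected_ipt_demand", "ipt_delivery_qty", "ipt_purchase_qty"))
  aux$labour_availability <- sf_aux(function(v, t, hist)
    availability_index(v$labour_stock + v$labour_delivery_qty +
                         v$labour_purchase_qty,
                       v$expected_labour_demand, com$cover_months),
    unit = "index",
    deps = c("expected_labour_demand", "labour_delivery_qty",
             "labour_purchase_qty"))
  aux$drug_availability <- sf_aux(function(v, t, hist)
    (v$ipt_availability + v$labour_availability) / 2,
    unit = "index", deps = c("ipt_availability", "labour_availability"))

  # district supervision
  aux$supervision_visit <- sf_aux(function(v, t, hist)
    as.numeric(t %% dis$visit_interval == 0), unit = "switch")
  aux$supervision_quality <- sf_aux(function(v, t, hist)
    supervision_quality(v$district_resources, v$mgr_motivation,
                        v$district_skill), unit = "index")

  # facility operations
  aux$motivation <- sf_aux(function(v, t, hist) {
    if (p4p_on)
      health_worker_motivation(v$drug_availability, v$supervision_quality,
                               v$staffing, trust = v$trust, p4p_on = TRUE)
    else
      health_worker_motivation(v$drug_availability, v$supervision_quality,
                               v$staffing)
  }, unit = "index", deps = c("drug_availability", "supervision_quality"))
  aux$provider_readiness <- sf_aux(function(v, t, hist)
    provider_readiness_ipt(v$knowledge, v$staffing, v$ipt_availability,
                           v$motivation),
    unit = "index", deps = c("ipt_availability", "motivation"))

  # P4P payment due this month (pays out the full outstanding liability)
  aux$p4p_payment_due <- sf_aux(function(v, t, hist)
    if (p4p_on && t %in% pay_months) v$p4p_liability else 0,
    unit = "currency/month")
  aux$staff_incentive <- sf_aux(function(v, t, hist)
    disburse(v$p4p_payment_due, p4p$staff_share)$staff,
    unit = "currency/month", deps = "p4p_payment_due")
  aux$operations_payment <- sf_aux(function(v, t, hist)
    v$p4p_payment_due - v$staff_incentive,
    unit = "currency/month", deps = c("p4p_payment_due", "staff_incentive"))
  aux$p4p_payment_made <- sf_aux(function(v, t, hist)
    as.numeric(v$p4p_payment_due > 0), unit = "switch",
    deps = "p4p_payment_due")
  aux$district_payment_due <- sf_aux(function(v, t, hist)
    if (p4p_on && t %in% pay_months) v$district_liability else 0,
    unit = "currency/month")
  aux$district_payment_made <- sf_aux(function(v, t, hist)
    as.numeric(v$district_payment_due > 0), unit = "switch",
    deps = "district_payment_due")

  # overdue bookkeeping from the record of earned cycle-end months
  aux$p4p_overdue <- sf_aux(function(v, t, hist) {
    if (!p4p_on) return(0)
    earned <- which(hist[, "p4p_earned"] > 0)
    months_overdue(t, earned, pay_months, p4p$lag)
  }, unit = "months")
  aux$district_overdue <- sf_aux(function(v, t, hist) {
    if (!p4p_on) return(0)
    earned <- which(hist[, "district_earned"] > 0)
    months_overdue(t, earned, pay_months, p4p$lag)
  }, unit = "months")

  # emergency purchases from facility-held funds (IPT first, labour next)
  aux$funds_available <- sf_aux(function(v, t, hist)
    v$facility_funds + v$baseline_inflow + v$operations_payment,
    unit = "currency", deps = "operations_payment")
  aux$ipt_purchase_qty <- sf_aux(function(v, t, hist) {
    stock_in <- v$ipt_stock + v$ipt_delivery_qty
    emergency_purchase(stock_in, v$expected_ipt_demand, v$funds_available,
                       policy_ipt)$units
  }, unit = "doses/month",
    deps = c("ipt_delivery_qty", "expected_ipt_demand", "funds_available"))
  aux$labour_purchase_qty <- sf_aux(function(v, t, hist) {
    stock_in <- v$labour_stock + v$labour_delivery_qty
    remaining <- v$funds_available - v$ipt_purchase_qty * com$ipt_price
    emergency_purchase(stock_in, v$expected_labour_demand,
                       max(0, remaining), policy_lab)$units
  }, unit = "doses/month",
    deps = c("labour_delivery_qty", "expected_labour_demand",
             "funds_available", "ipt_purchase_qty"))
  aux$drug_spend <- sf_aux(function(v, t, hist)
    v$ipt_purchase_qty * com$ipt_price +
      v$labour_purchase_qty * com$labour_price,
    unit = "currency/month",
    deps = c("ipt_purchase_qty", "labour_purchase_qty"))

  # ANC cascade for this month's pregnancy cohort; treatment is capped by
  # the IPT doses actually available, solving for the effective readiness
  # at which demanded doses equal the dispensable stock.
  aux$ipt_effective_readiness <- sf_aux(function(v, t, hist) {
    r <- v$provider_readiness
    preg <- v$new_pregnancies
    avail <- v$ipt_stock + v$ipt_delivery_qty + v$ipt_purchase_qty
    if (preg <= 0) return(r)
    demand <- preg * doses_per_woman(r)
    if (demand <= avail) return(r)
    lo <- 0; hi <- r
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (preg * doses_per_woman(mid) > avail) hi <- mid else lo <- mid
    }
    lo
  }, unit = "index",
    deps = c("provider_readiness", "new_pregnancies", "ipt_delivery_qty",
             "ipt_purchase_qty"))
  aux$ipt_doses <- sf_aux(function(v, t, hist)
    v$new_pregnancies * doses_per_woman(v$ipt_effective_readiness),
    unit = "doses/month",
    deps = c("new_pregnancies", "ipt_effective_readiness"))
  aux$ipt2_pct <- sf_aux(function(v, t, hist)
    100 * anc_core(dropout, v$ipt_effective_readiness)$ipt2_fraction,
    unit = "percent", deps = "ipt_effective_readiness")
  aux$anc_patients <- sf_aux(function(v, t, hist)
    v$new_pregnancies * mean_visits, unit = "persons/month",
    deps = "new_pregnancies")

  # facility-based deliveries
  aux$outreach <- sf_aux(function(v, t, hist)
    outreach_capacity(v$staffing,
                      min(1, v$facility_funds / v$funds_ref)),
    unit = "index")
  aux$perceived_quality <- sf_aux(function(v, t, hist)
    perceived_quality(v$drug_availability, v$motivation),
    unit = "index", deps = c("drug_availability", "motivation"))
  aux$fbd_frac <- sf_aux(function(v, t, hist)
    fbd_fraction(mean_visits, v$distance_index, v$awareness,
                 v$perceived_quality, weights),
    unit = "fraction", deps = "perceived_quality")
  aux$fbd_pct <- sf_aux(function(v, t, hist) 100 * v$fbd_frac,
                        unit = "percent", deps = "fbd_frac")
  aux$facility_deliveries <- sf_aux(function(v, t, hist)
    v$new_pregnancies * v$fbd_frac, unit = "persons/month",
    deps = c("new_pregnancies", "fbd_frac"))
  aux$labour_doses <- sf_aux(function(v, t, hist)
    min(v$facility_deliveries,
        v$labour_stock + v$labour_delivery_qty + v$labour_purchase_qty),
    unit = "doses/month",
    deps = c("facility_deliveries", "labour_delivery_qty",
             "labour_purchase_qty"))
  aux$ipt_stockout <- sf_aux(function(v, t, hist) {
    end_stock <- v$ipt_stock + v$ipt_delivery_qty + v$ipt_purchase_qty -
      v$ipt_doses
    as.numeric(end_stock < 1e-6)
  }, unit = "switch",
    deps = c("ipt_delivery_qty", "ipt_purchase_qty", "ipt_doses"))

  # awareness accumulation
  aux$awareness_inflow <- sf_aux(function(v, t, hist)
    v$alpha_outreach * v$outreach + v$beta_anc * anc1_frac,
    unit = "index/month", deps = "outreach")

  # cycle evaluation at cycle-end months
  aux$cycle_end <- sf_aux(function(v, t, hist)
    as.numeric(t %% cyc == 0), unit = "switch")
  aux$cycle_ipt2 <- sf_aux(function(v, t, hist) {
    if (t %% cyc != 0) return(0)
    prev <- if (cyc > 1) hist[(t - cyc + 1):(t - 1), "ipt2_pct"] else NULL
    mean(c(prev, v$ipt2_pct))
  }, unit = "percent", deps = "ipt2_pct")
  aux$cycle_fbd <- sf_aux(function(v, t, hist) {
    if (t %% cyc != 0) return(0)
    prev <- if (cyc > 1) hist[(t - cyc + 1):(t - 1), "fbd_pct"] else NULL
    mean(c(prev, v$fbd_pct))
  }, unit = "percent", deps = "fbd_pct")
  # Targets are set at programme commencement: the relative branch compares
  # each cycle's average to the pre-programme baseline plus the increment;
  # the absolute branch is a fixed coverage level, and once performance sits
  # above it, maintaining that average keeps the target achieved.
  aux$achieved_ipt2 <- sf_aux(function(v, t, hist) {
    if (!p4p_on || v$cycle_end == 0) return(0)
    as.numeric(v$cycle_ipt2 >= p4p$baseline_ipt2 + p4p$increment ||
                 v$cycle_ipt2 >= p4p$absolute_ipt2)
  }, unit = "switch", deps = c("cycle_end", "cycle_ipt2"))
  aux$achieved_fbd <- sf_aux(function(v, t, hist) {
    if (!p4p_on || v$cycle_end == 0) return(0)
    as.numeric(v$cycle_fbd >= p4p$baseline_fbd + p4p$increment ||
                 v$cycle_fbd >= p4p$absolute_fbd)
  }, unit = "switch", deps = c("cycle_end", "cycle_fbd"))
  aux$p4p_earned <- sf_aux(function(v, t, hist)
    p4p$pay_per_indicator * (v$achieved_ipt2 + v$achieved_fbd),
    unit = "currency/month", deps = c("achieved_ipt2", "achieved_fbd"))
  aux$district_earned <- sf_aux(function(v, t, hist) {
    if (!p4p_on || v$cycle_end == 0) return(0)
    stockouts <- sum(hist[(t - cyc + 1):(t - 1), "ipt_stockout"]) +
      v$ipt_stockout
    perf <- (v$cycle_ipt2 + v$cycle_fbd) / 200
    ok <- stockouts <= dis$stockout_cap && perf >= dis$perf_floor
    if (ok) dis$payment else 0
  }, unit = "currency/month",
    deps = c("cycle_end", "cycle_ipt2", "cycle_fbd", "ipt_stockout"))

  # ---- remaining flows ----------------------------------------------------
  flows$ipt_delivery <- sf_flow(function(v, t, hist) v$ipt_delivery_qty,
                                to = "ipt_stock", unit = "doses/month")
  flows$ipt_purchase <- sf_flow(function(v, t, hist) v$ipt_purchase_qty,
                                to = "ipt_stock", unit = "doses/month")
  flows$ipt_dispensing <- sf_flow(function(v, t, hist) v$ipt_doses,
                                  from = "ipt_stock", unit = "doses/month")
  flows$labour_delivery <- sf_flow(function(v, t, hist)
    v$labour_delivery_qty, to = "labour_stock", unit = "doses/month")
  flows$labour_purchase <- sf_flow(function(v, t, hist)
    v$labour_purchase_qty, to = "labour_stock", unit = "doses/month")
  flows$labour_dispensing <- sf_flow(function(v, t, hist) v$labour_doses,
                                     from = "labour_stock",
                                     unit = "doses/month")
  flows$funding_inflow <- sf_flow(function(v, t, hist) v$baseline_inflow,
                                  to = "facility_funds",
                                  unit = "currency/month")
  flows$p4p_operations_inflow <- sf_flow(function(v, t, hist)
    v$operations_payment, to = "facility_funds", unit = "currency/month")
  flows$drug_spending <- sf_flow(function(v, t, hist) v$drug_spend,
                                 from = "facility_funds",
                                 unit = "currency/month")
  flows$p4p_accrual <- sf_flow(function(v, t, hist) v$p4p_earned,
                               to = "p4p_liability", unit = "currency/month")
  flows$p4p_payment <- sf_flow(function(v, t, hist) v$p4p_payment_due,
                               from = "p4p_liability",
                               unit = "currency/month")
  flows$district_accrual <- sf_flow(function(v, t, hist) v$district_earned,
                                    to = "district_liability",
                                    unit = "currency/month")
  flows$district_payment <- sf_flow(function(v, t, hist)
    v$district_payment_due, from = "district_liability",
    unit = "currency/month")
  flows$awareness_gain <- sf_flow(function(v, t, hist) v$awareness_inflow,
                                  to = "awareness", unit = "index/month")
  flows$awareness_decay <- sf_flow(function(v, t, hist)
    v$lambda_awareness * v$awareness, from = "awareness",
    unit = "index/month")

  sf_model(stocks = stocks, flows = flows, auxiliaries = aux,
           constants = constants, states = states)
}

#' Run the facility P4P model
#'
#' Builds the model from a configuration and simulates it over the
#' configured horizon.
#'
#' @param config a configuration list (see [default_config()]).
#' @return An `sf_trajectory` (see [sf_simulate()]); key outcome columns
#'   are `ipt2_pct` and `fbd_pct`.
#' @examples
#' traj <- run_p4p(default_config())
#' mean(trajectory_value(traj, "ipt2_pct"))
#' @export
run_p4p <- function(config = default_config()) {
  cfg <- validate_config(config)
  model <- build_p4p_model(cfg)
  sf_simulate(model, sim_config(horizon = cfg$simulation$horizon,
                                start = cfg$simulation$start,
                                seed = cfg$simulation$seed))
}

#' Monthly outcome indicators from a trajectory
#'
#' @param traj an `sf_trajectory` from [run_p4p()].
#' @return A tibble with columns `month`, `ipt2_pct`, `fbd_pct`,
#'   `anc_patients`, `facility_deliveries`.
#' @export
p4p_outcomes <- function(traj) {
  tibble::tibble(
    month = seq_len(nrow(traj)),
    ipt2_pct = trajectory_value(traj, "ipt2_pct"),
    fbd_pct = trajectory_value(traj, "fbd_pct"),
    anc_patients = trajectory_value(traj, "anc_patients"),
    facility_deliveries = trajectory_value(traj, "facility_deliveries")
  )
}
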