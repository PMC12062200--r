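#' Scenario specification
#'
#' A labelled set of configuration overrides (dotted paths) applied on top
#' of a base configuration.
#'
#' @param label unique scenario label.
#' @param overrides named list mapping dotted configuration paths (e.g.
#'   `"p4p.staff_share"`) to replacement values; paths must exist.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, overrides = list()) {
  stopifnot(is.character(label), length(label) == 1L, is.list(overrides))
  structure(list(label = label, overrides = overrides),
            class = "scenario_spec")
}

#' Default scenario grid
#'
#' The comparison set used throughout the analysis: the control (P4P off),
#' the original 75:25 design under on-time and under actually delayed
#' payments, and the five staff:operations share designs (10:90, 25:75,
#' 50:50, 75:25, 90:10) under both payment schedules. Scenarios whose
#' resolved configurations coincide (the 75:25 share runs duplicate the
#' on-time/delayed runs) are deduplicated.
#'
#' @param shares staff shares to sweep.
#' @return List of [scenario_spec()] objects.
#' @export
default_scenarios <- function(shares = c(0.10, 0.25, 0.50, 0.75, 0.90)) {
  sc <- list(
    scenario_spec("control", list("p4p.enabled" = FALSE)),
    scenario_spec("p4p_on_time", list("p4p.schedule" = "on_time")),
    scenario_spec("p4p_delayed", list("p4p.schedule" = "actual_delayed"))
  )
  for (s in shares) {
    lab <- sprintf("share_%02d_%02d", round(100 * s), round(100 * (1 - s)))
    sc[[length(sc) + 1L]] <- scenario_spec(
      paste0(lab, "_on_time"),
      list("p4p.schedule" = "on_time", "p4p.staff_share" = s))
    sc[[length(sc) + 1L]] <- scenario_spec(
      paste0(lab, "_delayed"),
      list("p4p.schedule" = "actual_delayed", "p4p.staff_share" = s))
  }
  sc
}

apply_overrides <- function(config, overrides) {
  for (path in names(overrides))
    config <- config_set(config, path, overrides[[path]])
  config
}

#' Run a grid of scenarios
#'
#' Resolves each scenario's configuration, deduplicates identical
#' configurations (keeping the first label, recording aliases), runs each
#' distinct configuration once, and returns trajectories plus a tidy
#' outcome summary.
#'
#' @param config base configuration.
#' @param scenarios list of [scenario_spec()]; defaults to
#'   [default_scenarios()].
#' @return A list of class `scenario_grid` with elements:
#'   \describe{
#'     \item{trajectories}{named list of `sf_trajectory` objects (one per
#'       distinct configuration).}
#'     \item{outcomes}{tibble with columns `scenario`, `month`, `ipt2_pct`,
#'       `fbd_pct`.}
#'     \item{summary}{tibble with one row per scenario: horizon means and
#'       cumulative outcomes.}
#'     \item{aliases}{named character vector mapping duplicate scenario
#'       labels to the label that was run.}
#'   }
#' @export
run_scenario_grid <- function(config = default_config(), scenarios = NULL) {
  if (is.null(scenarios)) scenarios <- default_scenarios()
  labels <- vapply(scenarios, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate scenario labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  base <- validate_config(config)

  resolved <- lapply(scenarios, function(s) apply_overrides(base, s$overrides))
  keys <- vapply(resolved, function(cfg)
    paste(deparse(unclass(cfg)), collapse = ""), character(1))
  first <- !duplicated(keys)
  aliases <- stats::setNames(labels[which(first)][match(keys, keys[first])],
                             labels)

  trajectories <- list()
  rows <- list()
  summaries <- list()
  for (i in which(first)) {
    lab <- labels[i]
    traj <- run_p4p(resolved[[i]])
    trajectories[[lab]] <- traj
    out <- p4p_outcomes(traj)
    rows[[lab]] <- tibble::tibble(scenario = lab, month = out$month,
                                  ipt2_pct = out$ipt2_pct,
                                  fbd_pct = out$fbd_pct)
    summaries[[lab]] <- tibble::tibble(
      scenario = lab,
      mean_ipt2 = mean(out$ipt2_pct),
      mean_fbd = mean(out$fbd_pct),
      cum_ipt_doses = sum(trajectory_value(traj, "ipt_doses")),
      stockout_months = sum(trajectory_value(traj, "ipt_stockout")))
  }
  structure(list(trajectories = trajectories,
                 outcomes = do.call(rbind, rows),
                 summary = do.call(rbind, summaries),
                 aliases = aliases),
            class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat("<scenario_grid> ", length(x$trajectories), " distinct runs\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Classify outcome sensitivity to a parameter perturbation
#'
#' The three-level scale for one-at-a-time perturbations: a change in
#' outcome below 5 % is not sensitive; sensitive is 5 % up to (but not
#' including) 15 %; very sensitive is 15 % up to 25 %; highly sensitive is
#' 25 % or more (the top boundary is inclusive).
#'
#' @param max_change_pct nonnegative percent change in the outcome.
#' @return One of `"not sensitive"`, `"sensitive"`, `"very sensitive"`,
#'   `"highly sensitive"`.
#' @examples
#' classify_sensitivity(7)  # "sensitive"
#' classify_sensitivity(25) # "highly sensitive"
#' @export
classify_sensitivity <- function(max_change_pct) {
  if (!is.finite(max_change_pct) || max_change_pct < 0)
    stop("change in outcome must be a nonnegative percent")
  if (max_change_pct >= 25) "highly sensitive"
  else if (max_change_pct >= 15) "very sensitive"
  else if (max_change_pct >= 5) "sensitive"
  else "not sensitive"
}

#' One-at-a-time sensitivity analysis
#'
#' Perturbs each listed parameter by plus and minus a fraction of its value
#' (default 10 %), reruns the model, and records the change in each key
#' outcome (IPT2 and FBD monthly percentages) relative to the base run.
#' "Change in outcome" is summarised over the horizon by `metric`: the
#' maximum absolute relative monthly change (default, conservative), the
#' mean, or the end-of-horizon value.
#'
#' @param config base configuration.
#' @param parameters character vector of dotted configuration paths to
#'   numeric scalar parameters; defaults to the contextual factors of
#'   interest (community awareness initial stock, distance to facility, MSD
#'   fulfilment, facility alternative funding, staffing).
#' @param perturbation fractional adjustment (default 0.10).
#' @param metric `"max"`, `"mean"` or `"endpoint"`.
#' @return A tibble with columns `parameter`, `direction`, `outcome`,
#'   `change_pct`, `classification`.
#' @export
sensitivity_analysis <- function(config = default_config(),
                                 parameters = c("facility.awareness_init",
                                                "demand.distance_index",
                                                "commodities.msd_fulfilment",
                                                "funding.baseline_inflow",
                                                "facility.staffing"),
                                 perturbation = 0.10,
                                 metric = c("max", "mean", "endpoint")) {
  metric <- match.arg(metric)
  stopifnot(perturbation > 0)
  base_cfg <- validate_config(config)
  base <- p4p_outcomes(run_p4p(base_cfg))

  summarise_change <- function(new, old) {
    rel <- abs(new - old) / pmax(abs(old), .Machine$double.eps)
    100 * switch(metric,
                 max = max(rel),
                 mean = mean(rel),
                 endpoint = rel[length(rel)])
  }

  rows <- list()
  for (par in parameters) {
    value <- config_get(base_cfg, par)
    if (!is.numeric(value) || length(value) != 1L)
      stop("cannot perturb '", par, "': not a numeric scalar parameter")
    if (is.logical(value))
      stop("cannot perturb switch parameter '", par, "'")
    for (dir in c(1, -1)) {
      new_value <- value * (1 + dir * perturbation)
      out <- p4p_outcomes(run_p4p(config_set(base_cfg, par, new_value)))
      for (oc in c("ipt2_pct", "fbd_pct")) {
        change <- summarise_change(out[[oc]], base[[oc]])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          parameter = par,
          direction = if (dir > 0) "+10%" else "-10%",
          outcome = oc,
          change_pct = change,
          classification = classify_sensitivity(change))
      }
    }
  }
  do.call(rbind, rows)
}

#' Extreme-condition validation suite
#'
#' Forces selected parameters to extreme values and checks the model
#' produces the qualitatively expected behaviour:
#' \itemize{
#'   \item with a first-visit ANC dropout rate of 0.999, only a handful of
#'     patients attend the first visit (under 1 % of the cohort);
#'   \item with MSD fulfilment forced to zero and no facility funds, the
#'     IPT stock depletes to zero and stays there.
#' }
#'
#' @param config base configuration (the extremes are applied on top).
#' @return A tibble with columns `test`, `expectation`, `observed`, `pass`.
#' @export
extreme_condition_suite <- function(config = default_config()) {
  cfg <- validate_config(config)

  # extreme ANC1 dropout
  c1 <- cfg
  c1$demand$dropout[1] <- 0.999
  t1 <- run_p4p(c1)
  cas <- anc_cascade(1000, c1$demand$dropout, 1)
  visit1_frac <- cas$visits$attending[1] / 1000
  # and the collapse propagates through the services sector: IPT2 ~ 0
  pass1 <- visit1_frac < 0.01 &&
    max(trajectory_value(t1, "ipt2_pct")) < 1

  # Medical Stores severely impacted, no alternative funds
  c2 <- cfg
  c2$p4p$enabled <- FALSE
  c2$commodities$msd_fulfilment <- 0
  c2$funding$baseline_inflow <- 0
  c2$funding$funds_init <- 0
  t2 <- run_p4p(c2)
  stock <- trajectory_value(t2, "ipt_stock")
  depleted <- which(stock <= 1e-9)
  pass2 <- length(depleted) > 0 &&
    all(stock[min(depleted):length(stock)] <= 1e-9)

  tibble::tibble(
    test = c("anc1_dropout_extreme", "msd_fulfilment_zero"),
    expectation = c("visit-1 attendance < 1% of cohort",
                    "IPT stock depletes to zero and stays at zero"),
    observed = c(sprintf("visit-1 attendance = %.2f%% of cohort",
                         100 * visit1_frac),
                 if (length(depleted))
                   sprintf("stock zero from month %d onward", min(depleted))
                 else "stock never depleted"),
    pass = c(pass1, pass2)
  )
}
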