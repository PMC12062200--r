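#' Default model configuration
#'
#' The full parameter set of the facility P4P model, organised in sections
#' mirroring the model sectors. Every value can be overridden via
#' [load_config()] or by editing the returned list; [validate_config()]
#' rejects unknown keys and out-of-range values.
#'
#' Section overview:
#' \describe{
#'   \item{simulation}{horizon (months), start label, dt (fixed 1), seed.}
#'   \item{population}{initial cohort sizes (synthetic catchment of about
#'     10,000 persons), cohort residence times (months), monthly mortality
#'     rates, monthly fertility of the reproductive-age cohort.}
#'   \item{demand}{per-visit ANC dropout rates, facility-based delivery
#'     weights (visits, distance, awareness, quality), distance index.}
#'   \item{commodities}{MSD fulfilment fraction, order interval, unit
#'     prices, emergency purchase threshold and cover, availability cover
#'     months, initial drug stocks, initial readiness expectation used to
#'     seed demand forecasting.}
#'   \item{facility}{staffing, initial knowledge and its slow decay,
#'     initial trust, trust increment/decay and the severe-delay threshold,
#'     awareness initial stock and its inflow/decay coefficients, the
#'     funds reference level that normalises the operations-funds index.}
#'   \item{district}{resources, skill, initial manager motivation,
#'     supervision cadence and knowledge-gain parameters, district target
#'     criteria (stockout cap, performance floor), district payment size.}
#'   \item{funding}{baseline monthly inflow of facility-held funds and the
#'     initial balance.}
#'   \item{p4p}{programme switch, payment schedule mode, staff share,
#'     payment per indicator, target increment and absolute thresholds,
#'     cycle length, payment lag, the observed delayed payment months, and
#'     the pre-programme baseline levels of the two indicators used to
#'     evaluate the first cycle.}
#' }
#'
#' @return Nested named list of class `p4p_config`.
#' @export
default_config <- function() {
  structure(list(
    simulation = list(horizon = 54L, start = "2011-01", dt = 1, seed = 1L),
    population = list(
      cohorts = list(neonates = 80, infants = 240, preschool = 1280,
                     children = 2900, repro_adults = 4500,
                     older_adults = 1000),
      residence = list(neonates = 3, infants = 9, preschool = 48,
                       children = 120, repro_adults = 420),
      mortality = list(neonates = 0.002, infants = 8e-04, preschool = 3e-04,
                       children = 1e-04, repro_adults = 2e-04,
                       older_adults = 0.004),
      fertility = 0.009
    ),
    demand = list(
      dropout = c(0.03, 0.08, 0.15, 0.25),
      weights = list(visits = 0.3, distance = 0.2, awareness = 0.3,
                     quality = 0.2),
      distance_index = 0.9
    ),
    commodities = list(
      msd_fulfilment = 0.75,
      order_interval = 3L,
      ipt_price = 1,
      labour_price = 1,
      emergency_threshold = 0.5,
      emergency_cover = 1,
      cover_months = 1,
      ipt_stock_init = 120,
      labour_stock_init = 60,
      expected_readiness_init = 0.7
    ),
    facility = list(
      staffing = 0.8,
      knowledge_init = 0.5,
      knowledge_decay = 0.005,
      trust_init = 0.6,
      delta_up = 0.05,
      delta_down = 0.10,
      severe_delay = 4L,
      awareness_init = 0.40,
      alpha_outreach = 0.05,
      beta_anc = 0.06,
      lambda_awareness = 0.08,
      funds_ref = 300
    ),
    district = list(
      resources = 0.5,
      skill = 0.6,
      mgr_motivation_init = 0.6,
      gamma = 0.2,
      knowledge_threshold = 0.5,
      n_min = 3L,
      visit_interval = 3L,
      stockout_cap = 1L,
      perf_floor = 0.6,
      payment = 50
    ),
    funding = list(baseline_inflow = 5, funds_init = 20),
    p4p = list(
      enabled = TRUE,
      schedule = "on_time",
      staff_share = 0.75,
      pay_per_indicator = 250,
      increment = 5,
      absolute_ipt2 = 80,
      absolute_fbd = 85,
      cycle_length = 6L,
      lag = 3L,
      actual_months = c(13, 18, 22, 27, 34, 42),
      baseline_ipt2 = 72,
      baseline_fbd = 69
    )
  ), class = "p4p_config")
}

#' Validate a model configuration
#'
#' Checks the section/key structure against [default_config()] (unknown
#' keys are rejected, missing keys are filled with defaults) and enforces
#' basic bounds: rates and indices in `[0, 1]`, horizon at least 1, a
#' positive cycle length, a staff share in `[0, 1]`, and a recognised
#' payment schedule.
#'
#' @param config a nested list as returned by [default_config()], possibly
#'   partial.
#' @return The completed, validated configuration (class `p4p_config`).
#' @export
validate_config <- function(config) {
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- default_config()
  bad <- unknown_keys(config, defaults)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg <- modify_defaults(defaults, config)

  with(cfg$simulation, {
    if (horizon < 1) stop("simulation.horizon must be >= 1")
    if (!identical(as.numeric(dt), 1)) stop("simulation.dt is fixed at 1")
  })
  check_range <- function(x, key, lo = 0, hi = 1) {
    if (any(!is.finite(x)) || any(x < lo) || any(x > hi))
      stop(key, " must lie in [", lo, ", ", hi, "]")
  }
  check_range(cfg$demand$dropout, "demand.dropout")
  check_range(cfg$demand$distance_index, "demand.distance_index")
  if (any(unlist(cfg$demand$weights) < 0))
    stop("demand.weights must be nonnegative")
  check_range(cfg$commodities$msd_fulfilment, "commodities.msd_fulfilment")
  check_range(cfg$facility$staffing, "facility.staffing")
  check_range(cfg$facility$knowledge_init, "facility.knowledge_init")
  check_range(cfg$facility$trust_init, "facility.trust_init")
  check_range(cfg$facility$awareness_init, "facility.awareness_init")
  check_range(cfg$district$resources, "district.resources")
  check_range(cfg$district$skill, "district.skill")
  check_range(cfg$district$mgr_motivation_init, "district.mgr_motivation_init")
  check_range(cfg$p4p$staff_share, "p4p.staff_share")
  check_range(cfg$p4p$absolute_ipt2, "p4p.absolute_ipt2", 0, 100)
  check_range(cfg$p4p$absolute_fbd, "p4p.absolute_fbd", 0, 100)
  if (cfg$p4p$increment < 0) stop("p4p.increment must be >= 0")
  if (!cfg$p4p$schedule %in% c("on_time", "actual_delayed"))
    stop("p4p.schedule must be 'on_time' or 'actual_delayed'")
  if (is.unsorted(cfg$p4p$actual_months, strictly = TRUE))
    stop("p4p.actual_months must be strictly increasing")
  if (any(unlist(cfg$population$mortality) < 0) ||
      cfg$population$fertility < 0)
    stop("population rates must be >= 0")
  if (any(unlist(cfg$population$residence) <= 0))
    stop("population.residence times must be > 0")
  if (any(unlist(cfg$population$cohorts) < 0))
    stop("population.cohorts must be >= 0")
  structure(cfg, class = "p4p_config")
}

# keys present in `config` but absent from `defaults`, as dotted paths
unknown_keys <- function(config, defaults, prefix = character()) {
  if (!is.list(config) || !is.list(defaults) || is.null(names(defaults)))
    return(character())
  out <- character()
  for (k in names(config)) {
    path <- paste(c(prefix, k), collapse = ".")
    if (!k %in% names(defaults)) {
      out <- c(out, path)
    } else if (is.list(config[[k]]) && is.list(defaults[[k]]) &&
               !is.null(names(defaults[[k]]))) {
      out <- c(out, unknown_keys(config[[k]], defaults[[k]], c(prefix, k)))
    }
  }
  out
}

modify_defaults <- function(defaults, config) {
  for (k in names(config)) {
    if (is.list(config[[k]]) && is.list(defaults[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- modify_defaults(defaults[[k]], config[[k]])
    } else {
      defaults[[k]] <- config[[k]]
    }
  }
  defaults
}

#' Read a configuration file
#'
#' Reads a YAML or JSON configuration file, fills unspecified keys with the
#' documented defaults and validates the result. An empty file yields the
#' full default configuration.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `p4p_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported configuration format: .", ext)
  )
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' Look up or modify a configuration entry by dotted path
#'
#' @param config a `p4p_config`.
#' @param path dotted key path, e.g. `"commodities.msd_fulfilment"`.
#' @param value replacement value (for `config_set`).
#' @return `config_get`: the value. `config_set`: the modified config.
#' @export
config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- config
  for (k in keys) {
    if (!is.list(out) || !k %in% names(out))
      stop("unknown configuration path: ", path)
    out <- out[[k]]
  }
  out
}

#' @rdname config_get
#' @export
config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  config_get(config, path) # errors if the path does not exist
  rec <- function(x, keys) {
    if (length(keys) == 1L) {
      x[[keys]] <- value
    } else {
      x[[keys[1]]] <- rec(x[[keys[1]]], keys[-1])
    }
    x
  }
  out <- rec(config, keys)
  class(out) <- class(config)
  out
}

#' @export
print.p4p_config <- function(x, ...) {
  cat("<p4p_config>\n")
  cat("  horizon:", x$simulation$horizon, "months; start",
      x$simulation$start, "\n")
  cat("  P4P:", if (isTRUE(x$p4p$enabled)) "on" else "off",
      "| schedule:", x$p4p$schedule,
      "| staff share:", x$p4p$staff_share, "\n")
  cat("  sections:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
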