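#' Population ageing chain
#'
#' The population sector is a six-cohort ageing chain (neonates, infants,
#' pre-schoolers, children, reproductive-age adults, adults over 50). Each
#' cohort loses persons to age-specific mortality and to maturation into the
#' next cohort (cohort size divided by its residence time); neonates gain
#' births. Its single coupling to the rest of the model is the monthly
#' number of newly pregnant women, which drives the antenatal care and
#' delivery caseload.
#'
#' @param cohorts named numeric vector of cohort sizes (persons); names must
#'   include `neonates`, `infants`, `preschool`, `children`, `repro_adults`,
#'   `older_adults`.
#' @param rates a list with elements `mortality` (named per-cohort monthly
#'   rates, 1/month), `residence` (named residence times in months for all
#'   cohorts except the terminal one) and `fertility` (pregnancies per
#'   reproductive-age person-month).
#' @param dt time step in months.
#' @return `age_population()`: the updated cohort vector after one step.
#' @examples
#' rates <- list(
#'   mortality = c(neonates = 0, infants = 0, preschool = 0, children = 0,
#'                 repro_adults = 0, older_adults = 0),
#'   residence = c(neonates = Inf, infants = Inf, preschool = Inf,
#'                 children = Inf, repro_adults = Inf),
#'   fertility = 0
#' )
#' cohorts <- c(neonates = 100, infants = 200, preschool = 1000,
#'              children = 3000, repro_adults = 4500, older_adults = 1200)
#' age_population(cohorts, rates) # unchanged
#' @export
age_population <- function(cohorts, rates, dt = 1) {
  validate_cohorts(cohorts)
  validate_vital_rates(rates)
  mort <- rates$mortality[COHORT_NAMES]
  res <- rates$residence[COHORT_NAMES[-length(COHORT_NAMES)]]

  births <- new_pregnancies(cohorts, rates)
  maturation <- cohorts[names(res)] / res
  deaths <- cohorts * mort

  out <- cohorts
  inflow <- c(births, unname(maturation))
  outflow <- c(unname(maturation), 0) + deaths
  out <- cohorts + dt * (inflow - outflow)
  pmax(out, 0)
}

#' @return `new_pregnancies()`: pregnancies per month (fertility rate times
#'   the reproductive-age cohort).
#' @rdname age_population
#' @export
new_pregnancies <- function(cohorts, rates) {
  validate_cohorts(cohorts)
  if (rates$fertility < 0) stop("fertility rate must be >= 0")
  unname(rates$fertility * cohorts[["repro_adults"]])
}

COHORT_NAMES <- c("neonates", "infants", "preschool", "children",
                  "repro_adults", "older_adults")

validate_cohorts <- function(cohorts) {
  if (!all(COHORT_NAMES %in% names(cohorts)))
    stop("cohorts must be named: ", paste(COHORT_NAMES, collapse = ", "))
  if (any(cohorts < 0)) stop("cohort counts must be >= 0")
  invisible(cohorts)
}

validate_vital_rates <- function(rates) {
  if (any(rates$mortality < 0)) stop("mortality rates must be >= 0")
  if (any(rates$residence <= 0)) stop("residence times must be > 0")
  if (rates$fertility < 0) stop("fertility rate must be >= 0")
  invisible(rates)
}

#' Convert an annual demographic rate to a monthly rate
#'
#' Uses compounding: `(1 + annual)^(1/12) - 1`, so that applying the monthly
#' rate twelve times reproduces the annual rate.
#'
#' @param annual annual rate (e.g. 0.02 for 2 %/year).
#' @return Monthly rate.
#' @examples
#' (1 + annual_to_monthly_rate(0.02))^12 - 1 # 0.02
#' @export
annual_to_monthly_rate <- function(annual) {
  if (any(annual < -1)) stop("annual rate below -100%")
  (1 + annual)^(1 / 12) - 1
}
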