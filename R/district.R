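#' District-manager supervision quality
#'
#' The quality of Council Health Management Team supervision visits: the
#' mean of district-level resources, management-team motivation and manager
#' skill. Manager motivation responds to district incentive payments with
#' the same increment/decay rule as facility trust, so supervision quality
#' rises when district payments are made and erodes under severe delays.
#'
#' @param resources district resources index, `[0, 1]`.
#' @param manager_motivation management-team motivation, `[0, 1]`.
#' @param skill district-manager skill level, `[0, 1]`.
#' @return Quality index in `[0, 1]`.
#' @examples
#' supervision_quality(0.4, 0.6, 0.8) # 0.6
#' @export
supervision_quality <- function(resources, manager_motivation, skill) {
  check_index(resources, manager_motivation, skill)
  mean(c(resources, manager_motivation, skill))
}

#' Effect of a supervision visit on health-worker knowledge
#'
#' On a visit month, knowledge gains a saturating increment proportional to
#' supervision quality. When the facility's base knowledge is below a
#' threshold, it takes a few visits before supervision starts to raise
#' knowledge: the first `n_min - 1` visits only accumulate (the visit
#' counter advances with zero gain). Nothing changes on non-visit months.
#'
#' @param knowledge current knowledge index, `[0, 1]`.
#' @param visit logical: does a supervision visit occur this month?
#' @param quality supervision quality, `[0, 1]`.
#' @param visits_so_far cumulative supervision visits before this month.
#' @param base_threshold knowledge level below which the delayed-onset rule
#'   applies (default 0.5).
#' @param gamma gain coefficient (default 0.2).
#' @param n_min visits required before gains begin at low base knowledge
#'   (default 3).
#' @return A list with updated `knowledge` and `visits` count.
#' @examples
#' supervision_effect_on_knowledge(0.8, TRUE, 1, visits_so_far = 5)$knowledge
#' # 0.84
#' @export
supervision_effect_on_knowledge <- function(knowledge, visit, quality,
                                            visits_so_far,
                                            base_threshold = 0.5,
                                            gamma = 0.2, n_min = 3) {
  check_index(knowledge, quality)
  stopifnot(visits_so_far >= 0)
  if (!isTRUE(visit))
    return(list(knowledge = knowledge, visits = visits_so_far))
  visits <- visits_so_far + 1
  gain_active <- knowledge >= base_threshold || visits >= n_min
  if (gain_active)
    knowledge <- knowledge + gamma * quality * (1 - knowledge)
  list(knowledge = min(1, knowledge), visits = visits)
}

#' Facility funds ledger update
#'
#' Facility-held funds gain a baseline inflow and (under P4P) the
#' operations share of incentive payments, and are spent on emergency drug
#' purchases. Spending beyond the available balance is capped; the balance
#' never goes negative.
#'
#' @param balance current balance (currency).
#' @param baseline_inflow routine monthly inflow (currency/month).
#' @param p4p_inflow operations share of P4P payments arriving this month.
#' @param spend requested drug spend this month.
#' @return A list with the new `balance` and the realized `spend`.
#' @examples
#' apply_funding_flows(100, 50, 0, 30)$balance # 120
#' @export
apply_funding_flows <- function(balance, baseline_inflow, p4p_inflow = 0,
                                spend = 0) {
  stopifnot(balance >= 0, baseline_inflow >= 0, p4p_inflow >= 0, spend >= 0)
  available <- balance + baseline_inflow + p4p_inflow
  spend <- min(spend, available)
  list(balance = available - spend, spend = spend)
}

#' District incentive response
#'
#' The district management team earns its incentive when both cycle
#' criteria are met: few enough stockout months in the cycle and mean
#' facility performance above a floor. A payment applies the trust-style
#' saturating increment to manager motivation; otherwise motivation follows
#' the severe-delay decay rule.
#'
#' @param stockout_months stockout months observed in the cycle.
#' @param mean_performance mean facility performance across indicators,
#'   `[0, 1]`.
#' @param motivation current manager motivation, `[0, 1]`.
#' @param payment_made logical: is a district payment disbursed this month?
#' @param months_overdue months the earned district payment is overdue.
#' @param stockout_cap maximum stockout months permitted per cycle
#'   (default 1).
#' @param perf_floor minimum mean performance (default 0.6).
#' @param delta_up,delta_down,severe trust-rule parameters, see
#'   [update_trust()].
#' @return A list with `earned` (logical, criteria met) and updated
#'   `motivation`.
#' @examples
#' district_incentive_response(0, 1, 0.5, payment_made = TRUE,
#'                             months_overdue = 0)$motivation # 0.525
#' @export
district_incentive_response <- function(stockout_months, mean_performance,
                                        motivation, payment_made = FALSE,
                                        months_overdue = 0,
                                        stockout_cap = 1, perf_floor = 0.6,
                                        delta_up = 0.05, delta_down = 0.10,
                                        severe = 4) {
  stopifnot(stockout_months >= 0)
  check_index(mean_performance, motivation)
  earned <- stockout_months <= stockout_cap && mean_performance >= perf_floor
  motivation <- update_trust(motivation, payment_made, months_overdue,
                             delta_up, delta_down, severe)
  list(earned = earned, motivation = motivation)
}
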