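#' Provider readiness to deliver IPT
#'
#' The minimum of IPT drug availability and the average of four indices:
#' health-worker knowledge of IPT, staffing (fraction of positions filled),
#' IPT drug availability, and health-worker motivation. Taking the minimum
#' with availability ensures readiness to deliver IPT never exceeds the
#' stock of medicine available.
#'
#' @param knowledge health-worker IPT knowledge index, `[0, 1]`.
#' @param staffing fraction of positions filled, `[0, 1]`.
#' @param ipt_availability IPT drug availability index, `[0, 1]`.
#' @param motivation health-worker motivation index, `[0, 1]`.
#' @return Readiness in `[0, 1]`, never exceeding `ipt_availability`.
#' @examples
#' provider_readiness_ipt(0.8, 0.6, 0.4, 0.6) # min(0.4, 0.6) = 0.4
#' @export
provider_readiness_ipt <- function(knowledge, staffing, ipt_availability,
                                   motivation) {
  check_index(knowledge, staffing, ipt_availability, motivation)
  min(ipt_availability,
      mean(c(knowledge, staffing, ipt_availability, motivation)))
}

#' Health-worker motivation
#'
#' With the P4P programme off, the average of overall drug availability
#' (IPT and labour), district-manager supervision quality, and staffing.
#' With P4P on, trust in the programme joins the average as an equally
#' weighted fourth term; trust only exists when the programme is on.
#'
#' @param drug_availability availability of all drugs, `[0, 1]`.
#' @param supervision district supervision quality, `[0, 1]`.
#' @param staffing fraction of positions filled, `[0, 1]`.
#' @param trust trust-in-programme index, `[0, 1]`; only when `p4p_on`.
#' @param p4p_on logical switch for the P4P programme.
#' @return Motivation index in `[0, 1]`.
#' @examples
#' health_worker_motivation(0.6, 0.8, 0.4) # 0.6
#' health_worker_motivation(0.6, 0.8, 0.4, trust = 0.2, p4p_on = TRUE) # 0.5
#' @export
health_worker_motivation <- function(drug_availability, supervision, staffing,
                                     trust = NULL, p4p_on = FALSE) {
  check_index(drug_availability, supervision, staffing)
  if (!p4p_on) {
    if (!is.null(trust))
      stop("trust in the programme only exists when P4P is switched on")
    return(mean(c(drug_availability, supervision, staffing)))
  }
  if (is.null(trust)) stop("P4P is on but no trust value supplied")
  check_index(trust)
  mean(c(drug_availability, supervision, staffing, trust))
}

#' Trust-in-programme update
#'
#' Trust gently increases whenever a payment is made (a saturating
#' increment towards 1) and decays when payments are severely delayed
#' (4 or more months overdue). Short delays — overdue but by fewer than the
#' severe-delay threshold — merely suspend improvement: trust is unchanged.
#'
#' @param trust current trust index, `[0, 1]`.
#' @param payment_made logical: was a payment made this month?
#' @param months_overdue months the oldest earned-but-unpaid payment is
#'   overdue (0 when nothing is outstanding).
#' @param delta_up saturating increment on payment months (default 0.05).
#' @param delta_down proportional decay per severely delayed month
#'   (default 0.10).
#' @param severe delay in months at and beyond which trust erodes
#'   (default 4).
#' @return Updated trust in `[0, 1]`.
#' @examples
#' update_trust(0.5, payment_made = TRUE, months_overdue = 0)  # 0.525
#' update_trust(0.5, payment_made = FALSE, months_overdue = 2) # 0.5
#' update_trust(0.5, payment_made = FALSE, months_overdue = 5) # 0.45
#' @export
update_trust <- function(trust, payment_made, months_overdue,
                         delta_up = 0.05, delta_down = 0.10, severe = 4) {
  check_index(trust)
  stopifnot(months_overdue >= 0)
  if (isTRUE(payment_made)) {
    trust <- trust + delta_up * (1 - trust)
  } else if (months_overdue >= severe) {
    trust <- trust - delta_down * trust
  }
  min(1, max(0, trust))
}

#' Outreach capacity
#'
#' The facility's ability to perform community outreach: the mean of
#' staffing and an operations-funds index. Outreach feeds the accumulation
#' of community awareness.
#'
#' @param staffing fraction of positions filled, `[0, 1]`.
#' @param funds_index facility operations funds index, `[0, 1]`.
#' @return Index in `[0, 1]`.
#' @examples
#' outreach_capacity(0.6, 0.4) # 0.5
#' @export
outreach_capacity <- function(staffing, funds_index) {
  check_index(staffing, funds_index)
  (staffing + funds_index) / 2
}

check_index <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("index inputs must lie in [0, 1]")
  invisible(vals)
}
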