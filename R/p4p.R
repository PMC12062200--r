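#' Performance target for an incentivised indicator
#'
#' A facility achieves its target for a cycle if it either improves by a
#' specified number of percentage points over its previous performance, or
#' reaches an absolute level of coverage. Once the absolute level has been
#' passed, maintaining that average keeps the target achieved.
#'
#' @param indicator `"ipt2"` or `"fbd"`.
#' @param increment required improvement over the previous cycle,
#'   percentage points (default 5).
#' @param absolute absolute achievement threshold, percent.
#' @return An object of class `performance_target`.
#' @export
performance_target <- function(indicator = c("ipt2", "fbd"), increment = 5,
                               absolute) {
  indicator <- match.arg(indicator)
  stopifnot(increment >= 0, absolute >= 0, absolute <= 100)
  structure(list(indicator = indicator, increment = increment,
                 absolute = absolute), class = "performance_target")
}

#' Evaluate one six-month performance cycle
#'
#' Cycle performance is the mean of the indicator's six monthly values. The
#' target is achieved if performance is at least the previous cycle's level
#' plus the increment, or at least the absolute threshold.
#'
#' @param series monthly indicator values (percent), covering at least the
#'   cycle's months.
#' @param cycle_index which cycle (1-based; cycle k covers months
#'   `(6k-5)..6k`).
#' @param target a [performance_target()].
#' @param previous previous performance to compare against; if `NULL`,
#'   computed as the mean of the preceding cycle's months (cycle 1 requires
#'   an explicit baseline).
#' @param cycle_length months per cycle (default 6).
#' @return A list with `achieved`, `average` and `previous`.
#' @examples
#' target <- performance_target("fbd", increment = 5, absolute = 85)
#' evaluate_cycle(rep(86, 6), 1, target, previous = 86)$achieved # TRUE
#' @export
evaluate_cycle <- function(series, cycle_index, target, previous = NULL,
                           cycle_length = 6) {
  stopifnot(inherits(target, "performance_target"), cycle_index >= 1)
  months <- (cycle_index - 1L) * cycle_length + seq_len(cycle_length)
  if (length(series) < max(months))
    stop("incomplete cycle: series does not cover months ",
         min(months), "-", max(months), "; evaluation deferred")
  average <- mean(series[months])
  if (is.null(previous)) {
    if (cycle_index == 1L)
      stop("cycle 1 needs an explicit pre-programme baseline as `previous`")
    prev_months <- months - cycle_length
    previous <- mean(series[prev_months])
  }
  achieved <- average >= previous + target$increment ||
    average >= target$absolute
  list(achieved = achieved, average = average, previous = previous)
}

#' Payment earned for a cycle
#'
#' The sum of the per-indicator payment over achieved indicators; zero when
#' nothing is achieved or the programme is disabled.
#'
#' @param achieved named logical vector of per-indicator achievement flags.
#' @param pay_per_indicator currency per achieved indicator.
#' @param enabled logical P4P switch.
#' @return Currency amount.
#' @examples
#' payment_amount(c(ipt2 = TRUE, fbd = TRUE), 100) # 200
#' @export
payment_amount <- function(achieved, pay_per_indicator = 100,
                           enabled = TRUE) {
  stopifnot(is.logical(achieved), pay_per_indicator >= 0)
  if (!enabled) return(0)
  sum(achieved) * pay_per_indicator
}

#' Split a payment between staff incentives and facility operations
#'
#' The staff share funds health-worker incentive payments (driving trust
#' and motivation); the remainder supplements facility-held funds, where it
#' can be used to purchase drugs.
#'
#' @param amount payment amount (currency).
#' @param staff_share fraction allocated to staff, in `[0, 1]`
#'   (default 0.75, the original 75:25 design).
#' @return A list with `staff` and `operations`; the two always sum exactly
#'   to `amount`.
#' @examples
#' disburse(200, 0.75) # staff 150, operations 50
#' disburse(200, 0.10) # staff 20,  operations 180
#' @export
disburse <- function(amount, staff_share = 0.75) {
  stopifnot(amount >= 0, staff_share >= 0, staff_share <= 1)
  staff <- amount * staff_share
  list(staff = staff, operations = amount - staff)
}

#' Payment calendar
#'
#' Months in which incentive payments are disbursed. Under the planned
#' (`"on_time"`) schedule, each six-month cycle is paid three months after
#' it closes: months 9, 15, 21, ... Under the `"actual_delayed"` schedule,
#' payments follow the calendar actually observed during programme
#' implementation: months 13, 18, 22, 27, 34 and 42. Amounts earned for a
#' cycle are carried (no forfeiture) until their calendar month.
#'
#' @param mode `"on_time"` or `"actual_delayed"`.
#' @param horizon simulation horizon in months.
#' @param cycle_length months per performance cycle (default 6).
#' @param lag months between cycle close and planned payment (default 3).
#' @param actual_months the observed delayed payment months.
#' @return Increasing integer vector of payment months within the horizon.
#' @examples
#' payment_calendar("on_time", 54)        # 9 15 21 27 33 39 45 51
#' payment_calendar("actual_delayed", 54) # 13 18 22 27 34 42
#' @export
payment_calendar <- function(mode = c("on_time", "actual_delayed"),
                             horizon = 54, cycle_length = 6, lag = 3,
                             actual_months = c(13, 18, 22, 27, 34, 42)) {
  mode <- match.arg(mode)
  stopifnot(horizon >= 1, cycle_length >= 1, lag >= 0,
            !is.unsorted(actual_months, strictly = TRUE))
  months <- if (mode == "on_time") {
    ends <- seq(cycle_length, horizon, by = cycle_length)
    ends + lag
  } else {
    actual_months
  }
  as.integer(months[months <= horizon])
}

#' Months overdue for the oldest earned-but-unpaid cycle
#'
#' A cycle's payment falls due `lag` months after the cycle closes. Given
#' the months in which payments were actually earned (cycle-end months with
#' a positive earned amount) and the payment calendar, returns how many
#' months past due the oldest outstanding payment is at month `t` (0 when
#' nothing earned is outstanding or nothing is yet due).
#'
#' @param t current month.
#' @param earned_months cycle-end months at which a payment was earned.
#' @param pay_months the payment calendar (see [payment_calendar()]); each
#'   payment month clears everything outstanding.
#' @param lag months from cycle close to due date (default 3).
#' @return Nonnegative integer count of months overdue.
#' @examples
#' months_overdue(49, earned_months = c(6, 42),
#'                pay_months = payment_calendar("actual_delayed", 54)) # 4
#' @export
months_overdue <- function(t, earned_months, pay_months, lag = 3) {
  if (!length(earned_months)) return(0L)
  unpaid <- vapply(earned_months, function(e)
    !any(pay_months > e & pay_months <= t), logical(1))
  due <- earned_months[unpaid] + lag
  due <- due[due < t]
  if (!length(due)) return(0L)
  as.integer(t - min(due))
}
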