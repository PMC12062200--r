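#' Quarterly drug order to the Medical Stores Department
#'
#' Facilities order quarterly from the Medical Stores Department (MSD), one
#' drug unit per anticipated service event over the coming order interval.
#' Orders are issued only in order months (months 1, 1 + interval, ...).
#'
#' @param expected_monthly expected service events (drug units) per month.
#' @param t current month (1-based).
#' @param interval months between orders (default 3, quarterly).
#' @return Units ordered this month (0 outside order months).
#' @examples
#' place_quarterly_order(100, t = 1) # 300
#' place_quarterly_order(100, t = 2) # 0
#' @export
place_quarterly_order <- function(expected_monthly, t, interval = 3) {
  stopifnot(expected_monthly >= 0, interval >= 1)
  if ((t - 1L) %% interval != 0L) return(0)
  interval * expected_monthly
}

#' Partial fulfilment of an order by the supplier
#'
#' @param order units ordered.
#' @param fulfilment fraction of the request the supplier can provide,
#'   `[0, 1]`.
#' @return Units delivered.
#' @examples
#' msd_delivery(300, 0.75) # 225
#' @export
msd_delivery <- function(order, fulfilment) {
  stopifnot(fulfilment >= 0, fulfilment <= 1, order >= 0)
  order * fulfilment
}

#' Supply policy for a facility drug
#'
#' @param order_interval months between MSD orders (default 3).
#' @param fulfilment MSD fulfilment fraction (default 0.75).
#' @param threshold emergency reorder point, as a fraction of expected
#'   monthly demand (default 0.5 months of cover).
#' @param cover purchase-up-to target in months of expected demand
#'   (default 1).
#' @param price currency per drug unit (default 1).
#' @return A list of class `supply_policy`.
#' @export
supply_policy <- function(order_interval = 3, fulfilment = 0.75,
                          threshold = 0.5, cover = 1, price = 1) {
  stopifnot(order_interval >= 1, fulfilment >= 0, fulfilment <= 1,
            threshold >= 0, cover > 0, price > 0)
  structure(list(order_interval = order_interval, fulfilment = fulfilment,
                 threshold = threshold, cover = cover, price = price),
            class = "supply_policy")
}

#' Emergency drug purchase from facility-held funds
#'
#' When the stock on hand falls below the reorder point (a fraction of one
#' month's expected demand), the facility tops up towards one month of cover
#' using whatever facility-held funds allow.
#'
#' @param stock units on hand.
#' @param expected_monthly expected monthly demand in units.
#' @param funds facility-held funds available (currency); must be >= 0.
#' @param policy a [supply_policy()].
#' @return A list with `units` bought and `spend` in currency.
#' @examples
#' emergency_purchase(10, 100, funds = 30, supply_policy()) # buys 30
#' @export
emergency_purchase <- function(stock, expected_monthly, funds,
                               policy = supply_policy()) {
  stopifnot(inherits(policy, "supply_policy"), stock >= 0,
            expected_monthly >= 0)
  if (funds < 0) stop("facility funds must not be negative")
  if (stock >= policy$threshold * expected_monthly)
    return(list(units = 0, spend = 0))
  deficit <- max(0, policy$cover * expected_monthly - stock)
  units <- min(deficit, funds / policy$price)
  list(units = units, spend = units * policy$price)
}

#' Drug availability index
#'
#' Stock on hand relative to a cover target, capped at 1. With zero expected
#' demand there is no unmet need and the index is 1.
#'
#' @param stock units on hand.
#' @param expected_monthly expected monthly demand in units.
#' @param cover_months months of demand regarded as full cover (default 1).
#' @return Index in `[0, 1]`.
#' @examples
#' availability_index(150, 100, cover_months = 3) # 0.5
#' @export
availability_index <- function(stock, expected_monthly, cover_months = 1) {
  stopifnot(stock >= 0, expected_monthly >= 0, cover_months > 0)
  if (expected_monthly == 0) return(1)
  min(1, stock / (cover_months * expected_monthly))
}
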