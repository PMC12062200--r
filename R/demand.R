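#' Antenatal care visit cascade with IPT dosing
#'
#' Each month's cohort of newly pregnant women can attend up to four ANC
#' visits. At every visit a woman either drops out (visit-specific dropout
#' rate), attends and receives treatment — one dose of intermittent
#' preventive treatment (IPT), up to a cap of two doses across the whole
#' pregnancy — or attends untreated. Whether an attending woman with fewer
#' than two doses is treated is governed by provider readiness. The cascade
#' is deterministic cohort bookkeeping: dose counts are carried as fractions
#' of the still-attending cohort and of dropouts.
#'
#' @param entrants size of the pregnancy cohort entering the cascade.
#' @param dropout per-visit dropout rates, length 4, each in `[0, 1]`
#'   (probability of not attending that visit given the previous one was
#'   attended; the first element is the probability of never attending).
#' @param readiness provider readiness to deliver IPT, in `[0, 1]`; the
#'   probability an attending woman with fewer than two doses receives a
#'   dose at that visit.
#' @return A list of class `anc_cascade`:
#'   \describe{
#'     \item{visits}{tibble with one row per visit: `attending`, `dropouts`,
#'       `treated`, `untreated`.}
#'     \item{doses}{total IPT doses given (= drug units consumed).}
#'     \item{dose_distribution}{cohort fractions ending with 0, 1, and >= 2
#'       doses.}
#'     \item{ipt2_fraction}{fraction of the cohort receiving >= 2 doses.}
#'     \item{mean_visits}{mean number of visits attended per woman (0..4).}
#'     \item{entrants}{cohort size.}
#'   }
#' @examples
#' cas <- anc_cascade(1000, dropout = c(0.1, 0.1, 0.1, 0.1), readiness = 0.5)
#' cas$visits$attending[1] # 900
#' @export
anc_cascade <- function(entrants, dropout, readiness) {
  stopifnot(length(dropout) == 4, all(dropout >= 0 & dropout <= 1),
            length(readiness) == 1, readiness >= 0, readiness <= 1,
            entrants >= 0)
  core <- anc_core(dropout, readiness)
  structure(list(
    visits = tibble::tibble(
      visit = 1:4,
      attending = entrants * core$attending,
      dropouts = entrants * core$dropouts,
      treated = entrants * core$treated,
      untreated = entrants * (core$attending - core$treated)),
    doses = entrants * core$doses,
    dose_distribution = core$dose_distribution,
    ipt2_fraction = core$ipt2_fraction,
    mean_visits = core$mean_visits,
    entrants = entrants
  ), class = "anc_cascade")
}

# Fast per-woman cascade on cohort fractions (no validation, no tibbles);
# used inside simulation rules where it runs thousands of times.
anc_core <- function(dropout, readiness) {
  a0 <- 1; a1 <- 0; a2 <- 0     # still attending, by doses so far
  f0 <- 0; f1 <- 0; f2 <- 0     # left the cascade, by doses so far
  attending <- dropouts <- treated <- numeric(4)
  doses <- 0
  mean_visits <- 0
  for (k in 1:4) {
    d <- dropout[k]
    f0 <- f0 + a0 * d; f1 <- f1 + a1 * d; f2 <- f2 + a2 * d
    a0 <- a0 * (1 - d); a1 <- a1 * (1 - d); a2 <- a2 * (1 - d)
    att <- a0 + a1 + a2
    attending[k] <- att
    dropouts[k] <- if (k == 1) 1 - att else attending[k - 1] - att
    mean_visits <- mean_visits + att
    t0 <- a0 * readiness
    t1 <- a1 * readiness
    a0 <- a0 - t0; a1 <- a1 + t0 - t1; a2 <- a2 + t1
    treated[k] <- t0 + t1
    doses <- doses + treated[k]
  }
  list(attending = attending, dropouts = dropouts, treated = treated,
       doses = doses,
       dose_distribution = c(d0 = f0 + a0, d1 = f1 + a1, d2 = f2 + a2),
       ipt2_fraction = f2 + a2, mean_visits = mean_visits)
}

#' IPT2 coverage of a monthly cohort
#'
#' Percentage of the pregnant cohort receiving at least two doses of IPT.
#'
#' @param cascade an [anc_cascade()].
#' @return Percent in `[0, 100]`; an empty cohort returns 0 with a warning.
#' @examples
#' compute_ipt2_pct(anc_cascade(1000, rep(0, 4), readiness = 1)) # 100
#' @export
compute_ipt2_pct <- function(cascade) {
  stopifnot(inherits(cascade, "anc_cascade"))
  if (cascade$entrants <= 0) {
    warning("empty pregnancy cohort; IPT2 undefined, returning 0")
    return(0)
  }
  100 * cascade$ipt2_fraction
}

#' Facility-based delivery fraction
#'
#' The fraction of deliveries occurring at the facility is a weighted linear
#' combination (clamped to `[0, 1]`) of four determinants: the mean number
#' of ANC visits (mapped linearly from 0–4 visits onto `[0, 1]`), a
#' distance-to-facility index (1 = nearest), community awareness of maternal
#' and child health services, and the perceived quality of the facility.
#' The default weights give perceived quality the smaller share, reflecting
#' a calibration choice to down-weight perceived quality.
#'
#' @param mean_visits mean ANC visits per woman, 0–4.
#' @param distance distance index in `[0, 1]` (1 = nearest).
#' @param awareness community awareness index in `[0, 1]`.
#' @param quality perceived-quality index in `[0, 1]`.
#' @param weights nonnegative weights for (visits, distance, awareness,
#'   quality); normalized with a warning if they do not sum to 1.
#' @return Fraction in `[0, 1]`, monotone nondecreasing in every input.
#' @examples
#' fbd_fraction(3, 0.8, 0.5, 0.6) # 0.655
#' @export
fbd_fraction <- function(mean_visits, distance, awareness, quality,
                         weights = c(0.3, 0.2, 0.3, 0.2)) {
  stopifnot(length(weights) == 4, all(weights >= 0),
            mean_visits >= 0, mean_visits <= 4,
            all(c(distance, awareness, quality) >= 0),
            all(c(distance, awareness, quality) <= 1))
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  if (abs(s - 1) > 1e-9) {
    warning("weights do not sum to 1; normalizing")
    weights <- weights / s
  }
  g <- mean_visits / 4
  val <- sum(weights * c(g, distance, awareness, quality))
  min(1, max(0, val))
}

#' Perceived quality of facility and services
#'
#' Arithmetic mean of overall drug availability and the patient-provider
#' interaction index. Health-worker motivation is used as the model's proxy
#' for patient-provider interaction.
#'
#' @param drug_availability availability of all drugs (IPT and labour),
#'   `[0, 1]`.
#' @param interaction patient-provider interaction index (health-worker
#'   motivation), `[0, 1]`.
#' @return Index in `[0, 1]`.
#' @examples
#' perceived_quality(0.4, 0.8) # 0.6
#' @export
perceived_quality <- function(drug_availability, interaction) {
  stopifnot(drug_availability >= 0, drug_availability <= 1,
            interaction >= 0, interaction <= 1)
  (drug_availability + interaction) / 2
}
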