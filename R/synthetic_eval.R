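#' Simulation months of the three evaluation waves
#'
#' The impact evaluation surveyed facilities at three time points:
#' baseline (January 2012), short term (February 2013) and long term
#' (February/March 2015). With month 1 = January 2011 these map to
#' simulation months 13, 26 and 50.
#'
#' @return Named integer vector of wave months.
#' @export
evaluation_waves <- function() {
  c(baseline = 13L, short_term = 26L, long_term = 50L)
}

#' Generate a synthetic impact-evaluation dataset
#'
#' Emulates the structure of the programme's controlled before-and-after
#' evaluation: two arms (intervention = P4P on, control = P4P off), three
#' survey waves, and the two incentivised indicators (IPT2 and FBD). The
#' model is run once per arm under `true_params`; each arm-by-wave-by-
#' indicator cell is observed with Gaussian sampling noise of standard
#' deviation `noise_sd / sqrt(n_facilities)` percentage points (facility-
#' level clustering collapsed into the square-root scaling), truncated to
#' `[0, 100]`.
#'
#' @param true_params named list of dotted configuration paths to values,
#'   overriding [default_config()]; these are the generating parameters a
#'   calibration should recover.
#' @param n_facilities facilities surveyed per arm (default 75).
#' @param noise_sd facility-level observation noise in percentage points
#'   (default 2); 0 gives noise-free observations equal to model output.
#' @param seed integer seed controlling the observation noise.
#' @param config base configuration the overrides are applied to.
#' @return A list of class `synthetic_eval` with elements `data` (tibble:
#'   `arm`, `wave`, `month`, `indicator`, `value`), `true_params`,
#'   `n_facilities`, `noise_sd` and `seed`.
#' @export
generate_evaluation_dataset <- function(true_params = list(),
                                        n_facilities = 75,
                                        noise_sd = 2,
                                        seed = 1L,
                                        config = default_config()) {
  stopifnot(n_facilities >= 1, noise_sd >= 0)
  cfg <- apply_overrides(validate_config(config), true_params)
  model_cells <- evaluation_cells(cfg)
  sd_obs <- noise_sd / sqrt(n_facilities)

  data <- model_cells
  if (sd_obs > 0) {
    old_seed <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()))
    set.seed(seed)
    noise <- stats::rnorm(nrow(data), 0, sd_obs)
    data$value <- pmin(100, pmax(0, data$value + noise))
  }
  structure(list(data = data, true_params = true_params,
                 n_facilities = n_facilities, noise_sd = noise_sd,
                 seed = seed),
            class = "synthetic_eval")
}

# Model values for the 12 evaluation cells (2 arms x 3 waves x 2
# indicators). Each wave observes the mean of the preceding 12 months
# (the surveys sampled women who had delivered in the last 12 months),
# which also smooths the model's quarterly stockout volatility the way a
# recall-based survey would.
evaluation_cells <- function(cfg, recall_window = 12L) {
  waves <- evaluation_waves()
  rows <- list()
  for (arm in c("intervention", "control")) {
    acfg <- cfg
    acfg$p4p$enabled <- (arm == "intervention")
    out <- p4p_outcomes(run_p4p(acfg))
    for (w in names(waves)) {
      m <- waves[[w]]
      window <- max(1L, m - recall_window + 1L):m
      rows[[length(rows) + 1L]] <- tibble::tibble(
        arm = arm, wave = w, month = m,
        indicator = c("ipt2", "fbd"),
        value = c(mean(out$ipt2_pct[window]), mean(out$fbd_pct[window])))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.synthetic_eval <- function(x, ...) {
  cat("<synthetic_eval> ", x$n_facilities, " facilities/arm, noise sd ",
      x$noise_sd, " pp, seed ", x$seed, "\n", sep = "")
  print(x$data)
  invisible(x)
}

#' Calibrate free model parameters to an evaluation dataset
#'
#' Minimises the sum of squared differences between the model's and the
#' dataset's twelve evaluation cells (2 arms x 3 waves x 2 indicators) over
#' the free parameters, using bounded cyclic coordinate descent with
#' successive grid refinement — a derivative-free search that is robust to
#' the model's threshold-induced kinks and fully deterministic.
#'
#' @param dataset a [generate_evaluation_dataset()] result, or any list
#'   with a `data` tibble of the same shape.
#' @param free_params named list mapping dotted configuration paths to
#'   `c(lower, upper)` bounds.
#' @param config base configuration for non-free parameters.
#' @param n_grid points per coordinate pass (default 7).
#' @param n_rounds refinement rounds (default 3); each round shrinks the
#'   search interval around the incumbent.
#' @return A list of class `calibration_result` with `fitted` (named
#'   vector), `loss`, `start_loss`, `recovery` (tibble of relative errors
#'   against the dataset's true parameters, when available) and `trace`.
#' @export
calibrate <- function(dataset, free_params, config = default_config(),
                      n_grid = 7, n_rounds = 3) {
  stopifnot(is.list(dataset), !is.null(dataset$data))
  base_cfg <- validate_config(config)
  obs <- dataset$data

  loss_fn <- function(values) {
    cfg <- base_cfg
    for (i in seq_along(values))
      cfg <- config_set(cfg, names(values)[i], values[[i]])
    cells <- evaluation_cells(cfg)
    merged <- merge(as.data.frame(obs), as.data.frame(cells),
                    by = c("arm", "wave", "indicator"),
                    suffixes = c("_obs", "_mod"))
    loss <- sum((merged$value_obs - merged$value_mod)^2)
    if (!is.finite(loss))
      stop("non-finite calibration loss at ",
           paste(names(values), signif(unlist(values), 4),
                 sep = "=", collapse = ", "))
    loss
  }

  if (!length(free_params)) {
    l0 <- loss_fn(stats::setNames(list(), character()))
    return(structure(list(fitted = stats::setNames(numeric(), character()),
                          loss = l0, start_loss = l0,
                          recovery = NULL, trace = NULL),
                     class = "calibration_result"))
  }

  par_names <- names(free_params)
  lower <- vapply(free_params, function(b) b[1], numeric(1))
  upper <- vapply(free_params, function(b) b[2], numeric(1))
  stopifnot(all(lower < upper))
  for (p in par_names) config_get(base_cfg, p) # paths must exist

  current <- stats::setNames(as.list((lower + upper) / 2), par_names)
  width <- upper - lower
  best_loss <- loss_fn(current)
  start_loss <- best_loss
  trace <- list()

  for (round in seq_len(n_rounds)) {
    for (p in par_names) {
      centre <- current[[p]]
      lo <- max(lower[[p]], centre - width[[p]] / 2)
      hi <- min(upper[[p]], centre + width[[p]] / 2)
      grid <- seq(lo, hi, length.out = n_grid)
      for (g in grid) {
        cand <- current
        cand[[p]] <- g
        l <- loss_fn(cand)
        if (l < best_loss - 1e-12) {
          best_loss <- l
          current <- cand
        }
      }
      trace[[length(trace) + 1L]] <- tibble::tibble(
        round = round, parameter = p, value = current[[p]],
        loss = best_loss)
    }
    width <- width / (n_grid - 1) * 2 # shrink around the incumbent
  }

  fitted <- stats::setNames(unlist(current), par_names)
  recovery <- NULL
  if (!is.null(dataset$true_params) && length(dataset$true_params)) {
    common <- intersect(par_names, names(dataset$true_params))
    if (length(common)) {
      truth <- unlist(dataset$true_params[common])
      rel_err <- 100 * abs(fitted[common] - truth) /
        pmax(abs(truth), .Machine$double.eps)
      recovery <- tibble::tibble(
        parameter = common,
        true = unname(truth),
        fitted = unname(fitted[common]),
        rel_error_pct = unname(rel_err))
    }
  }
  structure(list(fitted = fitted, loss = best_loss, start_loss = start_loss,
                 recovery = recovery, trace = do.call(rbind, trace)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> loss ", signif(x$loss, 6), "\n", sep = "")
  if (length(x$fitted)) {
    for (p in names(x$fitted))
      cat("  ", p, " = ", signif(x$fitted[[p]], 6), "\n", sep = "")
  }
  if (!is.null(x$recovery)) print(x$recovery)
  invisible(x)
}
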