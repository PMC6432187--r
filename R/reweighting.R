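#' Reweight a generalised-ensemble time series to canonical averages
#'
#' Computes `<O>_beta = <O exp(-beta Ep) / W(Ep)> / <exp(-beta Ep) / W(Ep)>`
#' from a tagged series (each record carrying the `ln W` actually used at
#' simulation time), with log-sum-exp stabilisation so results are
#' invariant under adding any constant to `ln W`. The Kish effective
#' sample size `(sum w)^2 / sum(w^2)` is reported per temperature and
#' target temperatures where it falls below `ess_min` are flagged (the
#' trustworthy window of a single run).
#'
#' @param series A tibble with at least columns `ep` and `lnw` (as produced
#'   by [run_canonical()] and [run_weighted()]).
#' @param beta Inverse temperature(s) to reweight to. Give either `beta`
#'   or `temperature`.
#' @param temperature Temperature(s), alternative to `beta`.
#' @param observables Character vector of series columns to average.
#' @param ess_min Effective-sample-size threshold for the warning flag.
#' @return A tibble with one row per (temperature, observable):
#'   `beta`, `temperature`, `observable`, `value`, `ess`, `flag`.
#' @examples
#' toy <- make_fixture("two-state-toy", n = 100)
#' reweight(toy, beta = 1)  # <Ep> = 1 / (1 + e) for the two-level system
#' @export
reweight <- function(series, beta = NULL, temperature = NULL,
                     observables = "ep", ess_min = 100) {
  if (is.null(beta)) {
    stopifnot(!is.null(temperature))
    beta <- 1 / temperature
  }
  stopifnot(nrow(series) > 0, all(c("ep", "lnw") %in% names(series)))
  purrr::map_dfr(beta, function(b) {
    lw <- -b * series$ep - series$lnw
    a <- max(lw)
    wgt <- exp(lw - a)
    sw <- sum(wgt)
    ess <- sw^2 / sum(wgt^2)
    purrr::map_dfr(observables, function(ob) {
      o <- series[[ob]]
      ok <- !is.na(o)
      tibble::tibble(beta = b, temperature = 1 / b, observable = ob,
                     value = sum(wgt[ok] * o[ok]) / sum(wgt[ok]),
                     ess = ess, flag = ess < ess_min)
    })
  })
}

reweight_moment <- function(series, b, o) {
  lw <- -b * series$ep - series$lnw
  a <- max(lw)
  wgt <- exp(lw - a)
  ok <- !is.na(o)
  sum(wgt[ok] * o[ok]) / sum(wgt[ok])
}

#' Thermal derivative of a reweighted observable
#'
#' Uses the fluctuation identity
#' `d<O>/dT = beta^2 (<O Ep> - <O><Ep>)` (with `kB = 1`), evaluated by
#' reweighted moments. For `O = Ep` this is `beta^2 Var(Ep)`, the
#' extensive specific heat `C_V`. The potential energy `Ep` stands in for
#' the total energy throughout, consistent with sampling conformational
#' phase space only; kinetic terms would add analytic contributions.
#'
#' @inheritParams reweight
#' @param observables Series columns to differentiate.
#' @return A tibble with `beta`, `temperature`, `observable`, `dvalue_dt`,
#'   `ess`, `flag`.
#' @export
thermal_derivative <- function(series, beta = NULL, temperature = NULL,
                               observables = "ep", ess_min = 100) {
  if (is.null(beta)) {
    stopifnot(!is.null(temperature))
    beta <- 1 / temperature
  }
  purrr::map_dfr(beta, function(b) {
    lw <- -b * series$ep - series$lnw
    a <- max(lw)
    wgt <- exp(lw - a)
    ess <- sum(wgt)^2 / sum(wgt^2)
    me <- reweight_moment(series, b, series$ep)
    purrr::map_dfr(observables, function(ob) {
      o <- series[[ob]]
      mo <- reweight_moment(series, b, o)
      moe <- reweight_moment(series, b, o * series$ep)
      tibble::tibble(beta = b, temperature = 1 / b, observable = ob,
                     dvalue_dt = b^2 * (moe - mo * me),
                     ess = ess, flag = ess < ess_min)
    })
  })
}

#' Specific heat curve from a tagged series
#'
#' `C_V(T) = beta^2 Var(Ep)` via reweighted moments, optionally per bead.
#'
#' @inheritParams reweight
#' @param per_bead Divide by the total bead count `n`.
#' @param n Total bead count (required if `per_bead`).
#' @return A tibble with `temperature` and `cv`.
#' @export
specific_heat <- function(series, temperature, per_bead = FALSE, n = NULL) {
  d <- thermal_derivative(series, temperature = temperature,
                          observables = "ep")
  cv <- d$dvalue_dt
  if (per_bead) {
    stopifnot(!is.null(n))
    cv <- cv / n
  }
  tibble::tibble(temperature = d$temperature, cv = cv, ess = d$ess,
                 flag = d$flag)
}

#' Block-jackknife estimate and error
#'
#' Bias-corrected block jackknife for arbitrary (possibly nonlinear)
#' statistics of a time series, including reweighted ratio estimators:
#' the series is cut into `blocks` contiguous blocks, the statistic is
#' evaluated on each leave-one-block-out subsample, and the jackknife
#' bias correction and error are formed from those replicates.
#'
#' @param series A tibble (or vector) of consecutive measurements.
#' @param statistic Function mapping a subsample (same type as `series`)
#'   to a single number.
#' @param blocks Number of contiguous blocks (default 20).
#' @return A tibble with `estimate` (bias-corrected), `error`, `bias` and
#'   `blocks`.
#' @examples
#' x <- tibble::tibble(v = rnorm(200))
#' jackknife(x, function(s) mean(s$v))
#' @export
jackknife <- function(series, statistic, blocks = 20) {
  n <- if (is.data.frame(series)) nrow(series) else length(series)
  stopifnot(n >= blocks, blocks >= 2)
  cut_idx <- floor(seq(0, n, length.out = blocks + 1))
  take <- function(keep) {
    if (is.data.frame(series)) series[keep, , drop = FALSE] else series[keep]
  }
  full <- statistic(take(seq_len(n)))
  reps <- vapply(seq_len(blocks), function(b) {
    drop <- (cut_idx[b] + 1):cut_idx[b + 1]
    statistic(take(setdiff(seq_len(n), drop)))
  }, numeric(1))
  mr <- mean(reps)
  est <- blocks * full - (blocks - 1) * mr
  err <- sqrt((blocks - 1) / blocks * sum((reps - mr)^2))
  tibble::tibble(estimate = est, error = err,
                 bias = (blocks - 1) * (mr - full), blocks = blocks)
}

#' Locate peaks in an observable-versus-temperature curve
#'
#' Finds local maxima whose prominence (height above the higher of the
#' two flanking minima) exceeds a threshold. Used to draw transition
#' lines from `C_V(T)`, `dRgyr^2/dT` or `dGamma2/dT` scans.
#'
#' @param x Grid coordinate (e.g. temperature), increasing.
#' @param y Curve values on the grid.
#' @param prominence Minimum prominence; default `0.05 * diff(range(y))`.
#' @return A tibble with `x`, `y` and `prominence` per detected peak
#'   (zero rows for monotone curves).
#' @export
scan_peaks <- function(x, y, prominence = NULL) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  n <- length(y)
  empty <- tibble::tibble(x = numeric(0), y = numeric(0),
                          prominence = numeric(0))
  if (n < 3) return(empty)
  if (is.null(prominence)) prominence <- 0.05 * diff(range(y))
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  if (length(is_peak) == 0) return(empty)
  prom <- vapply(is_peak, function(i) {
    lmin <- min(y[1:i]); rmin <- min(y[i:n])
    # prominence relative to the higher of the flanking valleys
    y[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= prominence
  tibble::tibble(x = x[is_peak][keep], y = y[is_peak][keep],
                 prominence = prom[keep])
}
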