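#' Density of states from multicanonical production data
#'
#' A flat-histogram production run under frozen weights directly yields
#' the conformational density of states: `ln Omega = ln H - ln W` bin by
#' bin, with the arbitrary additive constant fixed so that the maximum
#' covered bin is zero. Unvisited bins are `NA`.
#'
#' @param weights The [weight_table()] used for the production run.
#' @param hist Per-sweep visit counts on the table's bins (`$hist` of
#'   [run_weighted()]).
#' @return An object of class `density_of_states` with a tibble `bins`
#'   (`ep`, `ln_omega`, `count`), the bin width `de`, and provenance.
#' @export
dos_from_weights <- function(weights, hist) {
  nb <- length(weights$lnw)
  stopifnot(length(hist) == nb)
  centers <- weights$emin + (seq_len(nb) - 0.5) * weights$de
  ln_omega <- ifelse(hist > 0, log(hist) - weights$lnw, NA_real_)
  ln_omega <- ln_omega - max(ln_omega, na.rm = TRUE)
  structure(
    list(bins = tibble::tibble(ep = centers, ln_omega = ln_omega,
                               count = hist),
         de = weights$de,
         provenance = list(iterations = weights$meta$iterations %||% NA)),
    class = "density_of_states")
}

#' @export
print.density_of_states <- function(x, ...) {
  cov <- sum(!is.na(x$bins$ln_omega))
  cat("<density_of_states>", cov, "covered bins of", nrow(x$bins),
      ", dE =", x$de, "\n")
  invisible(x)
}

#' @rdname dos_from_weights
#' @param x A `density_of_states`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.density_of_states <- function(x, ...) x$bins

# Gaussian-weighted local *linear* smoother: fitting a line in each
# window and evaluating it at the centre is exactly unbiased for linear
# trends even in one-sided boundary windows, where a plain renormalised
# kernel average would bend a monotone profile and fake curvature.
gauss_smooth <- function(y, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(3 * sigma))
  n <- length(y)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    good <- j[!is.na(y[j])]
    if (length(good) == 0) next
    x <- good - i
    wk <- exp(-0.5 * (x / sigma)^2)
    if (length(good) < 3) {
      out[i] <- sum(wk * y[good]) / sum(wk)
    } else {
      sw <- sum(wk); sx <- sum(wk * x); sxx <- sum(wk * x^2)
      sy <- sum(wk * y[good]); sxy <- sum(wk * x * y[good])
      det0 <- sw * sxx - sx^2
      out[i] <- if (det0 > 0) (sxx * sy - sx * sxy) / det0 else sy / sw
    }
  }
  out
}

#' Microcanonical inverse temperature and its derivative
#'
#' From the conformational entropy `S(Ep) = ln Omega(Ep)` (`kB = 1`):
#' `beta(Ep) = dS/dEp` by central differences on the (optionally
#' Gaussian-smoothed) `ln Omega`, and `gamma(Ep) = dbeta/dEp` by second
#' differences. `beta` lives on bin boundaries and `gamma` on bin centres
#' (staggered grid) so both are centred differences.
#'
#' @param dos A [dos_from_weights()] result.
#' @param smooth_sigma Gaussian smoothing width in bins (default 2);
#'   0 disables smoothing.
#' @return An object of class `micro_profile` with tibbles `beta`
#'   (`ep`, `beta`) and `gamma` (`ep`, `gamma`), and the smoothing window
#'   used.
#' @export
micro_beta_gamma <- function(dos, smooth_sigma = 2) {
  b <- dos$bins
  ok <- which(!is.na(b$ln_omega))
  stopifnot(length(ok) >= 3)
  # restrict to the largest contiguous covered stretch
  runs <- split(ok, cumsum(c(1, diff(ok) != 1)))
  ok <- runs[[which.max(lengths(runs))]]
  ep <- b$ep[ok]
  s <- gauss_smooth(b$ln_omega[ok], smooth_sigma)
  de <- dos$de
  n <- length(s)
  beta <- (s[-1] - s[-n]) / de
  ep_beta <- (ep[-1] + ep[-n]) / 2
  gamma <- (s[-(1:2)] - 2 * s[-c(1, n)] + s[-((n - 1):n)]) / de^2
  ep_gamma <- ep[-c(1, n)]
  structure(
    list(beta = tibble::tibble(ep = ep_beta, beta = beta),
         gamma = tibble::tibble(ep = ep_gamma, gamma = gamma),
         smooth_sigma = smooth_sigma, de = de),
    class = "micro_profile")
}

#' @export
print.micro_profile <- function(x, ...) {
  cat("<micro_profile>", nrow(x$gamma), "gamma bins, smoothing sigma =",
      x$smooth_sigma, "bins\n")
  invisible(x)
}

#' @rdname micro_beta_gamma
#' @param x A `micro_profile`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.micro_profile <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$beta, quantity = "beta", value = .data$beta,
                  beta = NULL),
    dplyr::mutate(x$gamma, quantity = "gamma", value = .data$gamma,
                  gamma = NULL))
}

#' Classify a transition from the microcanonical profile
#'
#' First-order-like transitions announce themselves as *back-bending* of
#' the microcanonical inverse temperature: an interior local maximum of
#' `beta(Ep)` below which `beta` decreases again (equivalently, a
#' positive peak of `gamma`), accompanied by a double-peaked canonical
#' energy distribution. Second-order-like transitions show a monotone
#' `beta` with an inflection of negative slope, i.e. a negative interior
#' peak of `gamma`. Features are accepted only above a noise threshold
#' estimated from the high-energy tail of the profile; otherwise the
#' result is `"none"`. The transition energy `Ep'` is the location of
#' the corresponding `gamma` extremum.
#'
#' Monotone walls of `gamma` at the covered-range boundary (the steep
#' ground-state rise of `beta`) form no interior extremum and are never
#' picked up.
#'
#' @param profile A [micro_beta_gamma()] result.
#' @param noise_mult Threshold multiplier on the tail noise estimates.
#' @return A one-row tibble with `order` (`"first"`, `"second"`, `"none"`),
#'   `ep_prime`, `gamma_peak` and `threshold`.
#' @export
classify_transition <- function(profile, noise_mult = 3) {
  g <- profile$gamma
  b <- profile$beta
  n <- nrow(g)
  nb <- nrow(b)
  tail_g <- g$ep >= g$ep[n] - 0.25 * (g$ep[n] - g$ep[1])
  thr <- noise_mult * stats::median(abs(g$gamma[tail_g]))
  none <- tibble::tibble(order = "none", ep_prime = NA_real_,
                         gamma_peak = NA_real_, threshold = thr)
  if (n < 5) return(none)

  # --- back-bending: interior local maximum of beta with a significant
  # drop towards lower energies
  # roughness (not slope) sets the back-bend significance scale: the
  # median absolute second difference of beta over the high-energy tail
  tail_b <- which(b$ep >= b$ep[nb] - 0.25 * (b$ep[nb] - b$ep[1]))
  bt <- b$beta[tail_b]
  thr_b <- noise_mult * stats::median(abs(diff(diff(bt))))
  bmax_idx <- which(vapply(2:(nb - 1), function(i) {
    b$beta[i] >= b$beta[i - 1] && b$beta[i] >= b$beta[i + 1]
  }, logical(1))) + 1
  if (length(bmax_idx) > 0) {
    drops <- vapply(bmax_idx, function(i) {
      b$beta[i] - min(b$beta[1:i])
    }, numeric(1))
    i <- bmax_idx[which.max(drops)]
    if (max(drops) > max(thr_b, 5 * .Machine$double.eps)) {
      # Ep' = inflection point: steepest rise of beta below its maximum
      lo_i <- which.min(b$beta[1:i])
      sel <- g$ep >= b$ep[lo_i] & g$ep <= b$ep[i]
      if (any(sel)) {
        gp <- max(g$gamma[sel])
        epp <- g$ep[sel][which.max(g$gamma[sel])]
        return(tibble::tibble(order = "first", ep_prime = epp,
                              gamma_peak = gp, threshold = thr))
      }
    }
  }

  # --- second order: negative interior local minimum of gamma; bins
  # within the smoothing window of the boundary are excluded (the
  # ground-state entropy wall leaves a residual wiggle there)
  y <- g$gamma
  edge <- max(2L, ceiling(3 * profile$smooth_sigma))
  if (n <= 2 * edge + 1) return(none)
  rng <- (edge + 1):(n - edge)
  is_min <- vapply(rng, function(i) {
    y[i] <= y[i - 1] && y[i] <= y[i + 1]
  }, logical(1))
  cand <- rng[is_min]
  cand <- cand[y[cand] < 0]
  if (length(cand) == 0) return(none)
  i <- cand[which.min(y[cand])]
  if (abs(y[i]) <= thr) {
    none$gamma_peak <- y[i]
    return(none)
  }
  tibble::tibble(order = "second", ep_prime = g$ep[i], gamma_peak = y[i],
                 threshold = thr)
}

#' @rdname classify_transition
#' @param x A `micro_profile`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.micro_profile <- function(x, ...) classify_transition(x)

#' Rescaled microcanonical inverse temperature
#'
#' Recenters `beta(Ep)` on the transition point: `beta(Ep) - beta(Ep')`
#' versus `Ep - Ep'`, for overlaying transitions at different stiffness.
#' A pure (invertible) transformation of the profile.
#'
#' @param profile A [micro_beta_gamma()] result.
#' @param ep_prime Transition energy (e.g. from [classify_transition()]).
#' @return A tibble with `dep = Ep - Ep'` and `dbeta = beta - beta(Ep')`.
#' @export
rescaled_beta <- function(profile, ep_prime) {
  b <- profile$beta
  b0 <- stats::approx(b$ep, b$beta, xout = ep_prime, rule = 2)$y
  tibble::tibble(dep = b$ep - ep_prime, dbeta = b$beta - b0)
}
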