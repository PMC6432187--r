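#' Binned weight table over potential energy
#'
#' Holds `ln W(Ep)` on a uniform energy grid. Used both for multicanonical
#' weights (`W` approximately `1 / Omega`) and for microcanonical-ensemble
#' weights. Proposals leaving the covered range `[emin, emin + nbins * de)`
#' are rejected by the sampler (out-of-range policy `"reject"`).
#'
#' @param emin Left edge of the first bin.
#' @param de Bin width (energy); default 0.5 in units of `epsilon`.
#' @param lnw Numeric vector of `ln W` per bin; `-Inf` marks forbidden bins.
#' @param meta Optional list of provenance fields (iterations, flatness...).
#' @return An object of class `weight_table`.
#' @export
weight_table <- function(emin, de, lnw, meta = list()) {
  stopifnot(de > 0, length(lnw) >= 1, !any(is.na(lnw)))
  structure(list(emin = emin, de = de, lnw = as.numeric(lnw), meta = meta),
            class = "weight_table")
}

#' @export
print.weight_table <- function(x, ...) {
  cat("<weight_table>", length(x$lnw), "bins, Ep in [",
      format(x$emin, digits = 6), ",",
      format(x$emin + length(x$lnw) * x$de, digits = 6),
      "), dE =", x$de, "\n")
  if (!is.null(x$meta$converged)) {
    cat("  converged:", x$meta$converged,
        " iterations:", x$meta$iterations,
        " flatness:", format(x$meta$flatness, digits = 3), "\n")
  }
  invisible(x)
}

#' @rdname weight_table
#' @param x A `weight_table`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.weight_table <- function(x, ...) {
  nb <- length(x$lnw)
  tibble::tibble(bin_left = x$emin + (seq_len(nb) - 1) * x$de,
                 bin_right = x$emin + seq_len(nb) * x$de,
                 ep = x$emin + (seq_len(nb) - 0.5) * x$de,
                 lnw = x$lnw)
}

#' @rdname weight_table
#' @exportS3Method generics::glance
glance.weight_table <- function(x, ...) {
  tibble::tibble(
    n_bins = length(x$lnw),
    emin = x$emin, de = x$de,
    converged = x$meta$converged %||% NA,
    iterations = x$meta$iterations %||% NA_integer_,
    flatness = x$meta$flatness %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lookup_lnw <- function(w, ep) {
  b <- floor((ep - w$emin) / w$de) + 1
  out <- rep(-Inf, length(ep))
  ok <- b >= 1 & b <= length(w$lnw)
  out[ok] <- w$lnw[b[ok]]
  out
}

derive_seed <- function(seed, k) {
  (as.numeric(seed) * 1103 + 7919 * as.numeric(k)) %% 2147483629 + 1
}

run_engine <- function(conf, spec, wtype, beta = 0, weights = NULL,
                       sweeps, discard, thin, seed, moves = NULL,
                       tune = TRUE, full_every = 5000L) {
  if (is.null(moves)) {
    moves <- move_set(spec, conf$n_chains, !is.null(conf$box))
  }
  if (is.null(weights)) {
    lnw <- 0; emin <- 0; de <- 1
  } else {
    lnw <- weights$lnw; emin <- weights$emin; de <- weights$de
  }
  res <- run_mc_cpp(conf$positions, conf$n_chains,
                    if (is.null(conf$box)) -1 else conf$box,
                    model_to_list(spec),
                    as.integer(wtype), beta, lnw, emin, de,
                    as.integer(moves$code), moves$prob, moves$amplitude,
                    as.integer(sweeps), as.integer(discard), as.integer(thin),
                    as.numeric(seed), tune, as.integer(full_every))
  series <- tibble::as_tibble(res$series)
  names(series) <- c("sweep", "ep", "elj", "ebend", "efene", "lnw",
                     "rgyr2", "ree", "cr", "gamma2")
  conf_out <- conformation(res$positions, conf$n_chains, conf$box)
  accept <- tibble::tibble(kind = moves$kind, proposed = res$proposed,
                           accepted = res$accepted,
                           rate = ifelse(res$proposed > 0,
                                         res$accepted / res$proposed, NA),
                           amplitude = res$amplitudes)
  list(series = series, conf = conf_out, hist = res$hist,
       ep_final = res$ep_final, ep_fresh = res$ep_fresh,
       max_drift = res$max_drift, acceptance = accept)
}

#' Canonical Metropolis production run
#'
#' Samples the Boltzmann distribution at temperature `T` with the
#' model-aware move set; move amplitudes are auto-tuned towards a 30-60%
#' acceptance rate during the discarded equilibration phase only, then
#' frozen (preserving detailed balance during measurement). One sweep is
#' `N * M` elementary proposals; observables are recorded every `thin`
#' sweeps.
#'
#' @param conf Starting [conformation()].
#' @param spec A [model_spec()].
#' @param temperature Dimensionless temperature `T > 0` (`kB = 1`).
#' @param sweeps Measured sweeps after the discard window.
#' @param discard Equilibration sweeps discarded before measurement.
#' @param thin Record observables every `thin` sweeps.
#' @param seed Integer RNG seed; equal seeds give bit-identical series.
#' @param moves Optional move table from [move_set()].
#' @param tune Auto-tune amplitudes during equilibration.
#' @return A list of class `mc_run`: `series` (tibble with per-measurement
#'   `ep`, `elj`, `ebend`, `efene`, `lnw = -beta * ep`, `rgyr2`, `ree`,
#'   `cr`, `gamma2`), final `conf`, `acceptance` table and the maximum
#'   drift between incremental and freshly recomputed energy.
#' @examples
#' conf <- make_fixture("rod", N = 8)
#' run <- run_canonical(conf, model_spec("bead_stick", kappa = 2),
#'                      temperature = 2, sweeps = 50, discard = 20, seed = 1)
#' head(run$series)
#' @export
run_canonical <- function(conf, spec, temperature, sweeps = 1000,
                          discard = round(sweeps / 5), thin = 1, seed = 1,
                          moves = NULL, tune = TRUE) {
  stopifnot(temperature > 0)
  e0 <- total_energy(conf, spec)
  if (!e0$finite) stop("starting conformation has non-finite energy")
  out <- run_engine(conf, spec, wtype = 0, beta = 1 / temperature,
                    sweeps = sweeps, discard = discard, thin = thin,
                    seed = seed, moves = moves, tune = tune)
  out$temperature <- temperature
  class(out) <- "mc_run"
  out
}

#' Production run under a fixed generalised weight table
#'
#' Runs a valid Markov chain with acceptance ratio `W(Ep') / W(Ep)` for a
#' frozen [weight_table()] (multicanonical or microcanonical weights) and
#' accumulates the per-sweep visit histogram on the table's bins.
#'
#' @inheritParams run_canonical
#' @param weights A [weight_table()].
#' @return A list of class `mc_run` as for [run_canonical()], with `hist`
#'   (per-sweep visit counts on the weight-table bins) and per-sample
#'   `lnw` equal to the table lookup of each `ep`.
#' @export
run_weighted <- function(conf, spec, weights, sweeps = 1000,
                         discard = round(sweeps / 5), thin = 1, seed = 1,
                         moves = NULL, tune = TRUE) {
  e0 <- total_energy(conf, spec)
  if (!e0$finite) stop("starting conformation has non-finite energy")
  out <- run_engine(conf, spec, wtype = 1, weights = weights,
                    sweeps = sweeps, discard = discard, thin = thin,
                    seed = seed, moves = moves, tune = tune)
  out$weights <- weights
  class(out) <- "mc_run"
  out
}

#' @export
print.mc_run <- function(x, ...) {
  cat("<mc_run>", nrow(x$series), "measurements\n")
  print(x$acceptance)
  invisible(x)
}

flatness_of <- function(hist) {
  if (all(hist == 0)) return(0)
  min(hist) / mean(hist)
}

#' Iterate multicanonical weights to a flat energy histogram
#'
#' Approximates the inverse conformational density of states iteratively:
#' starting from flat weights, each iteration runs the sampler under the
#' current table and updates `ln W <- ln W - ln H` on visited bins
#' (carry-forward for unvisited bins, optional 3-bin moving-average
#' smoothing of the update). Convergence is declared when the per-sweep
#' visit histogram satisfies `min / mean >= flat` over the covered range.
#'
#' The energy range is bracketed by short canonical pilot runs at the
#' temperature extremes `t_bracket` (the low-T pilot is annealed through a
#' short temperature ladder), unless `ebounds` is given explicitly.
#'
#' @param conf Starting [conformation()].
#' @param spec A [model_spec()].
#' @param ebounds Optional explicit `c(ep_min, ep_max)`.
#' @param de Energy bin width; default `0.5` (units of `epsilon`).
#' @param t_bracket Temperatures of the high-/low-T pilot runs.
#' @param pilot_sweeps Sweeps per pilot stage.
#' @param iter_sweeps Sweeps of the first iteration; grows by `growth`
#'   each iteration.
#' @param growth Multiplicative sweep growth per iteration.
#' @param max_sweeps Cap on per-iteration sweeps; once reached,
#'   iterations repeat at the cap (the accumulated recursion keeps
#'   improving) instead of growing without bound.
#' @param max_iter Maximum number of iterations.
#' @param flat Flatness threshold `min/mean` (default 0.5).
#' @param smooth Apply 3-bin moving-average smoothing to the `ln H` update.
#' @param seed Integer seed; pilot and iteration seeds are derived from it.
#' @param walkers Number of independent walkers whose histograms are
#'   summed before each weight update (1 = serial algorithm).
#' @param extra_starts Optional list of additional starting
#'   conformations (e.g. a folded hairpin for stiff chains): each is
#'   annealed at the low-temperature end to extend the energy bracket
#'   into basins the main annealing path cannot reach across a
#'   free-energy barrier, and then seeds one extra walker there.
#' @return A [weight_table()] whose `meta` records `converged`, `flatness`,
#'   `iterations`, a per-iteration `diagnostics` tibble, the final
#'   production-ready conformation(s) `conf` and the bin histogram of the
#'   last iteration.
#' @export
iterate_muca_weights <- function(conf, spec, ebounds = NULL, de = 0.5,
                                 t_bracket = c(0.1, 5), pilot_sweeps = 2000,
                                 iter_sweeps = 5000, growth = 1.3,
                                 max_sweeps = 20 * iter_sweeps,
                                 max_iter = 30, flat = 0.5, smooth = TRUE,
                                 seed = 1, walkers = 1, extra_starts = list()) {
  t_lo <- min(t_bracket); t_hi <- max(t_bracket)
  if (is.null(ebounds)) {
    hi <- run_canonical(conf, spec, t_hi, sweeps = pilot_sweeps,
                        discard = pilot_sweeps %/% 4, seed = derive_seed(seed, 1))
    # anneal towards the low-T pilot so the bracket reaches collapsed energies
    ladder <- exp(seq(log(t_hi), log(t_lo), length.out = 5))
    cc <- hi$conf
    emin_seen <- Inf
    for (k in seq_along(ladder)) {
      lo <- run_canonical(cc, spec, ladder[k], sweeps = pilot_sweeps,
                          discard = pilot_sweeps %/% 4,
                          seed = derive_seed(seed, 10 + k))
      cc <- lo$conf
      emin_seen <- min(emin_seen, min(lo$series$ep))
    }
    # additional starting structures (e.g. a folded hairpin for stiff
    # chains) extend the bracket into basins a single annealing path may
    # not reach across a first-order barrier
    extra_confs <- list()
    for (k in seq_along(extra_starts)) {
      ex <- run_canonical(extra_starts[[k]], spec, t_lo,
                          sweeps = pilot_sweeps,
                          discard = pilot_sweeps %/% 4,
                          seed = derive_seed(seed, 30 + k))
      emin_seen <- min(emin_seen, min(ex$series$ep))
      extra_confs[[k]] <- ex$conf
    }
    # high edge from the typical high-T energies, not the extreme outlier
    emax <- mean(hi$series$ep) + 3 * stats::sd(hi$series$ep) + 2 * de
    emin <- emin_seen - 2 * de
    start_conf <- hi$conf
  } else {
    emin <- ebounds[1]; emax <- ebounds[2]
    start_conf <- conf
    extra_confs <- list()
  }
  nb <- max(3L, ceiling((emax - emin) / de))
  w <- weight_table(emin, de, rep(0, nb))
  G <- rep(0, nb - 1)  # accumulated pair statistics of the recursion

  confs <- rep(list(start_conf), walkers)
  # walkers seeded in the basins of the extra starting structures let the
  # recursion estimate adjacent-bin ratios on both sides of a barrier
  # before any single walker has crossed it
  confs <- c(confs, extra_confs)
  walkers <- length(confs)
  diag_rows <- list()
  sw <- iter_sweeps
  converged <- FALSE
  flatn <- 0
  hist_total <- rep(0, nb)
  for (it in seq_len(max_iter)) {
    hist_total <- rep(0, nb)
    for (wk in seq_len(walkers)) {
      run <- run_weighted(confs[[wk]], spec, w, sweeps = round(sw),
                          discard = round(sw / 5), thin = 0,
                          seed = derive_seed(seed, 100 * it + wk),
                          tune = (it <= 2))
      confs[[wk]] <- run$conf
      hist_total <- hist_total + run$hist
    }
    flatn <- flatness_of(hist_total)
    visited <- hist_total > 0
    # accumulated (error-weighted) recursion on adjacent-bin ratios:
    # each pair contributes with statistical weight g = h0 h1 / (h0 + h1),
    # accumulated over iterations, so noisy single-iteration histograms
    # cannot overwrite well-determined parts of the weight function.
    dw <- diff(w$lnw)
    h0 <- hist_total[-nb]; h1 <- hist_total[-1]
    g <- ifelse(h0 > 0 & h1 > 0, h0 * h1 / (h0 + h1), 0)
    upd_idx <- which(g > 0)
    if (length(upd_idx) > 0) {
      Gnew <- G[upd_idx] + g[upd_idx]
      dw[upd_idx] <- dw[upd_idx] -
        (g[upd_idx] / Gnew) * log(h1[upd_idx] / h0[upd_idx])
      G[upd_idx] <- Gnew
    }
    if (smooth && length(dw) >= 3) {
      sm <- stats::filter(dw, rep(1 / 3, 3), sides = 2)
      keep <- !is.na(sm) & c(g > 0)
      dw[keep] <- sm[keep]
    }
    w$lnw <- cumsum(c(0, dw))
    w$lnw <- w$lnw - max(w$lnw)
    diag_rows[[it]] <- tibble::tibble(iteration = it, sweeps = round(sw),
                                      flatness = flatn,
                                      frac_visited = mean(visited))
    # require two consecutive flat iterations so a lucky histogram cannot
    # end the recursion on weights that are still rough near the edges
    if (flatn >= flat && it > 1 && diag_rows[[it - 1]]$flatness >= flat) {
      converged <- TRUE
      break
    }
    sw <- min(sw * growth, max_sweeps)
  }
  w$meta <- list(converged = converged, flatness = flatn,
                 pair_stats = G,
                 iterations = length(diag_rows),
                 diagnostics = dplyr::bind_rows(diag_rows),
                 conf = if (walkers == 1) confs[[1]] else confs,
                 hist = hist_total)
  if (!converged) {
    warning("multicanonical weights not converged after ", max_iter,
            " iterations (flatness ", format(flatn, digits = 3), ")")
  }
  w
}

#' Parallel multicanonical weight iteration
#'
#' Convenience wrapper around [iterate_muca_weights()] with `walkers > 1`:
#' per-iteration histograms of independent walkers (one seeded RNG each)
#' are summed before the mutual weight update, which is statistically
#' equivalent to the serial scheme and converges in at most as many
#' iterations. Walkers only communicate through the summed histogram at
#' iteration boundaries.
#'
#' @inheritParams iterate_muca_weights
#' @param walkers Number of independent walkers.
#' @return A [weight_table()], as for [iterate_muca_weights()].
#' @export
parallel_muca <- function(conf, spec, walkers = 4, ...) {
  iterate_muca_weights(conf, spec, walkers = walkers, ...)
}

#' Microcanonical-ensemble weight
#'
#' `W(Ep) = (E - Ep)^((Ndof - 2) / 2)` for total energy `E`: the kinetic
#' energy acts as a finite reservoir, in contrast to the infinite heat
#' bath of the canonical ensemble. Zero for `Ep >= E` (move rejection).
#'
#' @param ep Potential energy (vectorised).
#' @param e_total Fixed total energy `E`.
#' @param ndof Momentum-space degrees of freedom (`3 N` for `N` free
#'   particles).
#' @return The weight (not its logarithm).
#' @examples
#' microcanonical_weight(0, e_total = 2, ndof = 4)  # exponent 1 -> 2
#' @export
microcanonical_weight <- function(ep, e_total, ndof) {
  ifelse(ep < e_total, (e_total - ep)^((ndof - 2) / 2), 0)
}

#' Microcanonical weight table
#'
#' Discretises [microcanonical_weight()] onto a uniform energy grid for
#' use with [run_weighted()]. Bins at or above `e_total` get `-Inf`
#' (forbidden).
#'
#' @param e_total Fixed total energy.
#' @param ndof Momentum degrees of freedom.
#' @param emin Lower edge of the table.
#' @param de Bin width.
#' @param n_bins Number of bins.
#' @return A [weight_table()].
#' @export
nve_weight_table <- function(e_total, ndof, emin, de = 0.5,
                             n_bins = ceiling((e_total - emin) / de)) {
  centers <- emin + (seq_len(n_bins) - 0.5) * de
  lnw <- rep(-Inf, n_bins)
  ok <- centers < e_total
  lnw[ok] <- 0.5 * (ndof - 2) * log(e_total - centers[ok])
  weight_table(emin, de, lnw, meta = list(e_total = e_total, ndof = ndof))
}

#' Parallel tempering across a temperature ladder
#'
#' Runs one canonical replica per temperature and attempts neighbour
#' configuration swaps every `swap_every` sweeps with acceptance
#' `min(1, exp((beta_i - beta_j)(Ep_i - Ep_j)))`, which leaves the joint
#' Boltzmann ensemble invariant. With swaps disabled the replicas are
#' independent canonical runs.
#'
#' @param conf Starting [conformation()] (copied to every replica).
#' @param spec A [model_spec()].
#' @param temperatures Increasing temperature ladder.
#' @param sweeps Measured sweeps per replica.
#' @param swap_every Sweeps between swap attempts; `Inf` disables swaps.
#' @param discard Equilibration sweeps before measurements begin.
#' @param thin Measurement interval in sweeps.
#' @param seed Integer seed.
#' @return A list with `series` (tibble with a `temperature` column),
#'   and `swaps` (per-pair attempt/accept counts).
#' @export
parallel_tempering <- function(conf, spec, temperatures, sweeps = 1000,
                               swap_every = 10, discard = round(sweeps / 5),
                               thin = 1, seed = 1) {
  nr <- length(temperatures)
  stopifnot(nr >= 2)
  betas <- 1 / temperatures
  confs <- rep(list(conf), nr)
  eps <- vapply(seq_len(nr), function(i) total_energy(conf, spec)$ep, numeric(1))
  segments <- if (is.finite(swap_every)) swap_every else sweeps
  n_seg_discard <- ceiling(discard / segments)
  n_seg <- n_seg_discard + ceiling(sweeps / segments)
  swap_att <- rep(0, nr - 1); swap_acc <- rep(0, nr - 1)
  series <- vector("list", nr * n_seg)
  set.seed(derive_seed(seed, 0))
  idx <- 1
  for (sg in seq_len(n_seg)) {
    measuring <- sg > n_seg_discard
    for (i in seq_len(nr)) {
      run <- run_engine(confs[[i]], spec, wtype = 0, beta = betas[i],
                        sweeps = segments,
                        discard = if (sg == 1) round(segments / 2) else 0,
                        thin = if (measuring) thin else 0,
                        seed = derive_seed(seed, 1000 * sg + i),
                        tune = (sg == 1))
      confs[[i]] <- run$conf
      eps[i] <- run$ep_final
      if (measuring && nrow(run$series) > 0) {
        s <- run$series
        s$sweep <- s$sweep + (sg - n_seg_discard - 1) * segments
        s$temperature <- temperatures[i]
        s$replica <- i
        series[[idx]] <- s
        idx <- idx + 1
      }
    }
    if (is.finite(swap_every)) {
      start <- if (sg %% 2 == 1) 1 else 2
      if (start > nr - 1) next
      for (i in seq(start, nr - 1, by = 2)) {
        swap_att[i] <- swap_att[i] + 1
        lacc <- (betas[i] - betas[i + 1]) * (eps[i] - eps[i + 1])
        if (lacc >= 0 || log(stats::runif(1)) < lacc) {
          tmp <- confs[[i]]; confs[[i]] <- confs[[i + 1]]; confs[[i + 1]] <- tmp
          tmpe <- eps[i]; eps[i] <- eps[i + 1]; eps[i + 1] <- tmpe
          swap_acc[i] <- swap_acc[i] + 1
        }
      }
    }
  }
  list(series = dplyr::bind_rows(series[seq_len(idx - 1)]),
       swaps = tibble::tibble(pair = seq_len(nr - 1),
                              t_low = temperatures[-nr],
                              t_high = temperatures[-1],
                              attempted = swap_att, accepted = swap_acc,
                              rate = ifelse(swap_att > 0,
                                            swap_acc / swap_att, NA)))
}
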