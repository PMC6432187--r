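#' Read and materialise a run configuration
#'
#' Run configurations are YAML files holding the model choice and
#' parameters, system size (`N`, `M`, density or box edge), ensemble,
#' temperature / stiffness grids, sweep counts and seeds. All defaults
#' are filled in ("materialised") so that the returned object — and the
#' copy written next to the outputs — records every value actually used.
#'
#' @param path YAML file.
#' @return A named list of class `run_config` with every field populated.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  materialise_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A (possibly partial) configuration list.
#' @export
materialise_config <- function(cfg = list()) {
  defaults <- list(
    model = "bead_spring", kappa = 0, epsilon = 1, N = 13, M = 1,
    rho = NULL, box = NULL, ensemble = "canonical",
    temperature = 1, t_grid = NULL,
    sweeps = 10000, discard = 2000, thin = 1, seed = 1, walkers = 1,
    de = 0.5, t_bracket = c(0.1, 5), start = "coil",
    output = "run")
  out <- utils::modifyList(defaults, cfg)
  # modifyList drops NULL-valued entries; keep every field present so a
  # materialised configuration always lists all keys
  for (nm in setdiff(names(defaults), names(out))) out[nm] <- list(NULL)
  out <- out[union(names(defaults), names(out))]
  if (!is.null(out$rho) && is.null(out$box)) {
    out$box <- box_from_density(out$N, out$M, out$rho)
  }
  class(out) <- c("run_config", "list")
  out
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

config_spec <- function(config) {
  model_spec(config$model, kappa = config$kappa, epsilon = config$epsilon)
}

config_start_conf <- function(config, spec) {
  s <- bond_length(spec)
  if (config$M > 1) {
    make_fixture("random-bundle", N = config$N, M = config$M, spacing = s,
                 box = config$box, seed = config$seed)
  } else {
    make_fixture("coil", N = config$N, spacing = s, box = config$box,
                 seed = config$seed)
  }
}

#' Run a simulation described by a configuration
#'
#' Dispatches on `config$ensemble`: `"canonical"` (Metropolis at
#' `config$temperature`), `"muca"` (weight iteration followed by a
#' flat-histogram production run) or `"nve"` (microcanonical weights at
#' total energy `config$e_total` with `Ndof = 3 N M`).
#'
#' @param config A [read_run_config()] result (or list passed through
#'   [materialise_config()]).
#' @return An `mc_run` (canonical/nve) or a list with `weights` and
#'   `production` (muca).
#' @export
run_simulation <- function(config) {
  config <- materialise_config(unclass(config))
  spec <- config_spec(config)
  conf <- config_start_conf(config, spec)
  if (config$ensemble == "canonical") {
    run_canonical(conf, spec, config$temperature, sweeps = config$sweeps,
                  discard = config$discard, thin = config$thin,
                  seed = config$seed)
  } else if (config$ensemble == "muca") {
    w <- iterate_muca_weights(conf, spec, de = config$de,
                              t_bracket = config$t_bracket,
                              seed = config$seed, walkers = config$walkers)
    start <- if (inherits(w$meta$conf, "polymer_conf")) {
      w$meta$conf
    } else {
      w$meta$conf[[1]]
    }
    prod <- run_weighted(start, spec, w,
                         sweeps = config$sweeps,
                         discard = config$discard, thin = config$thin,
                         seed = derive_seed(config$seed, 999))
    list(weights = w, production = prod)
  } else if (config$ensemble == "nve") {
    stopifnot(!is.null(config$e_total))
    e0 <- total_energy(conf, spec)$ep
    w <- nve_weight_table(config$e_total, 3 * config$N * config$M,
                          emin = min(e0, 0) - 50 * config$de,
                          de = config$de)
    run_weighted(conf, spec, w, sweeps = config$sweeps,
                 discard = config$discard, thin = config$thin,
                 seed = config$seed)
  } else {
    stop("unknown ensemble: ", config$ensemble)
  }
}

#' Stiffness-temperature phase-diagram scan
#'
#' For every stiffness `kappa` on the grid: iterate multicanonical
#' weights, run flat-histogram production, reweight the specific heat
#' and the thermal derivatives of `Rgyr^2` (and, for multi-chain systems,
#' `Gamma2` and its derivative) onto the temperature grid, and collect
#' peak positions. Peak lines over `(kappa, T)` trace the collapse /
#' folding / aggregation transitions; the background observable
#' (`<Rgyr^2>` single chain, `<CR>` multi-chain) fills in the structural
#' map. Unconverged weight iterations are flagged and the scan continues.
#'
#' @param base_spec A [model_spec()] whose `kappa` is overridden per grid
#'   point.
#' @param N,M Beads per chain and number of chains.
#' @param kappa_grid Stiffness values.
#' @param t_grid Temperatures for the reweighted curves.
#' @param rho Density (sets the box for `M > 1`).
#' @param sweeps Production sweeps per stiffness.
#' @param seed Integer seed.
#' @param ... Passed to [iterate_muca_weights()].
#' @return A list with `peaks` (tibble: `kappa`, `t_peak`, `observable`,
#'   `height`, `converged`), `background` (tibble: `kappa`,
#'   `temperature`, observable columns) and `runs` (per-kappa diagnostics).
#' @export
scan_phase_diagram <- function(base_spec, N, M = 1, kappa_grid, t_grid,
                               rho = NULL, sweeps = 20000, seed = 1, ...) {
  boxL <- if (M > 1) box_from_density(N, M, rho) else NULL
  peaks <- list(); bg <- list(); runs <- list()
  for (ik in seq_along(kappa_grid)) {
    kap <- kappa_grid[ik]
    spec <- base_spec
    spec$kappa <- kap
    s <- bond_length(spec)
    conf <- if (M > 1) {
      make_fixture("random-bundle", N = N, M = M, spacing = s, box = boxL,
                   seed = derive_seed(seed, ik))
    } else {
      make_fixture("coil", N = N, spacing = s, seed = derive_seed(seed, ik))
    }
    w <- iterate_muca_weights(conf, spec, seed = derive_seed(seed, 50 + ik),
                              ...)
    start <- if (is.list(w$meta$conf) && !inherits(w$meta$conf,
                                                   "polymer_conf")) {
      w$meta$conf[[1]]
    } else {
      w$meta$conf
    }
    prod <- run_weighted(start, spec, w, sweeps = sweeps,
                         discard = round(sweeps / 10),
                         seed = derive_seed(seed, 90 + ik))
    series <- prod$series
    cv <- specific_heat(series, t_grid)
    drg <- thermal_derivative(series, temperature = t_grid,
                              observables = "rgyr2")
    curves <- list(cv = cv$cv, drgyr2_dt = drg$dvalue_dt)
    if (M > 1) {
      dg2 <- thermal_derivative(series, temperature = t_grid,
                                observables = "gamma2")
      g2 <- reweight(series, temperature = t_grid, observables = "gamma2")
      curves$dgamma2_dt <- dg2$dvalue_dt
      curves$gamma2 <- g2$value
    }
    for (ob in names(curves)) {
      pk <- scan_peaks(t_grid, curves[[ob]])
      if (nrow(pk) > 0) {
        peaks[[length(peaks) + 1]] <- tibble::tibble(
          kappa = kap, t_peak = pk$x, observable = ob, height = pk$y,
          converged = w$meta$converged)
      }
    }
    bg_obs <- if (M > 1) c("rgyr2", "cr") else "rgyr2"
    rw <- reweight(series, temperature = t_grid, observables = bg_obs)
    bg[[ik]] <- dplyr::mutate(
      tidyr::pivot_wider(rw[, c("temperature", "observable", "value")],
                         names_from = "observable",
                         values_from = "value"),
      kappa = kap, .before = 1)
    runs[[ik]] <- tibble::tibble(kappa = kap,
                                 converged = w$meta$converged,
                                 flatness = w$meta$flatness,
                                 iterations = w$meta$iterations)
  }
  list(peaks = dplyr::bind_rows(peaks), background = dplyr::bind_rows(bg),
       runs = dplyr::bind_rows(runs))
}

#' Scaled-down stiffness crossover of the collapse transition
#'
#' Runs the multicanonical weight iteration for a single bead-spring
#' chain at each requested stiffness and classifies the collapse
#' transition from the resulting entropy estimate: negative `gamma(Ep)`
#' peaks mark a continuous (second-order-like) collapse, back-bending of
#' `beta(Ep)` (a positive `gamma` peak) a discontinuous
#' (first-order-like) folding transition. The sign change locates the
#' crossover stiffness.
#'
#' Classification uses the accumulated-weight entropy estimator
#' `ln Omega = -ln W` of the converged recursion, which precision-weights
#' every iteration's histogram and is therefore the lowest-noise
#' desk-scale estimate; a separate production run (`sweeps > 0`) is used
#' only to record the realised flatness as a diagnostic.
#'
#' @param kappas Stiffness values to probe.
#' @param N Chain length (default 40, the bead-spring reference chain).
#' @param sweeps Production sweeps for the flatness diagnostic
#'   (0 skips it).
#' @param t_bracket Pilot temperature bracket for the weight iteration.
#' @param seed Integer seed.
#' @param smooth_sigma Smoothing passed to [micro_beta_gamma()].
#' @param ... Passed to [iterate_muca_weights()].
#' @return A tibble with `kappa`, `gamma_peak`, `ep_prime`, `order`,
#'   `converged`, `prod_flatness`.
#' @export
gamma_peak_scan <- function(kappas, N = 40, sweeps = 0,
                            t_bracket = c(0.25, 1.2), seed = 1,
                            smooth_sigma = 2, ...) {
  purrr::map_dfr(kappas, function(kap) {
    spec <- model_spec("bead_spring", kappa = kap)
    conf <- make_fixture("coil", N = N, spacing = spec$r0,
                         seed = derive_seed(seed, round(10 * kap)))
    # a hairpin pilot lets the energy bracket reach the folded basin of
    # stiff chains, which lies across a free-energy barrier
    hairpin <- make_fixture("hairpin", N = N, spacing = spec$r0)
    w <- iterate_muca_weights(conf, spec, t_bracket = t_bracket,
                              extra_starts = list(hairpin),
                              seed = derive_seed(seed, round(100 * kap) + 1),
                              ...)
    pf <- NA_real_
    if (sweeps > 0) {
      start <- if (inherits(w$meta$conf, "polymer_conf")) {
        w$meta$conf
      } else {
        w$meta$conf[[1]]
      }
      prod <- run_weighted(start, spec, w, sweeps = sweeps,
                           discard = round(sweeps / 10), thin = 5,
                           seed = derive_seed(seed, round(100 * kap) + 2))
      pf <- min(prod$hist) / mean(prod$hist)
    }
    dos <- dos_from_weights(w, rep(1, length(w$lnw)))
    # mask bins whose adjacent-bin ratios never accumulated enough
    # statistics: their carried-forward weights would fake features
    G <- w$meta$pair_stats
    nb <- length(w$lnw)
    rel <- c(G[1] >= 200, G[-1] >= 200 | G[-(nb - 1)] >= 200,
             G[nb - 1] >= 200)
    dos$bins$ln_omega[!rel] <- NA_real_
    prof <- micro_beta_gamma(dos, smooth_sigma = smooth_sigma)
    cls <- classify_transition(prof)
    tibble::tibble(kappa = kap, gamma_peak = cls$gamma_peak,
                   ep_prime = cls$ep_prime, order = cls$order,
                   converged = w$meta$converged, prod_flatness = pf)
  })
}
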