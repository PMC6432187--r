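#' Monte Carlo move set
#'
#' Builds the model-aware move mixture. All proposals are symmetric
#' (Hastings ratio 1): local displacements are uniform in a cube,
#' crankshaft and pivot rotation angles uniform in `[-amplitude, amplitude]`
#' with the rotation axis uniform on the sphere, and chain translations
#' place the chain's centre of mass uniformly in the box.
#'
#' The bead-stick model forbids local displacements (they would violate
#' the rigid bonds); its local move is the crankshaft rotation about the
#' axis joining the neighbours of the chosen bead (end beads rotate about
#' a random axis through their single neighbour). The default mixture is
#' crankshaft/local 0.6, pivot 0.4 for a single chain; multi-chain systems
#' in a box add chain translation with weight 0.2 (renormalised).
#'
#' @param spec A [model_spec()].
#' @param n_chains Number of chains.
#' @param boxed Whether a periodic box is present.
#' @param amplitudes Optional named numeric vector overriding default move
#'   amplitudes (names among `"local"`, `"crankshaft"`, `"pivot"`).
#' @return A tibble with columns `kind`, `code`, `prob`, `amplitude`.
#' @export
move_set <- function(spec, n_chains = 1, boxed = FALSE, amplitudes = NULL) {
  local_kind <- if (spec$kind == "bead_spring") "local" else "crankshaft"
  kinds <- c(local_kind, "pivot")
  probs <- c(0.6, 0.4)
  if (n_chains > 1 && boxed) {
    kinds <- c(kinds, "translation")
    probs <- c(probs * (1 - 0.2), 0.2)
  }
  amp_default <- c(local = 0.3 * spec$sigma, crankshaft = 1.0,
                   pivot = 1.0, translation = 0)
  amp <- amp_default[kinds]
  if (!is.null(amplitudes)) {
    for (nm in names(amplitudes)) {
      amp[kinds == nm] <- amplitudes[[nm]]
    }
  }
  codes <- c(local = 0L, crankshaft = 1L, pivot = 2L, translation = 3L)
  tibble::tibble(kind = kinds, code = unname(codes[kinds]),
                 prob = probs / sum(probs), amplitude = unname(amp))
}

#' Propose a single Monte Carlo move
#'
#' Generates one trial update of the given kind and returns the minimal
#' changed-bead set. Mainly useful for testing move geometry; the
#' production samplers run the same proposal code inside the compiled
#' loop.
#'
#' @param conf A [conformation()].
#' @param spec A [model_spec()].
#' @param kind One of `"local"`, `"crankshaft"`, `"pivot"`, `"translation"`.
#' @param amplitude Move amplitude (length for displacements, radians for
#'   rotations; ignored for translations).
#' @param seed Integer seed for the proposal RNG (deterministic).
#' @return A list with `ok`, bead index range `lo:hi`, the proposed
#'   coordinates `newpos`, and `symmetric = TRUE`.
#' @export
propose <- function(conf, spec, kind, amplitude = 0.5, seed = 1) {
  codes <- c(local = 0L, crankshaft = 1L, pivot = 2L, translation = 3L)
  stopifnot(kind %in% names(codes))
  if (kind == "local" && spec$kind == "bead_stick") {
    stop("local displacement is forbidden for the bead-stick model")
  }
  propose_move_cpp(conf$positions, conf$n_chains,
                   if (is.null(conf$box)) -1 else conf$box,
                   model_to_list(spec), codes[[kind]], amplitude, seed)
}

#' Metropolis acceptance decision
#'
#' Canonical mode accepts with probability `min(1, exp(-beta * delta_ep))`;
#' generalised mode accepts with `min(1, W(Ep') / W(Ep))` using a binned
#' weight table. Non-finite energy increases are always rejected
#' (infinite-energy sentinel).
#'
#' @param delta_ep Proposed energy change.
#' @param beta Inverse temperature (canonical mode).
#' @param weights A [weight_table()] (generalised mode).
#' @param ep_old Current energy (required in generalised mode).
#' @param u Uniform random number in `[0, 1)`; supplied for determinism in
#'   tests, drawn from the session RNG otherwise.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_ep, beta = NULL, weights = NULL,
                              ep_old = NULL, u = stats::runif(1)) {
  if (is.na(delta_ep) || delta_ep == Inf) return(FALSE)
  if (!is.null(weights)) {
    stopifnot(!is.null(ep_old))
    lw0 <- lookup_lnw(weights, ep_old)
    lw1 <- lookup_lnw(weights, ep_old + delta_ep)
    if (!is.finite(lw1)) return(FALSE)
    lacc <- lw1 - lw0
  } else {
    stopifnot(!is.null(beta))
    lacc <- -beta * delta_ep
  }
  lacc >= 0 || (u > 0 && log(u) < lacc)
}
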