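#' Interaction model for coarse-grained polymer chains
#'
#' Defines the two supported chain models and all interaction parameters.
#' Energies are in units of the Lennard-Jones well depth `epsilon`,
#' lengths in units of the LJ length `sigma`, and `kB = 1` so temperature
#' is dimensionless.
#'
#' The **bead-stick** model has rigid bonds of length `rb = 1` and
#' `sigma = epsilon = 1`; all non-bonded bead pairs interact through the
#' truncated and shifted Lennard-Jones potential. The **bead-spring**
#' model bonds beads with the finitely-extensible nonlinear elastic (FENE)
#' potential (`r0 = 0.7`, `R = 0.3`, `K = 40`, `sigma = 2^(-1/6) * r0`)
#' and applies the LJ attraction only between non-bonded monomers.
#' In both models the LJ potential is cut off and shifted at `rc = 2.5 sigma`
#' and semiflexibility enters through the worm-like-chain bending penalty
#' `kappa * (1 - cos(theta))` at every interior bond angle.
#'
#' Bonded pairs are excluded from the LJ sum in *both* models. For the
#' bead-stick model (where bonded pairs sit at the fixed distance `rb`)
#' this differs from the all-pairs convention only by the constant
#' `(N - 1) * lj_pair_energy(rb)` per chain, which cancels in all sampling
#' and analysis.
#'
#' @param kind `"bead_stick"` or `"bead_spring"`.
#' @param kappa Bending stiffness (energy units). Default 0 (fully flexible).
#' @param epsilon LJ energy scale.
#' @param sigma LJ length scale; defaults to 1 (bead-stick) or
#'   `2^(-1/6) * r0` (bead-spring).
#' @param rc LJ cutoff radius; default `2.5 * sigma`.
#' @param rb Fixed bond length (bead-stick only).
#' @param K FENE spring constant (bead-spring only).
#' @param R FENE half-width (bead-spring only).
#' @param r0 FENE equilibrium bond length (bead-spring only).
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("bead_spring", kappa = 4)
#' @export
model_spec <- function(kind = c("bead_stick", "bead_spring"), kappa = 0,
                       epsilon = 1, sigma = NULL, rc = NULL,
                       rb = 1, K = 40, R = 0.3, r0 = 0.7) {
  kind <- match.arg(kind)
  if (is.null(sigma)) {
    sigma <- if (kind == "bead_spring") 2^(-1 / 6) * r0 else 1
  }
  if (is.null(rc)) rc <- 2.5 * sigma
  stopifnot(epsilon > 0, sigma > 0, rc > sigma, kappa >= 0)
  if (kind == "bead_spring") stopifnot(K > 0, R > 0, r0 > R)
  spec <- list(kind = kind, kappa = kappa, epsilon = epsilon, sigma = sigma,
               rc = rc, rb = rb, K = K, R = R, r0 = r0)
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$kind, "\n")
  cat("  epsilon =", x$epsilon, " sigma =", format(x$sigma, digits = 6),
      " rc =", format(x$rc, digits = 6), " kappa =", x$kappa, "\n")
  if (x$kind == "bead_spring") {
    cat("  FENE: K =", x$K, " R =", x$R, " r0 =", x$r0, "\n")
  } else {
    cat("  rigid bonds: rb =", x$rb, "\n")
  }
  invisible(x)
}

#' Equilibrium bond length of a model
#'
#' `rb` for the bead-stick model, `r0` for the bead-spring model.
#' @param spec A [model_spec()].
#' @return A length.
#' @export
bond_length <- function(spec) {
  if (spec$kind == "bead_spring") spec$r0 else spec$rb
}

#' Truncated and shifted Lennard-Jones pair energy
#'
#' `4 epsilon ((sigma/r)^12 - (sigma/r)^6) - V(rc)` for r below the cutoff, zero
#' beyond the cutoff; continuous at `rc`.
#'
#' @param r Pair distance(s), strictly positive.
#' @param spec A [model_spec()].
#' @return Energy, vectorised over `r`.
#' @examples
#' spec <- model_spec("bead_stick")
#' lj_pair_energy(2^(1 / 6), spec)  # close to -1 (minimum, minus the shift)
#' @export
lj_pair_energy <- function(r, spec) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("pair distance must be finite and positive")
  }
  sr6 <- (spec$sigma / r)^6
  src6 <- (spec$sigma / spec$rc)^6
  shift <- 4 * spec$epsilon * (src6^2 - src6)
  ifelse(r < spec$rc, 4 * spec$epsilon * (sr6^2 - sr6) - shift, 0)
}

#' Worm-like-chain bending energy
#'
#' `kappa * (1 - cos(theta))` for the angle `theta` between successive
#' bonds; zero for a straight chain, maximal (`2 kappa`) for a full
#' back-fold.
#'
#' @param theta Bond angle(s) in radians, in `[0, pi]`.
#' @param kappa Bending stiffness.
#' @return Energy, vectorised over `theta`.
#' @export
bend_energy <- function(theta, kappa) {
  ct <- pmin(1, pmax(-1, cos(theta)))
  kappa * (1 - ct)
}

#' FENE bond energy
#'
#' `-(K/2) R^2 log(1 - ((r - r0)/R)^2)`, defined on the open interval
#' `(r0 - R, r0 + R)`; zero at `r0` and divergent at the bounds. Outside
#' the interval an infinite-energy sentinel (`Inf`) is returned so the
#' sampler rejects the move rather than erroring.
#'
#' @param r Bond distance(s).
#' @param spec A [model_spec()] of kind `"bead_spring"`.
#' @return Energy, vectorised over `r`; `Inf` outside the admissible range.
#' @export
fene_bond_energy <- function(r, spec) {
  x <- (r - spec$r0) / spec$R
  arg <- 1 - x^2
  ifelse(arg > 0, -0.5 * spec$K * spec$R^2 * log(arg), Inf)
}

#' Minimal-image displacement
#'
#' Maps each component of a displacement vector into `[-L/2, L/2)`.
#' Used for inter-chain pair distances and the phase-separation
#' parameter only; bond vectors never use the minimal image.
#'
#' @param delta Numeric vector or matrix of displacement components.
#' @param L Cubic box edge, `L > 0`.
#' @return Object of the same shape as `delta`.
#' @examples
#' minimal_image(c(0.9, 0, 0), L = 1)  # -0.1, 0, 0
#' @export
minimal_image <- function(delta, L) {
  stopifnot(L > 0)
  delta - L * floor(delta / L + 0.5)
}

#' Box edge from number density
#'
#' `L = (N M / rho)^(1/3)` for `M` chains of `N` beads at density
#' `rho = N M / V` in a cubic box of volume `V = L^3`.
#'
#' @param N Beads per chain.
#' @param M Number of chains.
#' @param rho Number density.
#' @return The box edge `L`.
#' @examples
#' box_from_density(13, 4, 1e-3)
#' @export
box_from_density <- function(N, M, rho) {
  stopifnot(N >= 1, M >= 1, rho > 0)
  (N * M / rho)^(1 / 3)
}

#' Polymer conformation
#'
#' A set of `M` chains of `N` beads each. Positions are stored unwrapped;
#' when a periodic box is present, only inter-chain distances use the
#' minimal-image convention (valid while each chain's extent stays below
#' `L / 2`, which the samplers rely on in the dilute regime).
#'
#' @param positions Numeric matrix, `N * M` rows by 3 columns.
#' @param n_chains Number of chains `M`; beads `((c-1)N + 1) : (cN)` belong
#'   to chain `c`.
#' @param box Cubic box edge `L`, or `NULL` for an isolated system.
#' @return An object of class `polymer_conf`.
#' @export
conformation <- function(positions, n_chains = 1, box = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) %% n_chains == 0,
            all(is.finite(positions)))
  if (!is.null(box)) stopifnot(box > 0)
  structure(
    list(positions = unname(positions), n_chains = as.integer(n_chains),
         n_beads = as.integer(nrow(positions) / n_chains),
         box = box),
    class = "polymer_conf")
}

#' @export
print.polymer_conf <- function(x, ...) {
  cat("<polymer_conf> M =", x$n_chains, "chains x N =", x$n_beads, "beads")
  if (!is.null(x$box)) cat("  box L =", format(x$box, digits = 6))
  cat("\n")
  invisible(x)
}

#' Check conformation bond invariants
#'
#' Bead-stick bonds must sit at `rb` (tolerance `1e-9`); bead-spring bonds
#' must lie strictly inside `(r0 - R, r0 + R)`.
#'
#' @param conf A [conformation()].
#' @param spec A [model_spec()].
#' @param tol Tolerance for the rigid-bond check.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_conformation <- function(conf, spec, tol = 1e-9) {
  bl <- chain_bond_lengths(conf)
  if (spec$kind == "bead_stick") {
    if (any(abs(bl - spec$rb) > tol)) {
      stop("bead-stick bond length deviates from rb by more than ", tol)
    }
  } else {
    if (any(bl <= spec$r0 - spec$R | bl >= spec$r0 + spec$R)) {
      stop("bead-spring bond outside the FENE range (r0 - R, r0 + R)")
    }
  }
  if (!is.null(conf$box)) {
    ext <- chain_extents(conf)
    if (any(ext >= conf$box / 2)) {
      stop("chain extent exceeds L/2; minimal-image bookkeeping invalid")
    }
  }
  invisible(TRUE)
}

chain_bond_lengths <- function(conf) {
  unlist(lapply(seq_len(conf$n_chains), function(c0) {
    p <- chain_positions(conf, c0)
    d <- diff(p)
    sqrt(rowSums(d^2))
  }))
}

chain_extents <- function(conf) {
  vapply(seq_len(conf$n_chains), function(c0) {
    p <- chain_positions(conf, c0)
    cm <- colMeans(p)
    2 * sqrt(max(rowSums(sweep(p, 2, cm)^2)))
  }, numeric(1))
}

#' Extract the positions of one chain
#'
#' @param conf A [conformation()].
#' @param chain Chain index in `1:M`.
#' @return An `N x 3` matrix.
#' @export
chain_positions <- function(conf, chain = 1) {
  N <- conf$n_beads
  conf$positions[((chain - 1) * N + 1):(chain * N), , drop = FALSE]
}

model_to_list <- function(spec) {
  list(kind = spec$kind, epsilon = spec$epsilon, sigma = spec$sigma,
       rc = spec$rc, kappa = spec$kappa, rb = spec$rb, K = spec$K,
       R = spec$R, r0 = spec$r0)
}

#' Total potential energy of a conformation
#'
#' Sums the shifted LJ energy over all non-bonded pairs (minimal image for
#' inter-chain pairs in a box), the bending sum over all interior angles,
#' and (bead-spring) the FENE bond energies. The bending sum `EBend` is
#' returned *unmultiplied* by `kappa`, so the two-dimensional energy
#' decomposition `p(ELJ, EBend)` is available without re-simulation;
#' the total is `Ep = ELJ + kappa * EBend + EFENE`.
#'
#' @param conf A [conformation()].
#' @param spec A [model_spec()].
#' @return A one-row tibble with columns `elj`, `ebend`, `efene`, `ep`,
#'   `finite`. Overlapping beads yield non-finite energy with
#'   `finite = FALSE` rather than an error.
#' @export
total_energy <- function(conf, spec) {
  res <- total_energy_cpp(conf$positions, conf$n_chains,
                          if (is.null(conf$box)) -1 else conf$box,
                          model_to_list(spec))
  tibble::tibble(elj = res$elj, ebend = res$ebend, efene = res$efene,
                 ep = res$ep, finite = res$finite)
}
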