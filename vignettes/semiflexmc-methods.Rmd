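---
title: "Models, sampling and analysis methods in semiflexmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, sampling and analysis methods in semiflexmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semiflexmc)
```

# The physical problem

`semiflexmc` simulates dilute solutions of coarse-grained semiflexible
polymers with short-range self- and mutual attraction, and analyses the
temperature-driven transitions these systems undergo: the collapse or
folding of a single chain, the appearance of thermodynamically stable
knotted phases, and the aggregation of several chains into amorphous
clusters or aligned bundles. Temperature plays the role of solvent
quality; all quantities are expressed in reduced units with the
Lennard-Jones well depth $\epsilon = 1$, the LJ length $\sigma$ setting
the length scale, and $k_B = 1$.

# Models

Two standard bead models are implemented, selected in `model_spec()`:

* **bead-stick** — rigid bonds of length $r_b = 1$, $\sigma = \epsilon = 1$.
* **bead-spring** — FENE bonds
  $V_{\mathrm{FENE}}(r) = -\tfrac{K}{2} R^2 \ln\!\big[1 - ((r - r_0)/R)^2\big]$
  with $K = 40$, $R = 0.3$, $r_0 = 0.7$ and $\sigma = 2^{-1/6} r_0$, so
  that the preferred non-bonded distance equals the bond length.

Non-bonded bead pairs interact through the truncated and shifted
Lennard-Jones potential
$V_{\mathrm{LJ}}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] - V_{\mathrm{LJ}}(r_c)$
with $r_c = 2.5\sigma$, and semiflexibility enters through the
worm-like-chain bending penalty $\kappa (1 - \cos\theta)$ at every
interior bond angle. The two parameterisations describe chains of equal
contour length ($N r_0 = 28$ for the bead-spring 40-mer and the
bead-stick 28-mer), but differ in the ratio of the non-bonded LJ minimum
distance $r_n = 2^{1/6}\sigma$ to the bond length: $r_n / r_b \approx 1.12$
for the bead-stick chain versus exactly 1 for the bead-spring chain.
That mismatch of length scales is what makes stable knotted phases
possible in the bead-stick model.

Two deliberate conventions:

* Bonded pairs are excluded from the LJ sum in *both* models. In the
  bead-stick model bonded pairs sit at the fixed distance $r_b$, so this
  choice differs from the all-pairs convention only by the constant
  $(N-1)\, V_{\mathrm{LJ},\mathrm{shifted}}(r_b)$ per chain, which
  cancels in every ensemble average, derivative and histogram the
  package produces. The offset is documented in `?model_spec`.
* The bending sum $E_{\mathrm{Bend}} = \sum (1 - \cos\theta)$ is stored
  *unmultiplied* by $\kappa$ next to $E_{\mathrm{LJ}}$, so the
  two-dimensional energy decomposition $p(E_{\mathrm{LJ}}, E_{\mathrm{Bend}})$
  is available from any saved series without re-simulation. The total
  potential energy is $E_p = E_{\mathrm{LJ}} + \kappa E_{\mathrm{Bend}} + E_{\mathrm{FENE}}$.

For multi-chain systems at density $\rho = NM/V$ a cubic periodic box
of edge $L = (NM/\rho)^{1/3}$ is used. Chains are stored unwrapped;
only inter-chain pair distances and the phase-separation parameter use
the minimal-image convention. This is valid while every chain's extent
stays below $L/2$, which the package asserts at validation time — in
the dilute regime studied here ($\rho = 10^{-3}$, so $L \approx 37$ for
$M = 4$, $N = 13$) the margin is comfortable.

# Monte Carlo moves

The move set is model-aware: local bead displacement (bead-spring
only — it would violate rigid bonds), crankshaft rotation of a bead
about the axis joining its neighbours (the bead-stick local move; end
beads rotate about a random axis through their single neighbour), pivot
rotation of a chain section about an interior vertex, and, for boxed
multi-chain systems, long-range chain translation that places the
centre of mass uniformly in the box — essential for sampling the void
space in dilute aggregation. All proposals are symmetric, so the
Metropolis ratio needs no Hastings correction. Default mixture:
local/crankshaft 0.6 and pivot 0.4, with translation taking probability
0.2 when active. Move amplitudes are auto-tuned towards 30–60%
acceptance **only during the discarded equilibration phase** and frozen
before measurements start, preserving detailed balance where it
matters. One sweep is $N \cdot M$ elementary proposals.

Bond-constraint violations (a FENE bond leaving $(r_0 - R, r_0 + R)$,
overlapping beads) are handled by an infinite-energy sentinel that
rejects the move; exceptions are reserved for malformed input.

# Generalized-ensemble sampling

Canonical Metropolis sampling (`run_canonical()`) is sufficient away
from first-order-like transitions. Near them the package uses the
multicanonical approach: sample with weights $W(E_p) \approx \Omega(E_p)^{-1}$
so that all potential energies in a target window are visited roughly
uniformly (`iterate_muca_weights()` followed by `run_weighted()`).

The weight iteration uses the accumulated (error-weighted) recursion on
adjacent-bin ratios: each iteration's histogram updates
$\ln W(E_{b+1}) - \ln W(E_b)$ with statistical weight
$g_b = h_b h_{b+1} / (h_b + h_{b+1})$ accumulated over iterations. A
naive $\ln W \leftarrow \ln W - \ln H$ overwrite oscillates badly at
desk-scale statistics (previously well-sampled regions are forgotten
each iteration); the accumulated recursion is stable and converges in
10–20 iterations for the systems treated here. Numerical choices, all
configurable:

* energy bin width $\Delta E = 0.5\,\epsilon$ (1.0 for the 40-mer scans);
* flatness criterion: min/mean visit count $\ge 0.5$ over the covered
  range, required in **two consecutive iterations** so a lucky histogram
  cannot end the recursion early;
* unvisited bins carry their weight forward; an optional 3-bin moving
  average smooths the update;
* the energy window is bracketed by canonical pilot runs at the
  temperature extremes of the scan: the upper edge from the mean plus
  three standard deviations of the high-$T$ pilot (using the pilot
  *maximum* would chase a single outlier into an essentially
  unreachable tail), the lower edge from a short annealing ladder down
  to the low-$T$ end; proposals leaving the window are rejected;
* per-iteration sweeps grow geometrically (factor 1.3) from 5000 up to
  a cap, after which iterations repeat at the cap until flat.

`parallel_muca()` sums the histograms of independent walkers before
each update — statistically equivalent to the serial scheme.
`parallel_tempering()` provides canonical replica exchange with swap
probability $\min\{1, e^{\Delta\beta\,\Delta E_p}\}$, and
`nve_weight_table()` implements the microcanonical weight
$W(E_p) = (E - E_p)^{(N_{\mathrm{dof}} - 2)/2}$, in which the kinetic
energy acts as a finite reservoir.

# Reweighting and errors

Canonical expectations at arbitrary $\beta$ follow from the generalized
ensemble by dividing out the simulation weight,
$\langle O \rangle_\beta = \langle O e^{-\beta E_p} / W \rangle_{GE} / \langle e^{-\beta E_p} / W \rangle_{GE}$,
implemented with log-sum-exp stabilisation (results are invariant under
adding any constant to $\ln W$, tested to $10^{-12}$). Thermal
derivatives use the fluctuation identity
$d\langle O\rangle/dT = \beta^2 (\langle O E_p\rangle - \langle O\rangle\langle E_p\rangle)$;
for $O = E_p$ this is the extensive specific heat. The sampled quantity
is the potential energy throughout — momenta are integrated out
analytically, so kinetic terms would only add smooth analytic
contributions.

Each reweighted value carries a Kish effective sample size
$(\sum w)^2 / \sum w^2$; temperatures where it drops below 100 are
flagged as outside the trustworthy window of that run. Errors of
arbitrary, possibly nonlinear statistics (reweighted ratios, peak
positions) come from a bias-corrected block jackknife with 20
contiguous blocks by default.

# Microcanonical analysis

A flat-histogram production run directly yields the conformational
density of states, $\ln\Omega = \ln H - \ln W$ bin by bin. From the
entropy $S(E_p) = \ln\Omega(E_p)$ the package forms the microcanonical
inverse temperature $\beta(E_p) = dS/dE_p$ and its derivative
$\gamma(E_p)$ by centred differences on a staggered grid ($\beta$ on bin
boundaries, $\gamma$ on centres), after Gaussian smoothing of
$\ln\Omega$ with $\sigma = 2$ bins (configurable and reported with the
result). Finite-size transition order is read off the dominant interior
extremum of $\gamma$: a positive peak means back-bending of
$\beta(E_p)$ — a first-order-like transition, accompanied by a
double-peaked canonical energy distribution — while a negative peak
marks a second-order-like transition. The extremum location is the
transition energy $E_p'$, and `rescaled_beta()` recenters
$\beta(E_p) - \beta(E_p')$ against $E_p - E_p'$ for overlaying
different stiffnesses. Edges of the covered range are excluded from
peak detection: they carry the steep ground-state rise of $\beta$ and
one-sided smoothing bias, not transition physics, and the noise
threshold ($3\times$ the median $|\gamma|$ of the high-energy tail)
separates genuine extrema from histogram noise.

For the bead-spring 40-mer this machinery reproduces the qualitative
stiffness crossover of the collapse transition: a negative
$\gamma$-peak (continuous collapse) at $\kappa = 2$, back-bending
(discontinuous folding) at $\kappa = 10$, with the sign change near
$\kappa \approx 6$. Three desk-scale choices matter here, all made by
`gamma_peak_scan()`:

* the entropy is taken from the *accumulated-weight estimator*
  $\ln\Omega \approx -\ln W$ of the converged recursion, which
  precision-weights every iteration's histogram and is far less noisy
  than a single production histogram at these statistics; bins whose
  adjacent-bin ratios accumulated fewer than 200 effective counts are
  masked (their carried-forward weights would fake features);
* the recursion's optional update smoothing is turned off for these
  scans — repeated 3-bin averaging over tens of iterations blurs the
  weak back-bend of a finite chain;
* the energy window is focused on the transition (pilot bracket
  $T \in [0.25, 1.2]$), with the folded basin reached through a hairpin
  pilot; flattening the huge rod-phase energy range above would cost
  orders of magnitude more sampling without informing the collapse.

The acceptance script reports the crossover as the midpoint of the
tightest stiffness pair whose order classifications bracket the sign
change ($\kappa = 4$ and $8$); at desk-scale statistics the bracket,
not the third digit, is the meaningful statement.

# Aggregation observables

For $M$ chains in a periodic box the package measures, per sweep, the
mean squared radius of gyration and end-to-end distance, the
end-to-end correlation
$C_R = \tfrac{2}{M(M-1)} \sum_{i<j} (\hat R_i \cdot \hat R_j)^2$ — a
nematic-like order parameter equal to 1 for aligned bundles and $1/3$
in expectation for uncorrelated chains — and the phase-separation
parameter $\Gamma_2 = \tfrac{1}{2M^2}\sum_{i,j} |r_{cm}^i - r_{cm}^j|^2$
with minimal-image centre-of-mass distances, which collapses at
aggregation. The double sum is read over ordered pairs (each unordered
pair twice), fixed by the two-chain closed form $\Gamma_2 = d^2/4$.
Chains whose end-to-end distance vanishes (closed loops) have no
direction; they are excluded from $C_R$ with the denominator adjusted
and the result flagged. Centres of mass are computed on unwrapped
chains and wrapped once — valid under the same extent-below-$L/2$
assertion as the energy bookkeeping, and avoiding circular-mean
machinery.

# Knot identification

Open chains have no strict topology, so classification starts with a
deterministic virtual closure: both endpoints are pushed radially
outward from the chain's centre of mass onto a sphere of three times
the maximal bead–centre distance and joined through a far apex point
(three added vertices). The closure arc stays well outside the chain,
keeping spurious entanglement minimal; conformations near a knotting
transition can still be closure-sensitive, which is a caveat of any
closure prescription rather than of this implementation.

The closed polygon is projected along a seed-derived random direction
(re-drawn on non-generic projections), its crossing diagram is
extracted, and the Alexander matrix is built from the crossing
relations, with generators labelled by the arcs between consecutive
undercrossings. Deleting one row and column and evaluating the
determinant at $t = -1.1$ and $1/t$ gives the fingerprint
$\Delta_p = |\Delta(t)\,\Delta(1/t)|$, which cancels the $\pm t^k$
normalisation ambiguity and distinguishes all prime knots up to 8
crossings. Classification is a nearest-match lookup in that reference
table within a relative tolerance of $10^{-3}$ — well below half the
$\approx 1.5\%$ gap between the two closest relevant entries
($4_1$ and $5_1$) — and `"unclassified"` otherwise. The determinant is
evaluated in floating point with partial pivoting; matrix sizes stay in
the low hundreds for the chains of interest. The Alexander invariant is
achiral, so mirror knots share a label; chirality detection and knot
localisation are out of scope.

The crossing-sign convention of the matrix rows was fixed by validating
against the figure-eight knot, whose mixed-sign diagram discriminates
the two possible conventions (the trefoil, with all crossings of one
sign, does not).

# What the fixtures emulate — and what they do not

All test inputs are generated in code: straight rods, hairpins, random
coils with a minimum-distance constraint, aligned and random bundles,
parametric $(p,q)$ torus-knot polygons, and an exactly solvable
two-level system for the reweighting identities. These fixtures pin
down closed-form limits ($R_{gyr}^2 = (N^2-1)/12$ for a rod, $C_R = 1$
for aligned bundles, Langevin-function orientation statistics for a
bending-only trimer) and the topology pipeline (torus knots have known
Alexander polynomials). What they do not probe: real experimental
polymers with heterogeneous sequences, solvent-mediated interactions
beyond the implicit-solvent LJ attraction, or dynamics — the Monte
Carlo trajectory carries no physical time. Passing tests therefore
demonstrate correctness of the statistical mechanics and topology
machinery at the stated system sizes, not transferability of the
coarse-grained model to any specific chemistry.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run the full pipelines at
reduced statistics chosen as the package's reference desk-scale
conditions: the flexible 13-mer for multicanonical self-consistency
(converged weights plus a $2\times 10^5$-sweep production run), the
40-mer at $\kappa \in \{2, 10\}$ (signs) and $\{4, 8\}$ (bracket) for
the collapse-order crossover with $2\times 10^5$-sweep productions, and
$10^5$ random draws for the $C_R \to 1/3$ law. Every random number in
the package flows from a single integer seed per entry point — equal
seeds give bit-identical trajectories (the compiled sampler uses its
own deterministic generator, independent of R's RNG state), and all
derived seeds stay below $2^{31}$.

# Known limitations

* The multicanonical energy window is fixed after the pilot bracket; a
  system whose ground state lies far below anything the annealing pilot
  reaches will be flagged `not converged` rather than silently
  extended.
* $\Gamma_2$ and the minimal-image bookkeeping assume dilute conditions
  (chain extent below $L/2$); dense systems violate the assertion.
* The $\gamma$-peak crossover at desk scale brackets $\kappa \approx 6$
  but cannot resolve it sharply; cluster-scale statistics would be
  required for the full phase diagrams.
* Knot labels near the knotting transition inherit the closure caveat
  above.
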