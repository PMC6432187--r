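# semiflexmc

Generalized-ensemble Monte Carlo for dilute, mutually attractive
**semiflexible polymers**, with the analysis stack needed to map their
structural transitions: single-chain collapse and folding, stable knotted
phases, and multi-chain aggregation into amorphous clusters or aligned
bundles.

The package is aimed at statistical-mechanics and soft-matter researchers
who want a self-contained, scriptable implementation of this toolchain in
R: coarse-grained chain models, flat-histogram sampling, canonical
reweighting with honest errors, microcanonical transition classification,
and topological knot detection.

## What is implemented

**Models.** Chains of `N` beads (optionally `M` chains in a cubic periodic
box at density `rho = NM/V`), in two standard parameterisations built by
`model_spec()`:

* *bead-stick*: rigid bonds `rb = 1`, `sigma = epsilon = 1`;
* *bead-spring*: FENE bonds `V(r) = -(K/2) R^2 ln[1 - ((r - r0)/R)^2]`
  with `K = 40`, `R = 0.3`, `r0 = 0.7`, `sigma = 2^(-1/6) r0`.

Non-bonded pairs interact via the Lennard-Jones potential truncated and
shifted at `rc = 2.5 sigma`; semiflexibility enters as the worm-like-chain
bending penalty `kappa (1 - cos theta)`, so the total potential energy is
`Ep = ELJ + kappa EBend + EFENE`.

**Sampling.** Canonical Metropolis (`run_canonical()`), multicanonical
flat-histogram weights `W(Ep) ~ 1/Omega(Ep)` via an accumulated
error-weighted recursion (`iterate_muca_weights()`, `parallel_muca()`)
with frozen-weight production runs (`run_weighted()`), microcanonical
weights `W = (E - Ep)^((Ndof-2)/2)` (`nve_weight_table()`), and parallel
tempering. Moves are model-aware (crankshaft, pivot, local displacement,
long-range chain translation), symmetric, and auto-tuned only during
discarded equilibration.

**Analysis.** Reweighting to canonical expectations
`<O>_beta = <O e^(-beta Ep)/W> / <e^(-beta Ep)/W>` with log-sum-exp
stabilisation and Kish effective-sample-size guards; thermal derivatives
`d<O>/dT = beta^2 (<O Ep> - <O><Ep>)`; block-jackknife errors for
nonlinear statistics; density of states `ln Omega = ln H - ln W`;
microcanonical `beta(Ep) = dS/dEp` and `gamma(Ep) = dbeta/dEp` with
first/second-order classification from the sign of the dominant gamma
peak; aggregation order parameters `CR` (nematic-like end-to-end
alignment: 1 for bundles, 1/3 for uncorrelated chains) and `Gamma2`
(mean squared minimal-image COM distance); 2D energy histograms
`p(ELJ, EBend)`; and Alexander-polynomial knot classification of open
chains at `t = -1.1` (`identify_knot()`, `knot_fraction()`).

## A worked example

Multicanonical analysis of the collapse of a flexible bead-spring 13-mer:

```r
library(semiflexmc)

spec <- model_spec("bead_spring", kappa = 0)
conf <- make_fixture("coil", N = 13, spacing = spec$r0, seed = 3)

w <- iterate_muca_weights(conf, spec, de = 0.5, t_bracket = c(0.2, 3),
                          iter_sweeps = 4000, growth = 1.2, seed = 11)
glance(w)
#> # A tibble: 1 x 6
#>   n_bins  emin    de converged iterations flatness
#>    <int> <dbl> <dbl> <lgl>          <int>    <dbl>
#> 1     93 -28.1   0.5 TRUE              15    0.512

prod <- run_weighted(w$meta$conf, spec, w, sweeps = 2e5, discard = 2e4,
                     seed = 12)
min(prod$hist) / mean(prod$hist)   # production flatness
#> [1] 0.80445

reweight(prod$series, temperature = c(1, 2, 3))
#> # A tibble: 3 x 6
#>    beta temperature observable value    ess flag
#>   <dbl>       <dbl> <chr>      <dbl>  <dbl> <lgl>
#> 1 1               1 ep         -6.33 50774. FALSE
#> 2 0.5             2 ep          1.21 52011. FALSE
#> 3 0.333           3 ep          3.95 55274. FALSE
```

One converged weight table covers the whole temperature window: the
reweighted mean energies agree with direct Metropolis runs at each
temperature within their combined jackknife errors (the test suite checks
this at 2 sigma). Feeding the production histogram to
`dos_from_weights()` and `micro_beta_gamma()` yields the entropy
derivatives; `classify_transition()` then reads off the transition order,
and for a knotted bead-stick chain `identify_knot()` returns the knot
class, e.g. `3_1` for a trefoil-shaped conformation with fingerprint
`Delta_p = 9.0546`.

A thin command-line front-end over the same functions is provided in
`exec/semiflexmc` (subcommands `simulate`, `iterate-weights`, `reweight`,
`analyze-micro`, `knots`, `fixtures`, `scan`), reading YAML run
configurations.

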