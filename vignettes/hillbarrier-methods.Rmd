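---
title: "Models, measures and algorithms in hillbarrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, measures and algorithms in hillbarrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillbarrier)
```

## The model class and its assumptions

`hillbarrier` works with finite-state, continuous-time Markov processes
presented as labelled directed graphs: vertices are molecular states, edges
are transitions, labels are rates with units 1/time. Two assumptions are
hard-wired and shape the whole package:

* **First-order binding.** An edge at which the input ligand binds carries
  the label `rate * x`, linear in the free input concentration `x`. Higher
  binding stoichiometries are rejected at construction
  (`binds_input ∈ {0, 1}`), and an edge whose target pattern gains a site
  must carry the flag.
* **Reservoir.** Ligand concentrations are not depleted by binding. The
  input ligand is the only concentration tracked explicitly; every other
  ligand is held constant and folded into the rate constants. Consequently
  `x` enters the mathematics only through binding-edge labels, and a
  response is a genuine function of `x` under quasi-static variation.

States may carry arbitrary extra structure (conformations, coregulators,
occupancy of non-input sites). The data model does not name such features;
they are represented as distinct vertices sharing an input-binding pattern,
which is all that the coarse-graining ever inspects.

## Steady states: three routes and why each exists

1. **Enumeration** (`spanning_trees`, `rho_poly`). Every non-root vertex
   selects one outgoing edge; the choice is kept iff every vertex reaches
   the root. This is the brute-force oracle, capped at 10 vertices, and the
   source of the per-vertex polynomial in `x` (sum over trees of the product
   of labels, collecting the binding-edge `x` factors by power). It is the
   reference against which everything else is tested.
2. **Determinants** (`count_spanning_trees`, `rho_at`). The Matrix-Tree
   theorem equates the rooted tree sum with a signed first minor of the
   Laplacian. Structure-only counts use fraction-free (Bareiss)
   elimination: on integer matrices every intermediate quantity is itself a
   minor determinant, divisions are exact, and the result is an exact
   integer as long as intermediates stay below 2^53 — comfortably true for
   the 15×15 minor of the four-site hypercube, whose 42,467,328 rooted
   trees per vertex the package reproduces bit-exactly. The same routine is
   exact on dyadic-rational rates (denominators a power of two), which the
   random oracle fixtures use so that enumeration and minors can be compared
   with `identical()` rather than with a tolerance.
3. **GTH state elimination** (`steady_state`). For probabilities we use the
   Grassmann–Taksar–Heyman algorithm rather than normalized minors: it
   performs only additions and divisions of nonnegative quantities, so each
   component of the stationary vector is obtained with small *relative*
   error even when its value is 1e-12. That matters for block conditionals
   (below), where a ratio of two tiny probabilities must stay stable across
   six decades of `x`; determinant evaluation only controls absolute error
   and visibly fails this at extreme concentrations.

## Detailed balance diagnostics

A reversible graph can reach thermodynamic equilibrium iff the product of
forward/backward label ratios is 1 around every cycle. `cycle_condition`
checks a fundamental cycle basis (spanning tree plus chords); the tolerance
is applied to `|log` of the product`|` (default 1e-9) so the test is
invariant under rescaling of rates. Binding-edge `x` factors cancel around
any cycle — patterns return to themselves — so the check involves rate
constants only. Under the cycle condition, `mu_vector` assigns each vertex
the path product from a reference vertex with empty pattern; the net number
of binding edges along any such path equals the pattern size, so the weight
is `gamma_i * x^{|S_i|}` with `gamma_i` x-free. Path independence is
implied by the basis check rather than re-verified per vertex; the
implementation does assert that the path exponent matches the pattern size
for every vertex, which would catch a mislabeled graph.

## Coarse-graining

`coarse_grain` merges vertices sharing a binding pattern. The coarse edge
label into block `z` is `Q` times the block's tree-sum at the evaluation
concentration; with these labels the coarse graph satisfies the cycle
condition *by construction* (the labels depend only on the target block, so
ratio products telescope) and its steady state equals the block sums of the
fine one — whether or not the fine graph obeys detailed balance. Design
choices:

* `Q` is fixed at 1 and exposed only so tests can confirm it cancels.
* The coarse graph is built **at a fixed `x`** and rebuilt per `x` when a
  grid is swept. Coarse-graining is a steady-state statement; nothing is
  claimed about coarse dynamics, and an x-independent coarse object exists
  only in the equilibrium case (where `mu_vector` of the coarse graph
  recovers the monomial structure).
* Patterns never reached by the fine graph simply do not appear: the coarse
  structure is in general a strict substructure of the hypercube (mutual
  exclusion removes vertices, ordered binding removes edges).

The conditional probabilities `chi_i` (vertex probability divided by its
block sum) are x-free exactly when the fine graph satisfies the cycle
condition; their drift with `x` is otherwise generic, and the package's
fixtures demonstrate both regimes.

## The equilibrium rational form and its samplers

At equilibrium every response collapses to a degree-`l` rational function
whose denominator coefficients are positive and dominate the numerator's,
`l` being the maximum number of concurrently bound sites
(`equilibrium_rational_form` computes the coefficients as block sums of the
vertex weights; contiguity of degrees 0..l is guaranteed because sites bind
one at a time). The converse — every such coefficient vector is realized by
some equilibrium mechanism — is taken as given here; it licenses sampling
coefficients directly instead of sampling graphs:

* `sample_equilibrium_coefficients`: `log10 beta_i` uniform on `[-a, a]`,
  then `log10 alpha_i` uniform on `[-a, log10 beta_i]`. The exponent range
  `a` is the only tuning parameter; the equilibrium region stabilizes
  rapidly as `a` grows.
* `alpha_i = 0` exactly (e.g. a strict fractional-saturation numerator) has
  probability zero under log-uniform sampling; an optional `zero_mass`
  places point mass there for boundary studies. The default of 0 mirrors
  the sampler used to build the universal region.
* `sample_unconstrained_coefficients` drops the `alpha <= beta` coupling;
  the resulting functions may exceed 1 and escape the equilibrium region —
  the control showing the coefficient constraints are what confine it.

Away from equilibrium no coefficient extraction is attempted: the degree of
the response depends on the whole graph structure (for the full `m`-cube it
is `2^m - 1`), so nonequilibrium responses are handled either through the
exact tree polynomial (small graphs) or numerically.

## Position and steepness

Given a bounded response on `[0, ∞)`, `x_half` is the smallest positive
concentration where the response is halfway between its infimum and
supremum (chosen strictly positive even if the value at 0 already sits
halfway), and position/steepness are the location and value of the global
maximum of the normalized slope `|dq/dy|`, `q(y) = r(y * x_half)`.

For rational responses everything reduces to polynomial root isolation: the
slope's numerator is `C = A'B - AB'`, its critical points are roots of
`C'B - 2CB'`, and the half-crossing solves `A - hB = 0`. Numerical choices:

* **Internal concentration rescaling.** Before any root finding, `x` is
  rescaled by `(beta_0 / beta_l)^(1/l)`. Position and steepness are scale
  invariant in exact arithmetic; rescaling makes them scale invariant in
  floating point too, and conditions coefficient vectors spanning many
  decades.
* **Root polishing.** `polyroot` can lose five digits on badly scaled
  cubics; every real candidate root gets up to four guarded Newton steps.
* **Tie-break.** Among slope maximizers within relative tolerance 1e-9 of
  the maximum, the smallest is returned; a maximizer at the origin is
  legitimate (`p = 0`, the low-position wing) and not an error.
* **Degenerate origin crossing.** If the constant term of `A - hB` is zero
  to relative 1e-11 the root at the origin is deflated, implementing the
  "next crossing" convention; a residual check with a log-grid bisection
  fallback guards against root-finding failure outright.
* Tolerances (imaginary-part threshold 1e-7 relative, tie 1e-9, constancy
  1e-13) are package options (`hillbarrier.im_tol` etc.).

Hill functions with non-integer coefficient are not rational in `x`, so
`position_steepness` has a numeric method for them (and for arbitrary
response functions): log-grid scan, then root isolation on a five-point
finite-difference derivative of the slope. It agrees with the closed-form
Hill line to ~1e-12, an independent cross-check of both routes. The test
suite additionally compares the rational path against a complex-step
differentiation grid oracle on hundreds of random responses.

## Region estimation

`estimate_region` reproduces the boundary-exploration strategy for (p, s)
regions: bin sampled points on a square grid (cell side 0.005), define the
working boundary as occupied cells with an empty axis neighbor, and
repeatedly (phase 1) mutate a boundary cell's archived parameters until an
empty cell is hit, then (phase 2) pull mutations toward a target placed
outside the boundary — the cell center displaced 3 cell widths along the
mean empty-neighbor direction — to escape deep valleys. Unstated details of
the published procedure are fixed here as follows: mutation multiplies each
parameter by `10^eps`, `eps ~ U(-0.25, 0.25)`, clipped to the sampling box,
with numerator coefficients re-clipped below their denominator partners;
each phase gets up to `phase_tries` (default 200) attempts; one iteration
processes one randomly chosen boundary cell; convergence is declared after
`stagnation_limit` (default 1,500) consecutive iterations without a new
boundary cell, with a `max_iter` safety cap. The grid is an unbounded
sparse set — cells in the wings can have astronomically large indices, so
indices are kept as exact doubles — and any axis truncation is a display
concern, never a computational one. Runs are reproducible from the seed
recorded in the returned object.

Desk-scale checks in the test suite use `n_init = 2e4`, `stagnation_limit
= 200`, `phase_tries = 50` and `max_iter = 1500` at `m = 2`: sizes chosen
so the whole three-range sweep (`a = 1, 2, 3`) completes in minutes while
still exhibiting the qualitative behavior of interest — the boundary cell
nearest the Hill point of `H_2` moves monotonically closer as `a` grows and
never crosses it in both coordinates. Full-size asymptotic regions for
`m = 4` or `6` are multi-hour computations and are out of scope.

## Synthetic fixtures: what they emulate and what they do not

`random_binding_graph(m, k_internal, a, equilibrium)` builds the test
systems: each binding pattern of the `m`-cube carries `k_internal` internal
states (a conformation, or occupancy of a non-input site) joined in a
reversible chain, and every binding transition is realized at every
internal copy, so binding and internal transitions interleave in cycles.
This product structure matters: if internal states hang off a single
anchor as pendant decorations, their tree weights are exactly proportional
to the anchor's and the block conditionals become x-free even without
detailed balance — a degenerate family that would mask the
equilibrium/nonequilibrium dichotomy the fixtures exist to exhibit.
Equilibrium labelings draw a log-uniform weight per vertex on `[-a, a]`
(default `a = 2`, i.e. rate ratios across roughly four decades, a realistic
span for binding free energies) and set each pair's rate ratio to the
weight ratio, so the cycle condition holds by construction; nonequilibrium
labelings draw every rate independently. What these fixtures do **not**
emulate: ligand depletion, oligomerization, correlated rates, or any
specific biochemical parameterization — passing tests demonstrate the
mathematical dichotomies on generic graphs, not fit to any organism's
numbers.

The barrier tests run at `m = 2` (the smallest nontrivial case): 1e5
equilibrium coefficient draws at `a = 3` with zero escapes, against 1e4
nonequilibrium hypercube draws with tens of escapes, both at fixed seeds
chosen once; the contrast is overwhelming rather than marginal, so the
stochastic assertions are stable.

## Known limitations

* Exact integer work relies on doubles below 2^53; graphs far larger than
  the six-site hypercube would need true big-integer arithmetic.
* Dense determinants and GTH are O(n^3): fine for the tens-of-vertices
  graphs the theory concerns, not for state spaces of thousands.
* The printed degree of nonequilibrium hypercube responses is implemented
  as `2^m - 1` (the value the tree polynomial actually attains for
  `m = 2`, where the symbolic denominator has degree 3); the test suite
  asserts the computed value.
* Nonequilibrium (p, s) regions are sampled, not characterized; their
  shape remains an open problem.
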