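# hillbarrier

How sharp can the dose–response curve of a molecular system be if the system
runs at thermodynamic equilibrium? **hillbarrier** provides the machinery to
answer that question for any Markov-process model of ligand binding: it
computes exact steady states of labelled directed graphs (the *linear
framework*), coarse-grains arbitrarily complicated mechanisms onto the
hypercube of input-binding patterns, measures the intrinsic *position* and
*steepness* of an input–output response, and estimates the universal region
of (position, steepness) points attainable at equilibrium — whose boundary
is set by the Hill function `H_m(x) = x^m / (1 + x^m)`, with `m` the number
of input binding sites. Responses that beat `H_m` in both position and
steepness certify that the underlying mechanism spends energy. The package
is aimed at quantitative biologists modelling gene regulation, allostery and
receptor signalling, and at anyone fitting Hill coefficients to data.

## The model

A mechanism is a strongly connected directed graph `G`: vertices are
molecular states carrying a pattern `S ⊆ {1..m}` of occupied input sites,
edges are transitions with positive rate labels, and an edge at which one
input molecule binds carries an extra factor `x` (the free input
concentration; first-order mass-action binding from a reservoir). The
steady state is, by the Matrix-Tree theorem,

    u_i*(x) ∝ ρ_i(G) = Σ_{T rooted at i} Π_{edges of T} label,

and an input–output response is `r(x) = Σ λ_i u_i*(x)` with weights
`λ_i ∈ [0, 1]`. At thermodynamic equilibrium (cycle condition: label-ratio
products equal 1 around every cycle) the steady state collapses to
Boltzmann-like vertex weights `γ_i x^{|S_i|}`, and every response becomes

    r(x) = (α_0 + α_1 x + ... + α_l x^l) / (β_0 + β_1 x + ... + β_l x^l),
    0 ≤ α_i ≤ β_i,  β_i > 0,

with `l` the maximum number of concurrently bound sites — independent of
every other detail of the mechanism. Sharpness is measured intrinsically:
`x_half` is the smallest positive concentration where `r` is halfway between
its infimum and supremum, `q(y) = r(y·x_half)` is the normalized response,
steepness `s` is the global maximum of `|dq/dy|` and position `p` the
smallest `y` attaining it.

## Worked example

A transcription-factor-like system: the input ligand binds at two sites and
a second, non-input ligand occupies a third site (8 states), at
thermodynamic equilibrium with randomly drawn free energies:

```r
library(hillbarrier)
set.seed(1)
g <- hypercube_plus_one(2, equilibrium = TRUE)
round(steady_state(g, x = 1), 4)
#>    {}#1    {}#2   {1}#1   {1}#2   {2}#1   {2}#2 {1,2}#1 {1,2}#2
#>  0.0008  0.0021  0.0131  0.2880  0.0004  0.2631  0.4030  0.0295

rf <- equilibrium_rational_form(g, fractional_saturation(g))
rf
#> <hb_response> degree l = 2, equilibrium constraints: satisfied
#>   alpha: 0 364.9 558.9
#>   beta:  3.67 729.8 558.9
position_steepness(rf)
#> <hb_sharpness> p = 0, s = 8.05687 (x_half = 0.0810293, range [0, 1])
```

The eight-state mechanism collapses to a degree-2 rational response whose
numerator coefficients are dominated by the denominator's — the universal
equilibrium structure. Its unnormalized slope is largest at the origin
(`p = 0`): this response sits in the low-position "wing" of the equilibrium
region, far from the Hill point `hill_point(2) = (p = 0.577, s = 0.650)`.
No equilibrium two-site response can exceed that point in both coordinates;
a nonequilibrium one can:

```r
ne <- noneq_ps_sample(2, a = 3, n = 2000, seed = 1)
head(exceeds_hill_barrier(ne, 2), 3)
#>             p         s
#> 138 0.6482986 0.6877948
#> 144 0.5901306 0.6538878
#> 319 0.6048346 0.6516797
```

Thirteen of 2,000 randomly labelled hypercube models (fractional-saturation
output, no detailed-balance constraint) land strictly beyond the Hill point
of `H_2` in both position and steepness — impossible at equilibrium, and the
signature of energy expenditure.

The same operations are scriptable from a shell via the thin CLI at
`inst/cli/hillbarrier.R` (`make-hypercube`, `steady-state`, `coarse-grain`,
`sharpness`, `region-estimate`, `noneq-sample`, ...).

## Vignette

`vignettes/hillbarrier-methods.Rmd` documents the model assumptions, the
numerical choices (exact tree counting, subtraction-free steady states,
root-isolation sharpness), the synthetic fixture generators, and the region
estimation algorithm with its hyperparameters.
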