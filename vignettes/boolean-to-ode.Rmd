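---
title: "From Boolean regulatory networks to continuous ODE models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From Boolean regulatory networks to continuous ODE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolcube)
```

## The modelling problem

For most regulatory systems, only qualitative knowledge is available:
factor A activates B, C represses B. Such knowledge converts naturally to
a Boolean network — N species, each on or off, each updated by a logical
function of its regulators — but Boolean models cannot express
intermediate expression levels, continuous transitions, or different
time-scales. `boolcube` bridges the gap: it converts a Boolean model into
a system of ordinary differential equations whose qualitative behaviour
(in particular its steady-state structure) mirrors the discrete model,
while adding a continuous, quantitative phenotype.

Each species $X_i$ with Boolean update function
$B_i(x_{i_1}, \dots, x_{i_d}) \in \{0,1\}$ becomes a continuous variable
$\bar x_i \in [0,1]$ obeying

$$\frac{d\bar x_i}{dt} = \frac{1}{\tau_i}\left(\bar B_i(\bar x_{i_1},
  \dots, \bar x_{i_d}) - \bar x_i\right),$$

an activation term minus first-order decay. The life-time $\tau_i$ sets
the species' time-scale (all times in the package are in units of these
life-times; $\tau_i = 1$ by default). The substance of the method is the
continuous homologue $\bar B_i$ of the Boolean function, available in
three variants:

* **BooleCube** — the unique multilinear interpolation
  $$\bar B(\bar x) = \sum_{c \in \{0,1\}^d} B(c) \prod_{j=1}^{d}
    \left(c_j \bar x_j + (1 - c_j)(1 - \bar x_j)\right),$$
  affine in each coordinate and exact at every corner of the hypercube.
* **HillCube** — the BooleCube evaluated on Hill-transformed inputs
  $f(x) = x^n/(x^n + k^n)$. This adds the sigmoidal, switch-like response
  characteristic of cooperative gene regulation: $n$ measures
  cooperativity (slope), and $k \in (0,1)$ is the threshold at which
  activation is half-maximal — the continuous counterpart of the Boolean
  on/off boundary. Since $f(1) = 1/(1+k^n) < 1$, HillCubes approach the
  Boolean values at the corners without reaching them.
* **normalized HillCube** — each Hill term divided by its value at 1,
  $f(x)/f(1)$, which restores exact corner agreement: every Boolean
  steady state is then an exact equilibrium of the continuous system
  (method tag `hillcubenorm`, the package default).

For large Hill exponents the Hill-based systems have a stable steady
state in the neighbourhood of each Boolean steady state; the test suite
exercises this steep-limit property at $n = 100$ on random networks.

## Model representation and parsing

A model is a species list plus at most one update rule per species. Rules
are stored as truth tables ("hypercubes with edge length 2"): an ordered
input list and a $2^d$ binary table. The table index order is fixed —
first input slowest-varying — so serialized tables are portable. Work
with any of:

* equation text, one `Name = expression` line per rule with `&&`, `||`,
  `~` (aliases `AND`/`OR`/`NOT`, `&`/`|`/`!`), parentheses and literals
  0/1. Precedence is NOT > AND > OR with left-associativity; the
  choice is conventional (matching most programming languages) and
  parentheses always override it.
* GraphML interaction graphs (edge attribute `sign` ∈ {`+`,`-`}), where
  multiple regulators combine through the generic logic
  $(A_1 \ominus \dots \ominus A_m) \odot \lnot(I_1 \otimes \dots \otimes
  I_n)$ with configurable connectives; the default
  ($\ominus = \lor, \odot = \land, \otimes = \lor$) reads "on iff at
  least one activator and no inhibitor is active". A factor listed as
  both activator and inhibitor stays in both lists — deduplicating would
  silently change the logic. Nodes labelled `&` build sum-of-products
  hypergraph rules for arbitrary Boolean functions.
* the native JSON format (lossless round trip of species, tables,
  parameters and compartment flags).

Species that never appear on a left-hand side are *constant inputs*:
their Boolean value never changes and their derivative is pinned to 0.
This lets graphs with source nodes convert without inventing
self-activation; the alternative (first-order decay to 0) is available
via `decay_inputs = TRUE`. Rule in-degree is capped (default 16,
configurable) because table size and conversion cost grow as $2^d$.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| $n$ | Hill coefficient (cooperativity, slope) per interaction | — | 3 |
| $k$ | half-activation threshold per interaction | fraction of maximal level | 0.5 |
| $\tau_i$ | life-time of species $i$ | time | 1 |

Defaults follow `default_parameters()`; individual interactions are
overridden with `set_hill()` / `set_tau()`, keyed by the
(target, input) pair so the same regulator can act with different
kinetics on different targets. When a vector field is built with an
incomplete parameter set, missing entries are filled from the defaults
with a warning rather than an error — convenient for quick exploration,
loud enough not to pass silently.

## Discrete and continuous analysis

Synchronous Boolean analysis enumerates all $2^N$ states (N ≤ 22 by
default): steady states, the deterministic state-transition graph
(out-degree exactly 1), and all attractors — terminal cycles found by
path-following, cross-checked in the tests against brute-force step
iteration. Reported states are in lexicographic order to make outputs
deterministic.

Continuous analysis integrates the assembled vector field with
`deSolve::ode` (lsoda, relative tolerance $10^{-6}$). Stable-state
discovery (`find_stable_states`) integrates a set of initial conditions
(default: the uniform 11×11 grid on $[0,1]^2$ for phase-plane work) to a
horizon `t_end`, keeps endpoints whose derivative $\infty$-norm is below
$10^{-6}$, merges them by single-linkage clustering in the
$L_\infty$ metric at tolerance $10^{-2}$ (coarse enough to absorb solver
jitter, fine enough to separate corner attractors), and reports cluster
means as representatives with per-initial-condition basin labels.

Two numerical choices deserve explanation:

* **Convergence is derivative-based, not displacement-based**: slow
  transients near saddle points would otherwise masquerade as
  convergence. Inside `find_stable_states` the solver runs at tightened
  tolerances (rtol $10^{-8}$, atol $10^{-10}$) so that the endpoint
  residual stays well below the convergence criterion.
* **Stability classification.** A deterministic grid contains points
  lying exactly on symmetry axes (e.g. the diagonal of a toggle switch),
  and trajectories started there converge to saddle points — genuine
  equilibria that are not stable states. Each representative is therefore
  classified by the eigenvalues of a central-difference Jacobian: stable
  iff every real part is ≤ $10^{-6}$. Neutral directions count as stable,
  so degenerate fields whose every point is an equilibrium (e.g. the
  BooleCube of the identity rule) keep all their representatives.

With the defaults, both wirings of the mutual inhibitory switch (OR
logic `X = X || ~Y`, `Y = Y || ~X`, and the corresponding AND logic)
yield three stable continuous steady states, each adjacent to one
Boolean steady state — the two committed lineages plus a third state
(co-expression for OR, all-off for AND).

In the sensitive self-activation regime (all $n = 2$ for dimer binding,
self-activation $k = 0.01$, inhibition $k = 0.5$), the AND switch
converted with the *non-normalized* HillCube reproduces the phase
portrait of a mechanistic reaction-based model of the same motif: two
symmetric co-expression states (both factors above 0.1) plus the trivial
origin, reached only from initial conditions below the self-activation
threshold. The interior pair exists only for the non-normalized
conversion — normalized Hill terms reach exactly 1, which collapses those
states onto the axes — and its eigenvalues are $O(10^{-3})$, so the
analysis integrates to $t_\mathrm{end} = 3000$ life-times there instead
of the default 50.

## Multicompartment models and pattern screening

`expand_multicompartment()` turns a single-cell model into a linear,
non-periodic row of C compartments with copies `S_c` of every species.
Species flagged *intercompartmental* model secreted factors: wherever a
flagged species feeds a rule, compartment c instead reads the OR of the
copies in the adjacent compartments c−1 and c+1 (one neighbour at the row
ends). The compartment's own copy is excluded by default — a secreted
factor acts on its neighbours — with `include_self = TRUE` for the
inclusive variant, since either convention is defensible. A four-species
boundary-maintenance network (Otx2/Gbx2 mutual inhibition, Wnt1/Fgf8
cross-compartment mutual dependence) expanded to six compartments gives
the expected 6·4 = 24 coupled equations.

`pattern_is_maintained()` is the model-selection predicate: embed a
target on/off pattern as a continuous state, integrate (default 20
life-times, enough for the default kinetics to settle by several decay
times), threshold each species at its Hill threshold (global 0.5 by
default, or per-species mean incoming $k$), and require the pattern to be
reproduced exactly. `screen_models()` maps the predicate over a candidate
ensemble. The published screen of curated vs. random boundary networks
cannot be reproduced verbatim — the curated rule sets and the original
random pool are not printed — so the suite exercises the predicate on
constructed fixtures: hand-validated boundary networks (which all pass)
against `random_boolean_model()` ensembles (which essentially never do).

## The random-model generator

`random_boolean_model(n_species, max_indegree, seed)` draws, per species,
an in-degree uniform on {0, …, max_indegree}, a uniform sample of
distinct inputs, and a uniform random truth table. It emulates the
"arbitrarily chosen regulatory network" null ensemble of model-selection
screens. It does **not** emulate the statistics of real regulatory
networks — no degree-distribution skew, no enrichment for canalizing or
monotone functions, no sparsity structure — so a pass rate against this
ensemble says how selective a pattern is against unstructured logic, not
against biologically plausible competitors.

## Export

`to_sbml()` writes SBML Level 3 Version 2 using **rate rules, not
reactions**: the converted system is a phenomenological ODE, and encoding
it as mass-action chemistry would misrepresent its semantics. All cube
expressions are emitted fully expanded (corner-sum form over
Hill-transformed inputs) so the file is self-contained for any
SBML-aware simulator; the tests re-integrate exported documents through
an independent MathML reader and match endpoints to $10^{-4}$.
`to_script()` renders the same right-hand sides as runnable R or
MATLAB/Octave scripts through pluggable text templates. Models persist in
a native JSON format, and a thin command-line front end
(`inst/cli/boolcube.R`) exposes conversion, analysis and export as shell
subcommands.

## Problem sizes and limitations

The test suite runs at desk scale: random-network properties use 50–200
replicates with N ≤ 6 species and in-degree ≤ 4; continuous analyses use
the 11×11 phase grid; the steep-limit fixed-point property uses $n =
100$ on 50 random models; the screening example uses tens of random
candidates. These sizes were chosen to pin the mathematical properties,
not to benchmark throughput.

Known limitations:

* Only synchronous Boolean updating is implemented; asynchronous schemes
  are out of scope.
* Exhaustive enumeration bounds discrete analysis at $2^N$ states;
  there is no sampling-based attractor search for large N.
* Stable-state discovery sees only what its initial conditions reach;
  it is not a continuation or bifurcation method.
* Compartment rows are 1-D and non-periodic, with identical parameters
  in every compartment; there is no diffusion term.
* Parameter fitting to data is out of scope; parameters express
  hypotheses, not estimates.
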