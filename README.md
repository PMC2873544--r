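# boolcube

Convert qualitative Boolean models of gene regulation into continuous
ODE systems — and analyze both.

## Who this is for

Systems biologists often know *that* A activates B and C represses it,
without rate constants. That knowledge fits a Boolean network: N species
`X_1..X_N`, each on/off, each updated synchronously by a logical function
`B_i` of its regulators. `boolcube` turns such a model into a system of
ordinary differential equations so that intermediate levels, continuous
transitions and time-scales become accessible, while the qualitative
structure (notably the steady states) is preserved.

## The method

Each species becomes a continuous variable `x_i ∈ [0,1]` with

    dx_i/dt = ( B̄_i(x_i1, ..., x_id) - x_i ) / τ_i

where `τ_i` is the species' life-time and `B̄_i` a continuous homologue
of the Boolean update function, in one of three forms:

* **BooleCube** — the multilinear interpolation of the truth table,
  `B̄(x) = Σ_{c∈{0,1}^d} B(c) Π_j (c_j x_j + (1-c_j)(1-x_j))`,
  exact at every corner of the unit hypercube;
* **HillCube** — the BooleCube over Hill-transformed inputs
  `f(x) = x^n/(x^n + k^n)` (cooperativity `n`, half-activation
  threshold `k`), adding the sigmoidal response of real gene regulation;
* **normalized HillCube** — Hill terms rescaled by `f(1)`, restoring
  exact corner agreement so that every Boolean steady state is an exact
  equilibrium of the ODE (the default, tag `hillcubenorm`).

Models are written as Boolean equation text, imported from GraphML
interaction graphs/hypergraphs, or built at random; analysis covers
Boolean steady states, state-transition graphs and attractors,
numerical integration, stable-state discovery with basin labels,
linear multicompartment expansion with secreted (intercompartmental)
factors, and an ensemble pattern-maintenance screen. Converted systems
export to SBML (rate rules) and R/MATLAB script files.

## Worked example: the mutual inhibitory switch

Two factors, each self-activating and repressing the other — the classic
stem-cell lineage-decision motif:

```r
library(boolcube)

m <- parse_boolean_equations("X = X || ~Y\nY = Y || ~X")
boolean_steady_states(m)
#>      X Y
#> [1,] 0 1
#> [2,] 1 0
#> [3,] 1 1

vf <- build_vector_field(m, "hillcubenorm")   # n = 3, k = 0.5, tau = 1
find_stable_states(vf, phase_grid(11))
#> Stable-state analysis: 121 initial conditions, 3 equilibria (3 stable)
#>      X Y stable basin_size
#> [1,] 0 1      1         31
#> [2,] 1 0      1         31
#> [3,] 1 1      1         59
```

The three Boolean steady states — the two committed lineages (1,0)/(0,1)
and the co-expression "priming" state (1,1) — persist as the three stable
continuous steady states, and the basin sizes quantify how much of the
unit square commits to each fate. A single trajectory shows the
continuous dynamics:

```r
tr <- integrate_field(vf, c(0.9, 0.1), t_end = 10)
tail(tr$states, 1)
#>        X Y
#> [201,] 1 0
```

A state starting X-dominant commits fully to the X lineage.

## Command-line use

A thin CLI over the package functions lives at `inst/cli/boolcube.R`
(after installation: `system.file("cli", "boolcube.R", package =
"boolcube")`), with subcommands `convert`, `steadystates`, `stg`,
`expand`, `simulate`, `basins`, `select` and `export`. Example:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/boolcube.R", package="boolcube"))')" \
  simulate model.json --method hillcubenorm --t-end 20 --x0 0.9,0.1 --out traj.csv
```

See `vignettes/boolean-to-ode.Rmd` for the full account of the method,
parameter meanings, numerical choices and limitations.
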