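# fockpop

Operatorial (fermionic Fock-space) lattice model of coupled human
population and natural-resource densities, with resource-driven migration
and conflict between neighbouring cells. The package is aimed at
quantitative ecologists and archaeodemographers who want to reproduce and
probe the mechanism by which *migration plus conflict* turns incoherent
local population cycles into large synchronized oscillations of the
global density around a carrying capacity — the regime reconstructed for
pre-agricultural South America from summed calibrated radiocarbon date
densities.

## The model in one paragraph

Each cell `α` of an `L × L` lattice carries two fermionic modes, humans
`a_α` and resources `b_α`, obeying the canonical anticommutation
relations, so each local density `n_α = ⟨Ψ, a†_α a_α Ψ⟩ = ‖a_α Ψ‖²`
lives in `[0, 1]`. The state evolves by `i ∂_t Ψ = H(Ψ) Ψ` with

```
H = Σ_α [ ω^a_α a†_α a_α + ω^b_α b†_α b_α + λ_α (a†_α b_α + b†_α a_α) ]
  + Σ_<αβ> p γ_αβ (a_α a†_β + a_β a†_α)
```

where every coefficient is a fixed function of the local resource/human
ratio `K_α = n^b_α / n^a_α` (σ = 12.5, τ = 0.35, μ = 0.25, p = 1 for the
published fit):

```
ω^a = σ [exp(−(K − 1/τ)²) K]^{1/2}      (human inertia, high when resources abound)
ω^b = σ [exp(−(K/τ)²) / K]^{1/2}        (resource inertia, high when resources are scarce)
λ   = ω^a + ω^b + μ                     (predator–prey exchange)
γ_αβ = ω^b(K_α) + ω^b(K_β)              (migration strength on the edge α–β)
```

`H = H†` conserves `‖Ψ‖` and the global `n^a + n^b`, whose half is the
carrying capacity `K` around which the global human density oscillates.
The initialization places every cell at the carrying capacity: per-cell
human densities jittered ±10% around `K/L²` (summing to `K` exactly),
resources complementary.

## Worked example

```r
library(fockpop)

params  <- model_params()                       # published parameter set
lattice <- lattice_spec(3, boundary = "periodic")
init    <- init_spec(K_total = 0.5, seed = 1)

# migration scenario: full Fock-space dynamics (dimension 4^9 = 262144)
mig <- run_scenario("migration", params, lattice, init,
                    horizon = 15, dt = 1e-3)

# no-migration scenario: exact decoupled per-cell fast path
nomig <- run_scenario("no_migration", params, 9, init,
                      horizon = 15, dt = 1e-3)

oscillation_interval(mig)[c("min_ratio", "max_ratio")]
#> $min_ratio
#> [1] 0.7216895
#> $max_ratio
#> [1] 1.357136

oscillation_interval(nomig)[c("min_ratio", "max_ratio")]
#> $min_ratio
#> [1] 1.009523
#> $max_ratio
#> [1] 1.182932

conservation_check(mig)$max_conservation_dev
#> [1] 2.7e-06    # global n_a + n_b conserved to integration accuracy
```

The migration run's global human density sweeps roughly `0.7 K` to
`1.4 K` — large synchronized oscillations; without migration the global
curve stays within a few percent of its mean, and flattens further as
cells are added:

```r
trs <- lapply(c(9, 100, 1000), function(m)
  run_scenario("no_migration", params, m, init, horizon = 15, dt = 1e-3))
smoothing_metric(trs)       # std of global density/K, decreasing in cells
```

A synthetic reference curve with prescribed extremes stands in for an
empirical demographic reconstruction in the comparison statistics:

```r
ref <- make_reference_fixture(K_ref = 0.185, min_ratio = 0.70, max_ratio = 1.57)
compare_reference(mig, ref)$interval_diff
```

A thin command-line front end ships in `inst/cli/fockpop.R`
(`simulate`, `sweep`, `analyze`, `fixture` subcommands over YAML configs;
presets in `config_preset()`).

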