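# fluxness

Non-equilibrium steady states (NESS) of chemical reaction networks from a
variational principle, for systems-biology modellers and statistical
physicists working with stoichiometric models.

A reactor with M species and N reactions is described by stoichiometric
coefficients ξ^μ_i (negative = substrate, positive = product), reference
concentrations c̄_μ, boundary exchange rates u^μ (positive = intake) and
bounded reaction fluxes |ν_i| ≤ q^max_i. Over time scales on which chemical
potentials drift slowly, the stationary fluxes minimize

    H(ν) = Σ_μ (Σ_i ξ^μ_i ν_i + u^μ)² / c̄_μ
         = νᵀJν + 2hᵀν + const,      J_ij = Σ_μ ξ^μ_i ξ^μ_j / c̄_μ

— a Hopfield-type quadratic form with Hebbian couplings in which reactions
interact through shared metabolites, competing for scarce substrates. H is
zero exactly at mass balance (the flux-balance condition) and equals, up to
units, the rate at which entropy production decays in the steady state.

The package provides:

- **netio** — a plain-text TSV network format (species and reaction tables,
  formula strings like `"GLC + ATP -> G6P + ADP"`), reader/writer/validator
  (`read_network()`, `write_network()`, `validate_network()`).
- **coupling** — the quadratic form (`build_couplings()`, `hamiltonian()`,
  `balance_residuals()`).
- **dynamics** — a stochastic resource-allocation dynamics that realizes the
  minimization: each reaction samples a direction m_i = ±1 with
  P(+) = (1 + tanh y_i)/2 and the scores y descend the gradient of H
  (`simulate_dynamics()`, with an RcppArmadillo core), plus flux estimation,
  bidirectional/frozen classification and the Gibbs-energy link
  ΔG = −2RT·y (`estimate_fluxes()`, `classify_reactions()`,
  `deltaG_from_y()`).
- **ensemble** — random-network ensembles and the ergodicity-breaking phase
  transition in the ratio n = N/M (`phase_sweep()`,
  `estimate_critical_point()`, `autoplot()`).
- **stability** — linear stability of the bidirectional sector against the
  Marchenko–Pastur spectral edge σ²(1 − √r)² (`bidirectional_spectrum()`,
  `stability_verdict()`).
- **steady_state** — direct box-constrained minimization of H, the affine
  structure of the balanced-solution set, minimum-norm loop removal, and a
  thermodynamic-feasibility certificate via the Gordan alternative
  (`minimize_hamiltonian()`, `solution_space()`, `minimize_flux_norm()`,
  `check_thermo_feasibility()`).
- **thermo** — Gibbs energies, flux ratios, entropy production and its decay
  rate −R·H, perturbation free energies (`gibbs_energy()`,
  `entropy_production()`, `entropy_decay_check()`).
- **hrbc** — a reduced human red-blood-cell model (30 metabolites, 23
  reactions; glycolysis + pentose phosphate pathway + Rapoport-Leubering
  shunt + two pumps) with an exactly three-dimensional steady-state flux
  space and a closed-form optimum for the glucose partition between
  glycolysis and the PPP (`load_hrbc_network()`, `optimal_g6pdh()`,
  `ppp_fraction_bounds()`).

Results are tibbles or small S3 objects with broom-style `tidy()`/`glance()`
methods and ggplot2 `autoplot()` views.

## Worked example

A minimal driven reactor — species A (c̄ = 1) supplied at rate 0.5,
converted by one reaction into B (c̄ = 2) which is drained at the same rate:

```r
library(fluxness)

net <- reaction_network(
  species   = tibble::tibble(id = c("A", "B"), cbar = c(1, 2),
                             u = c(0.5, -0.5), is_boundary = TRUE),
  reactions = tibble::tibble(id = "R1", stoich = "A -> B", qmax = 1))

tidy(minimize_hamiltonian(net))
#> # A tibble: 1 × 3
#>   reaction  flux at_bound
#>   <chr>    <dbl> <lgl>
#> 1 R1         0.5 FALSE

tr <- simulate_dynamics(net, steps = 2e4, eta = 0.1, seed = 1, rescale = 1)
estimate_fluxes(tr, net)
#> # A tibble: 1 × 2
#>   reaction  flux
#>   <chr>    <dbl>
#> 1 R1         0.5

deltaG_from_y(tr, R = 1, T_abs = 1)
#> # A tibble: 1 × 3
#>   reaction     y delta_G
#>   <chr>    <dbl>   <dbl>
#> 1 R1       0.600   -1.20
```

Both routes agree: the unique steady state carries flux 0.5 through R1
(exactly balancing supply and drain, so H = 0), the reaction stays
bidirectional, and its score fluctuates around atanh(0.5) ≈ 0.549, i.e. a
driving force ΔG ≈ −1.1 RT — the reaction runs forward, downhill.

The red-cell case study, from the bundled command-line tool:

```sh
Rscript inst/cli/fluxness hrbc --uglc 1 --udpgm 0.5
#> u_g6pdh* = 1.12808 (a = 1.2950, b = -0.3338), F = 0.1880 in [0.1176, 0.2158]
```

At typical blood concentrations the optimal pentose-phosphate flux is
u* = a·u_glc + b·u_dpgm with a = 1.295 and b = −0.334, and the fraction of
glucose carbon routed through the PPP ranges from F = 0.118 (maximal
2,3-DPG shunt flux) to F = 0.216 (no shunt flux); raising ambient CO2 pushes
the optimum toward F = 1, where the PPP consumes all six glucose carbons.

The same executable exposes `simulate`, `sweep`, `minimize`, `stability` and
`feasible` subcommands; every run writes its parameters and seed to a JSON
manifest, and a flat TOML config file can supply defaults.

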