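---
title: "A variational principle for non-equilibrium steady states of reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A variational principle for non-equilibrium steady states of reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxness)
```

## The model

Consider a well-mixed reactor with $M$ chemical species and $N$ reactions.
Stoichiometric coefficients $\xi^\mu_i$ are signed (negative = substrate,
positive = product in the forward direction), species $\mu$ carries a
reference concentration $\bar c_\mu > 0$ and a boundary exchange rate $u^\mu$
(positive = net intake), and reaction $i$ carries a net flux $\nu_i$ — the
average number of microscopic transitions per time per volume — bounded by
enzyme availability, $|\nu_i| \le q^{max}_i$.

Over time scales on which chemical potentials vary slowly (so concentrations
can be frozen at $\bar c_\mu$), the stationary fluxes minimize

$$
H(\nu) \;=\; \sum_\mu \frac{1}{\bar c_\mu}
  \Big( \sum_i \xi^\mu_i \nu_i + u^\mu \Big)^2
\;=\; \nu^{T} J \nu + 2 h^{T} \nu + \text{const},
\qquad
J_{ij} = \sum_\mu \frac{\xi^\mu_i \xi^\mu_j}{\bar c_\mu},
\quad
h_i = \sum_\mu \frac{\xi^\mu_i u^\mu}{\bar c_\mu}.
$$

`H` is a concentration-weighted sum of squared per-species imbalances: it is
zero exactly at mass balance (the flux-balance condition
$\sum_i \xi^\mu_i \nu_i + u^\mu = 0$ for every species), and positive
otherwise. The quadratic form is a Hopfield-type Hamiltonian with Hebbian
couplings: two reactions interact exactly when they share a species,
cooperatively (negative $J_{ij}$) when one produces what the other consumes,
competitively (positive $J_{ij}$) when they compete for or jointly flood the
same compound, with interaction strength inversely proportional to the
compound's abundance. Whether $\min H = 0$ is attainable depends on the
network, the bounds and the boundary fluxes: the exact-balance regime recovers
flux balance analysis, while $\min H > 0$ states satisfy the weaker
net-production inequalities familiar from Von Neumann-type growth models.

We include the constant term $\sum_\mu (u^\mu)^2/\bar c_\mu$ in `H` so that
the quadratic form and the residual form agree exactly; the global prefactor
of `H` is set to one. Both choices are inert: rescaling `H` by any positive
constant changes neither its minimizers nor the location of the phase
transition discussed below.

## The stochastic resource-allocation dynamics

Each reaction carries a score (accumulator) $y_i$; at each discrete step every
reaction samples a direction $m_i \in \{-1, +1\}$ with

$$
P(m_i = +1) = \frac{1 + \tanh y_i}{2}
\qquad\Longleftrightarrow\qquad
\frac{P(+)}{P(-)} = e^{2 y_i},
$$

and the scores then move against the (sampled) gradient of `H`:

$$
y_i \leftarrow y_i - \eta\, \rho \Big( \sum_j J_{ij} m_j + h_i \Big),
$$

with learning rate $\eta$ (default 1) and rescale factor $\rho$ (default
$1/M$, which keeps the drift $O(1)$ as networks grow). The probability ratio
$e^{2y_i}$ plays the role of the substrate-to-product concentration ratio, so
$y_i$ is directly a thermodynamic driving force: detailed balance identifies
$\Delta G_i = -2 R T\, y_i$ (see `deltaG_from_y()` and `flux_ratio()`).

Two asymptotic behaviors occur. If $y_i$ stays bounded, both microscopic
directions keep occurring — the reaction is *bidirectional* — and its mean
flux is pinned by the zero-gradient condition $(J\nu + h)_i = 0$. If $y_i$
drifts linearly, the reaction *freezes* into unidirectional operation
($\nu_i = \pm 1$, the box bound). The fraction $\phi$ of frozen reactions is
the order parameter of the ensemble experiments. The time-averaged sampled
directions estimate the fluxes; because the accumulator integrates the
gradient, the running flux average converges at rate $1/T$ (not the
Monte-Carlo $1/\sqrt T$) wherever the accumulators stay bounded.

The mean-field variant (`stochastic = FALSE`) replaces $m$ by $\tanh y$ and is
the deterministic skeleton of the dynamics; it serves as the oracle for the
stochastic runs in the test suite.

Numerical choices: accumulators are clipped at $|y| = 500$ ($\tanh$ saturates
to machine precision near $|y| \approx 19$, so clipping only prevents
overflow); 256 geometrically spaced checkpoints record the transient and the
asymptotic growth; the burn-in discarded before flux averaging defaults to the
first half of the run. The classifier calls a reaction frozen when its
accumulator either sits on the clipping rail or has moved, over the second
half of the run, by more than `eps_slope` per step *per unit* $\eta\rho$ —
i.e. when the mean gradient it felt exceeds `eps_slope` (default $10^{-2}$).
Expressing the slope in gradient units makes the threshold independent of
$\eta$, $\rho$ and $M$; it coincides with the raw slope when
$\eta\rho = 1$.

## Random ensembles and the ergodicity-breaking transition

The ensemble (`ensemble_spec()`) draws $\xi^\mu_i = \pm 1$ each with
probability $p/2$ (0 otherwise), makes each species a boundary species with
probability $q$ with uniform intake $b_0$, and sets
$\bar c = q^{max} = V = \Delta t = 1$. The symmetric $\pm 1$ choice keeps the
entries zero-mean, as the spectral theory assumes; $b_0$ only scales `H` in
the unbalanced phase and does not move the transition.

A counting argument locates the transition: the balance conditions pin the
$N_{bid}$ bidirectional fluxes through at most $M$ independent linear
equations, so when $N_{bid} > M$ the balanced set is under-constrained,
multiple steady states coexist, and the initial condition selects among them
— ergodicity breaks. The package measures, as a function of $n = N/M$: the
ensemble average of $H/M$, the frozen fraction $\phi$, and
$n_{bid} = n(1-\phi)$. The two estimators of the critical ratio — where
$\langle H \rangle$ vanishes and where $n_{bid}$ crosses 1 — agree within one
grid step (`estimate_critical_point()`). Ergodicity is probed by comparing an
unbiased start ($y_0 = 0$) with a polarized one ($y_0 = +5$, i.e.
$\langle m \rangle \approx 0.9999$); any strongly polarized start serves, and
the same network realizations are used for both starts so the comparison is
paired.

Default study conditions: $M = 50$, $p = 0.25$, $q = 0.5$, $b_0 = 1$,
$T = 2\times 10^4$ steps, 20 realizations per grid point, 11 ratios
$n \in [0.25, 4]$. These keep the full sweep under a minute of computing while
leaving both phases and the crossover well resolved; a larger-scale run (200
realizations, as in the original ensemble experiments) is available through
`reps = 200`.

```{r, eval = FALSE}
spec <- ensemble_spec(M = 50, p = 0.25, q = 0.5, b0 = 1, reps = 20)
sw <- phase_sweep(spec, n_grid = seq(0.25, 4, length.out = 11), seed = 1)
estimate_critical_point(sw)
autoplot(sw)
```

What the generator does *not* emulate: real stoichiometries are sparse with
heavy-tailed degree sequences, coefficients beyond $\pm 1$, and correlated
pathway structure; reaction time scales are heterogeneous (Arrhenius), while
here every reaction attempts a transition every step; and molecular noise at
low copy number is outside the frozen-concentration approximation. Passing
ensemble tests therefore validates the mechanism (constraint counting,
freezing, loss of ergodicity), not quantitative predictions for any
particular organism.

## Linear stability and the spectral edge

Linearizing the dynamics around a steady state, frozen reactions are
insensitive to perturbations and the bidirectional sector relaxes through the
restricted Gram matrix $K_{ij} = \frac1M \sum_\mu \xi^\mu_i \xi^\mu_j /
\bar c_\mu$ (times a positive diagonal factor from the $\tanh$ derivative,
which cannot flip eigenvalue signs and is therefore ignored in the verdict).
For i.i.d. entries of variance $\sigma^2$ the smallest eigenvalue approaches
the Marchenko–Pastur edge $\sigma^2 (1 - \sqrt r)^2$ at aspect ratio
$r = N_{bid}/M$: positive for $r < 1$ (stable, ergodic), zero at $r = 1$
(marginal — the same condition as the counting argument), and the Gram matrix
is singular for $r > 1$. `bidirectional_spectrum()` estimates $\sigma^2$ from
the network when it is not the standard ensemble; eigenvalues below
$10^{-10}$ in magnitude are treated as zero.

## Direct minimization, loop removal, feasibility

`minimize_hamiltonian()` solves the box-constrained convex QP with an
accelerated projected-gradient phase (step $1/L$, $L = 2\lambda_{max}(J)$,
restart on objective increase) polished by exact coordinate minimization;
convexity makes any KKT point a global minimum, so the grid-search oracle in
the tests checks optimality, not luck. Defaults: start at 0, iteration cap
$10^5$, tolerance $10^{-10}(1 + \|h\|_\infty)$ on the projected gradient.
Flux bounds are symmetric $[-q^{max}, q^{max}]$; a priori irreversibility is
expressed by setting one bound to zero, but none is assumed by default.

Any two minimizers differ by a stoichiometric null vector (the difference
lies in $\ker J = \ker S$ and is automatically $h$-orthogonal), so the
minimizer set is the affine space through one solution intersected with the
box. `minimize_flux_norm()` projects the origin onto that intersection with
Dykstra's alternating projections: the result is the unique minimum-norm
steady state, with every mass-balance residual — hence `H` — unchanged.

`check_thermo_feasibility()` implements the Gordan alternative: either
species potentials $g$ exist making every active reaction strictly downhill
($(\xi^T g)_i\,\mathrm{sign}(\nu_i) < 0$), or the flux configuration contains
a stoichiometrically closed cycle with matching signs — an infeasible loop
that the norm minimization is guaranteed to remove (shifting against a cycle
lowers the norm without touching the residuals). The search is a minimum-norm
point computation over the convex hull of the signed stoichiometric rows
(accelerated projected gradient on the simplex): a positive distance yields
the separating potentials, a vanishing one yields the cycle weights, which
are then polished by exact projection onto the null space of the supporting
columns. Strictness is enforced by a relative margin ($10^{-6}$ at
$\|g\|_\infty = 1$); fluxes below $10^{-8}\max(1, \|\nu\|_\infty)$ count as
zero and are excluded.

## Thermodynamics

With ideal dilute chemical potentials, the Gibbs energy of reaction $i$ is
$\Delta G_i = \Delta G^0_i + RT \sum_\mu \xi^\mu_i \ln (c_\mu/c_0)$ and
detailed balance gives the forward/reverse flux ratio
$e^{-\Delta G_i/RT}$. The reaction entropy production is
$\sigma = -\frac1T \sum_i \nu_i \Delta G_i \ge 0$ for feasible states. In a
steady state with residuals $r_\mu$, concentrations drift as
$\dot c_\mu = r_\mu$, and the *full* entropy production (reaction plus
boundary-exchange terms, $T\sigma = -\sum_\mu \mu_\mu r_\mu$) decays at rate

$$
\frac{d\sigma}{dt} = -R \sum_\mu \frac{r_\mu^2}{c_\mu} = -R\,H .
$$

Balanced steady states therefore hold entropy production constant, while
unbalanced ones dissipate at a rate that decreases as slowly as the
constraints allow — `H` is the decay rate of entropy production. In the
notation $d\sigma/dt = -\kappa H/T$ the self-consistent constant is
$\kappa = R\,T$; `entropy_decay_check()` keeps $\kappa$ as an argument and
reports the empirically measured ratio rather than asserting the constant,
since the proportionality depends on the (convention-dependent) prefactor of
`H`. The finite-difference window is capped at a 1% concentration change so
the linearization error stays well inside the reported ratio.

Perturbing an equilibrated closed system by forcing fluxes $\delta\nu$ for a
time $\tau$ raises the free energy per volume by
$\frac{RT\tau^2}{2} H_0(\delta\nu) \ge 0$ with $H_0$ the closed-system `H` —
the second law in quadratic form, and the sense in which minimizing `H`
during relaxation is Gibbs' stability argument made dynamical.

The accumulator link $\Delta G = -2RTy$ is validated in the tests at the
sampling level (the empirical direction frequencies reproduce
$P(+)/P(-) = e^{2y}$) and through the closed-form entropy-decay ratio on the
one-reaction reactor; a full co-simulation of drifting concentrations is
outside the frozen-concentration approximation that defines the model.

## The red-blood-cell case study

The packaged network is a reconstruction of the standard reduced human
erythrocyte model: glycolysis, the pentose phosphate pathway (PPP), the
Rapoport-Leubering shunt, and two effective pumps (Na/K-ATPase and NADPHase,
the glutathione-reductase load) — 30 metabolites, 23 reactions, with
extracellular glucose, lactate, K, Na and CO2 as the five boundary species.
Species concentrations are textbook physiological values; water and protons
are omitted as usual in reduced stoichiometric models. In the ATPase row the
ion species denote the extracellular-facing pools (per ATP: two K consumed
from the medium, three Na returned to it), which makes the uniform exchange
formula $\dot x_s = \sum_i \xi^s_i \nu_i$ reproduce the physical pump
direction.

Imposing exact balance on the 25 intracellular metabolites leaves exactly
three degrees of freedom, chosen as glucose uptake $u_{glc}$, the shunt flux
$u_{dpgm}$, and the PPP commitment flux $u_{g6pdh}$; `hrbc_free_flux_basis()`
constructs the linear map to all 23 fluxes from the null space of the
internal stoichiometric matrix. Carbon is conserved by construction:
$6\,u_{glc} = 3\,\dot x_{LAC} + \dot x_{CO_2}$.

The extracellular medium defines its own variational function
$H_{ext} = \sum_s \dot x_s^2 / x_s$ over the five boundary species.
Minimizing it over $u_{g6pdh}$ at fixed uptake and shunt flux is exactly
solvable: $u^*_{g6pdh} = a\,u_{glc} + b\,u_{dpgm}$ with

$$
a = \frac{2/(3 x_{LAC}) + 2W/3}{D},\qquad
b = -\frac{W/3}{D},\qquad
W = \frac{4}{x_K} + \frac{9}{x_{Na}},\quad
D = \frac{1}{9 x_{LAC}} + \frac{1}{x_{CO_2}} + \frac{W}{9}.
$$

Both are ratios of quadratic-form coefficients and hence invariant under a
common rescaling of the concentrations. As $x_{CO_2}$ grows, $a \to 6$: the
PPP consumes essentially all the glucose, 6 being the carbon count of
glucose. The glucose partition fraction is $F = u_{g6pdh}/(6 u_{glc})$.

Two design decisions were genuinely open. First, the admissible operating
regime: we constrain only the physically one-way steps (uptake, the two
committed branch entries, lactate export, the pumps; `hrbc_forward_only()`),
leaving the near-equilibrium interconversions free to reverse — full PPP
recycling *requires* phosphoglucose isomerase and the PFK-level step to run
backwards, and only under this weaker set does the maximal CO2:glucose ratio
reach its carbon-stoichiometric value of 6. Second, the bounds on $F$:
$u_{dpgm}$ is swept from 0 to the largest value keeping the one-way steps
forward (the ATPase constraint binds), with $u_{g6pdh}$ at its optimum
throughout; since $b < 0$, $F_{max}$ occurs at zero shunt flux and $F_{min}$
at the shunt maximum. With the default blood concentrations (GLC 5 mM, LAC
1 mM, K 4 mM, Na 140 mM, CO2 1.2 mM) the package computes $a = 1.295$,
$b = -0.334$ and $F \in [0.118, 0.216]$ — the arterial-blood operating point
of an unstressed cell sits near the lower end, and raising ambient CO2 (the
oxidative-stress proxy in this reduced description) pushes the optimum
monotonically toward the PPP.

```{r, eval = FALSE}
env <- rbc_environment()
optimal_g6pdh(1, 0, env)
ppp_fraction_bounds(env)
hrbc_max_co2_ratio()
```

Because the supplementary concentration table of the original reduced model
is not distributed with the package sources, the fixture's concentrations are
stated physiological estimates; all structural claims (cardinalities, rank,
carbon factor) are independent of them, and the $(a, b, F)$ values above are
functions of the five extracellular concentrations only.

## Problem sizes used by the test suite

Module tests run on toy reactors ($M \le 8$) and small ensembles. The
end-to-end suite uses: the full sweep at the default study conditions above
(about a minute); 50 random box-QPs with $N \le 3$ against a nested refining
grid search reaching $10^{-3}$ resolution; 100 random environments for the
closed-form/numeric red-cell optimum (agreement $10^{-8}$); one $M = 400$,
$r = 0.5$ Gram spectrum against the Marchenko–Pastur edge (15% band, which at
this size also absorbs the finite-size offset); 20 closed reactors
($M = 20$, $T = 10^4$, $\eta = 0.1$) for equilibration; 50 loop-removal +
feasibility rounds; and 10 ergodic-phase consistency checks at $M = 30$,
$n = 0.5$, $T = 5\times 10^4$, $\eta = 0.1$ with tolerance 0.05 on
$\|\hat\nu - \nu^*\|_\infty$ (the residual stochastic bias is $O(\eta\rho)$,
an order of magnitude below that tolerance).

## Known limitations

Concentrations are parameters, not state: the theory holds on time scales
where chemical potentials drift slowly, and the package never integrates the
concentration dynamics. The discrete dynamics forces one attempted transition
per reaction per step, erasing kinetic time-scale heterogeneity; its
continuum (Langevin) limit is deliberately not implemented, as the noise
amplitude is not fixed by the discrete model. The feasibility solver is
iterative: its zero-distance decision uses a threshold
($10^{-5}$ relative) backed by exact cycle refinement, which is robust on the
tested scales but, like any LP-free approach, can in principle stall on
adversarially ill-conditioned inputs. The red-cell model is a reduced
description — no hemoglobin-oxygen binding, no 2,3-DPG feedback, effective
pumps — so its outputs are operating *ranges*, not kinetic predictions.
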