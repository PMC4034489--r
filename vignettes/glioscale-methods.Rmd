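---
title: "Cross-scale glioblastoma growth and multiscale sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-scale glioblastoma growth and multiscale sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`glioscale` simulates glioblastoma growth in a two-dimensional in-vitro-like
region (3 mm x 3 mm, a 200 x 200 lattice whose 15 um spacing matches the
average glioblastoma cell diameter) across three coupled layers:

* **Cellular layer.** Each lattice site holds at most one tumour-cell agent.
  Agents either migrate to an empty neighbouring site, proliferate by
  placing a daughter on an empty neighbouring site, or rest — the
  Go-or-Grow dichotomy. Both movement and daughter placement are
  chemotactic: among the empty Moore neighbours, the one with maximal
  glucose is chosen, ties broken uniformly at random.
* **Microenvironment layer.** Every site carries a glucose concentration
  `x10` (g/L). Glucose is consumed by cells, diffuses with an
  occupancy-dependent diffusivity, and cannot leave the region (no-flux
  boundaries).
* **Molecular layer.** Every cell carries a nine-species signalling state
  `x1`–`x9` (pmol/L): miR-451, MO25 mRNA, the miRNA-bound mRNA complex,
  MO25 protein, the LKB1-STRAD scaffold, phosphorylated AMPK,
  phosphorylated TSC2, active Rheb and active mTORC1. Glucose drives
  miR-451 synthesis; miR-451 represses MO25 translation by sequestering its
  mRNA into a decaying complex; MO25 assembles the scaffold that
  phosphorylates AMPK; AMPK activates TSC2, which inactivates Rheb, which
  in turn is required to activate mTORC1; AMPK also inhibits mTORC1
  directly. The net effect is a nutrient switch: scarce glucose puts AMPK
  high / mTORC1 low (energy stress, migration), abundant glucose the
  reverse (growth, proliferation).

Each macro time step represents one hour. Per step, every cell reads its
site's glucose, integrates its molecular network over the hour, re-decides
its phenotype by comparing AMPK (`x6`) and mTORC1 (`x9`) against calibrated
thresholds, consumption and diffusion update the field, and the agents act
in a freshly shuffled order. A run terminates when the first cell reaches
the lattice boundary and reports four endpoints: the number of steps
`M_time` (inverse expansion speed), and the total / migrating /
proliferating cell counts in the final step (`M_total`, `M_mig`,
`M_prolif`).

## The reconstructed reaction network

The nine rate equations shipped here are a documented canonical
reconstruction assembled from the published species list, reaction-constant
table and interaction diagram of the underlying model family: mass-action
binding for the miR-451/mRNA interaction, Michaelis–Menten
phosphorylation/dephosphorylation (Goldbeter–Koshland) cycles for AMPK,
TSC2 and mTORC1 over conserved pools, first-order constitutive Rheb
activation with TSC2-mediated inactivation, and saturating glucose-driven
miR-451 synthesis. Every one of the 31 perturbable reaction constants
appears in exactly one reaction. The equation bodies sit behind a narrow
interface (`molecular_rhs()`), so a different right-hand side can be
substituted without touching the rest of the package; no claim is made that
these bodies equal the original model's unpublished forms. Two consequences
of the reconstruction are worth knowing:

* MO25 protein (`x4`) has no degradation reaction, so total MO25 grows
  slowly without bound while everything downstream saturates. "Steady
  state" therefore means a fixed relaxation horizon (2e6 s) plus a scaled
  residual check `max |x'| / (1 + |x|) < tol`, not a strict fixed point.
  Using one shared horizon for all glucose levels keeps the steady states
  comparable, which makes the calibrated switch monotone in glucose.
* Over many simulated days the same slow drift gradually raises AMPK in
  every cell, so late in a long run proliferating tumours acquire a
  migratory rim and finish their expansion by invasion — qualitatively the
  energy-stress switch operating on the model's own slow timescale.

## Pools, conversions and thresholds

Conserved pools are `A_tot = T_tot = R_tot = M_tot = 1000` pmol/L and
`S_tot = 500` pmol/L, on the scale of the printed Michaelis constants
(1e2–5e2 pmol/L). Glucose enters the network twice: as
`g * kappa` (pmol/L, `kappa = 5.551e9` pmol/g from the 180.16 g/mol molar
mass) driving miR-451 synthesis, and as the dimensionless `g / 4.5`
saturating the direct AMPK inactivation.

Phenotype thresholds are calibrated once per (baseline) parameter set:
`theta_A` and `theta_M` are midpoints of the AMPK and mTORC1 steady states
at the extreme printed glucose levels 0.3 and 4.5 g/L. At the defaults the
steady states are `x6 = 892 / 402` and `x9 = 479 / 771` pmol/L, giving
`theta_A = 647` and `theta_M = 625`. By construction the low-glucose state
classifies MIGRATING and the high-glucose state PROLIFERATING; conflicting
or sub-threshold signal pairs map to QUIESCENT. Perturbed runs in the
sensitivity sweep deliberately reuse the baseline thresholds: the sweep
should measure network effects, not threshold drift.

# Numerical choices

**Stiffness.** The printed reaction constants span 5e-3 to 1.8e6 in their
respective units; the resulting relaxation rates range from ~5e-3 /s (mRNA
turnover) to ~2e5 /s (AMPK cycle). An explicit fixed-step fourth-order
integrator needs substeps below ~1e-6 s for stability, i.e. billions of
substeps per one-hour macro step — unusable. The package therefore keeps
two integration paths:

* `integrate_cell()`: the classical fixed-step Runge–Kutta scheme, exact
  for the contracts it serves (short horizons, convergence checks,
  non-stiff parameterisations), with post-step clamping to `[0, pool]` and
  a clamp counter.
* `advance_states()` (used by the driver and `steady_state()`): an
  adaptive backward-Euler scheme in compiled code, damped-Newton solves
  with a numerically differenced Jacobian and step doubling on success.
  L-stability lets it cross the hour in a few tens of internal steps per
  cell. Its first-order accuracy is adequate because within a macro step
  each cell sits on the slow manifold of the network; the unit tests pin
  it against `deSolve::lsoda` to 2%.

**Diffusion.** The field update is explicit forward-time centred-space in
conservative finite-volume form: the flux across each site pair is damped
by the harmonic mean of the two sites' occupancy factors (`alpha_occ = 0.5`
on occupied sites), and boundary faces carry no flux. Every interior flux
being antisymmetric, total mass is conserved exactly for arbitrary
occupancy patterns. The earlier-considered alternative — damping a site's
whole Laplacian update — is not conservative; over the thousands of
substeps in a macro step its spurious interface sources grow large enough
to invert the chemotactic gradient around the tumour, which freezes
migration entirely.

The default diffusivity `D = 1.3e-13` m^2/s is an *effective model
parameter*, chosen once so that the field relaxes over roughly two cell
diameters per hourly macro step (`D * dt / dx^2` of order 1). This is the
regime the agent rules presuppose: consumption maintains glucose gradients
on the front scale that chemotaxis can read. A physically aqueous
diffusivity (~1e-10–1e-9 m^2/s) flattens the closed 3 mm dish to within
1e-9 g/L every step, leaving only numerical residue for the agents to
follow. The stability bound `dt <= dx^2/(4D)` is enforced before any
update; the default substep is 90% of it.

**Consumption.** Each occupied site loses `0.18016 * r * weight * dt` g/L
per consumption call (the printed molar uptake rate `r = 1.17e-2` mmol/L/s
converted to mass), clamped at zero, with the dimensionless weights
`C1 = 0.8571` for proliferating and `C2 = 0.1429` for migrating and
quiescent cells — the two printed weights sum to one and proliferation is
the energetically expensive programme. Applied naively over the full 3600 s
step this would drain 6.5 g/L per site per hour and empty any printed
glucose level within a few steps. The driver therefore references uptake to
a nutrient reservoir column above the cell monolayer, as in the petri-dish
setting the model emulates: `uptake_scale = 0.005` (15 um cell height over
a 3 mm medium column) multiplies the consumption time. At 4.5 g/L this
sustains several hundred hours of proliferative growth before depletion —
the regime in which the high-glucose endpoint behaviour is measured.

**Other fixed choices.** Moore (8-site) neighbourhoods; division delay
`t_div = 24` macro steps (one division per simulated day); daughter cells
copy the mother's molecular state and both clocks reset; cells seeded at
the steady state of their local glucose (no start-up transient in
`M_time`); agents act in a freshly sampled random permutation each step to
avoid directional artefacts; the operator order per step is fixed
(molecular update, phenotype, consumption, diffusion, actions). All
randomness flows from the run seed through R's RNG, so a `(config, seed)`
pair reproduces a trajectory bit-exactly.

# The sensitivity pipeline

The sweep multiplies one reaction parameter at a time by each factor in

```{r}
glioscale::lsa_factors()
```

under each initial glucose level 0.3, 1.125, 2.25 and 4.5 g/L — 31 x 20 x 4
= 2480 settings, three replicate runs each, replicate seeds derived as
`base + index`. Per setting the four endpoint means yield normalised
sensitivity coefficients

S = (M_pert / M_base - 1) / (b - 1),

one shared baseline mean per glucose level, plus the plain relative changes
dM = M_pert / M_base - 1 for the time and total-count endpoints. The
summary reports, per parameter and endpoint, max |S| over factors and
glucose levels with its argmax glucose.

Selection then builds two groups of parameter scalings: **Factor+**
(dM_time > 9 at 0.3 g/L — strong slow-down of expansion under scarcity) and
**Factor-** (dM_total < -0.8 at 4.5 g/L — strong shrinkage of the final
population under abundance). The threshold criterion for Factor- is applied
to the total-count endpoint; that is the reading consistent with the
group's stated purpose of "few total cells at high glucose". All cross-group
pairs that do not scale the same parameter twice are enumerated — the
packaged groups admit exactly 603 — and combined runs are screened for
dM_time > 0.01 together with dM_total < -0.01 per glucose level, the 0.01
margin discarding combinations with negligible effect.

## The surrogate

Reproducing the full sweep numerically requires 2480 x 3 full-grid
stochastic simulations of an unpublished equation system; that is outside
what a test suite can or should do. The pipeline is therefore exercised
end-to-end against a **surrogate endpoint generator**: endpoint `e` under
perturbations (p_i, b_i) is `baseline_e(glucose) * prod_i b_i^{w_e(p_i)}`
with multiplicative lognormal replicate noise `exp(sigma * z)` and integer
rounding. This is the simplest structure with the monotone log-scale
response the sensitivity coefficients presuppose, and it has a closed-form
coefficient `(b^w - 1)/(b - 1)` that serves as an analytic oracle for every
pipeline stage. What surrogate-based tests demonstrate is the correctness
of the pipeline machinery — design enumeration, averaging, coefficient
algebra, selection, pairing, screening, reporting — not the simulator's
biology; the simulator's biology is tested separately at reduced scale
(below). The surrogate makes no claim to match the simulator
quantitatively, and it has no spatial interactions beyond its additive
log-response.

# Problem sizes used by the tests

The packaged test-suite runs the full combinatorial and algebraic checks at
their published sizes (2480-setting design, 603 pairs, 797-cell seed, 1e3+
random algebra cases) and the behavioural checks at reduced spatial scale:
a 60 x 60 lattice with a radius-5 (81-cell) seed, three replicates per
glucose level, chosen so the whole suite completes on one CPU in minutes.
At that scale the behavioural contrast is unambiguous: at 0.3 g/L the
tumour reaches the boundary in ~25 steps as a migratory front, at 4.5 g/L
in ~350–400 steps as a compact proliferating mass more than an order of
magnitude larger. Full-scale (200 x 200, radius 16) runs use the identical
code path; only grid size, seed radius and replicate counts differ.

# Known limitations

* The reaction right-hand sides are a reconstruction; quantitative
  reproduction of published full-scale sweep values is out of reach and not
  attempted. The packaged reference summary of that sweep is shipped for
  comparison only and never used as a test oracle.
* The unbounded MO25 pool makes very long runs drift toward the migratory
  phenotype at every glucose level; endpoints at the printed scales are
  dominated by the pre-drift regime, but multi-month simulations would not
  be meaningful.
* No cell death, no mechanical interaction, no 3-D geometry, no explicit
  therapy; one nutrient species only.
* The magnitude ordering of coefficients at equal outputs
  (S(b1) > S(b2) for b1 < b2) is only a theorem when the output ratio
  exceeds one; the property tests restrict to that regime.
* Replicate noise in the surrogate is independent lognormal per endpoint;
  real replicate endpoint fluctuations are correlated through the shared
  trajectory, so surrogate-based power statements do not transfer to the
  simulator.
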