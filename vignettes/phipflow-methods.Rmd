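---
title: "Modelling continuous-flow PHIP hydrogenation: kinetics, calibration and chip transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling continuous-flow PHIP hydrogenation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phipflow)
```

## The problem

Parahydrogen-induced polarisation (PHIP) produces hyperpolarised molecules
by catalytic hydrogenation with para-enriched hydrogen. Run continuously in
a microfluidic chip — liquid channel, gas-permeable PDMS membrane window,
detection chamber — the method delivers a steady stream of hyperpolarised
product, but the yield depends delicately on the flow rate: too slow and
the product relaxes back to thermal polarisation before it reaches the
detector; too fast and neither hydrogen uptake nor reaction time suffice.
`phipflow` models this trade-off in two coupled stages:

1. a mass-action kinetic model of propargyl acetate hydrogenation over the
   cationic rhodium catalyst Rh(dppb)(COD)BF4, calibrated against
   tube-scale NMR kinetics, and
2. a steady two-dimensional convection–diffusion–reaction model of the chip
   that embeds those kinetics in the device geometry and predicts
   chamber-mean concentrations as a function of flow rate.

Only concentrations are modelled. Spin dynamics are reduced to a single
first-order sink: hyperpolarised allyl acetate `4` converts to "relaxed"
allyl acetate `4rx` with rate constant $k_6 = 1/T_1$. Polarisation levels
and signal enhancements are out of scope.

## Kinetic network

Ten species: precursor catalyst `1`, active catalyst `1a`, dissolved
hydrogen `2`, propargyl acetate `3`, complex `3a`, allyl acetate `4`,
complex `4a`, relaxed allyl acetate `4rx`, propyl acetate `5`, cyclooctene
`6`. Six irreversible reactions:

$$
\begin{aligned}
\mathbf{1} + \mathbf{2} &\xrightarrow{k_1} \mathbf{1a} + \mathbf{6} &
\mathbf{1a} + \mathbf{3} &\xrightarrow{k_2} \mathbf{3a} &
\mathbf{3a} + \mathbf{2} &\xrightarrow{k_3} \mathbf{1a} + \mathbf{4} \\
\mathbf{1a} + \mathbf{4} &\xrightarrow{k_4} \mathbf{4a} &
\mathbf{4a} + \mathbf{2} &\xrightarrow{k_5} \mathbf{1a} + \mathbf{5} &
\mathbf{4} &\xrightarrow{k_6} \mathbf{4rx}
\end{aligned}
$$

The induction period (COD hydrogenation, cyclooctene release) is collapsed
into the single activation step $k_1$; oxidative addition and migratory
insertion are collapsed into the concerted reduction steps $k_3$ and $k_5$.
Rates follow mass action; the right-hand side is generated from the
stoichiometry matrix as $\dot c = S\,v(c)$ and is verified in the test
suite against the hand-written rate equations on random states
(difference $\le 10^{-12}$ mM/s). Two linear invariants follow from the
stoichiometry and are enforced as properties: total catalyst
$[1]+[1a]+[3a]+[4a]$ and the organic backbone
$[3]+[3a]+[4]+[4a]+[4rx]+[5]$ are conserved along every trajectory
(relative drift $\le 10^{-6}$).

Two switches cover the two experimental regimes:

* **hydrogen clamping** — the tube experiment keeps methanol saturated at
  5 bar (solubility 4 mM/bar, hence 20 mM); this is represented by zeroing
  the hydrogen derivative rather than removing the species, so the same
  network object serves the tube (clamped) and the chip (free, membrane-fed)
  models;
* **relaxation** — $k_6$ is active only when `relaxation_enabled = TRUE`.
  The calibration experiments used thermal hydrogen, so $k_6 = 0$ there;
  the chip model uses $k_6 = 0.14\ \mathrm{s^{-1}}$, from proton $T_1
  \approx 7$ s of comparable acetates. `4rx` never re-enters the cycle: on
  the relaxation timescale the chemical identity is unchanged, but the
  model deliberately keeps relaxed product distinct (and, as a
  simplification, excludes it from rebinding; the same approximation is
  inherent in treating `4` and `4rx` as separate species at all).

Units: concentrations in mM, which numerically equals mol·m⁻³, so the
fitted rate constants in 1/(mM s) transfer to the chip solver (SI volumes)
without conversion. Integration uses `deSolve::lsoda` with an analytic
Jacobian, `rtol = 1e-8`, `atol = 1e-10` mM; negative excursions are clipped
to zero only below `max(1e-9, 100*atol)` mM, anything larger is an error.

## Calibration

The tube observables are the four NMR integral regions — propargyl, allyl,
propyl, catalyst — mapped to the *free* species `3`, `4`, `5`, `1`. Bound
complexes are not added in: the integrals come from distinct chemical-shift
regions, and the catalyst region (bound COD) tracks the precursor. This is
an approximation, documented rather than hidden.

`fit_rate_constants()` minimises the inverse-variance weighted residual sum
of squares over $k_1 \dots k_5$ with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`, box $[0, 10]$ 1/(mM s)), integrating the
clamped-hydrogen model at every evaluation. Three numerical choices matter
and were each forced by observed failure modes:

* **Finite-difference step.** The objective is computed through an ODE
  solve, so it carries $\sim 10^{-7}$ relative noise. The default
  machine-epsilon forward-difference step makes the numeric Jacobian pure
  noise along weakly identified directions (notably $k_2$, the fast binding
  step, which the 40 s sampling cadence barely resolves). `epsfcn = 1e-6`
  sets the step to $\sim 10^{-3}$ relative, above the solver noise; with it
  the noiseless self-consistency fit recovers all five constants to
  machine-level residuals.
* **Multistart.** The surface has distinct basins in which different steps
  play the rate-limiting role. The default start screens a deterministic
  13-point candidate grid (three uniform vectors over three decades plus
  one-factor spreads) by objective value and descends from the best two.
  Supplying `initial_guess` bypasses the multistart. (A single fixed guess
  of 0.01 — the obvious default — demonstrably stalls in the wrong basin
  on noiseless data, which is why the screened start is the default.)
* **Unidentified directions.** In noisy replicates $k_2$ occasionally runs
  to its upper bound with a numerically vanishing Jacobian column: that
  dataset simply cannot bound the constant from above. Such constants get
  the whole feasible range as their interval and the fit is flagged, per
  the "wide interval, never silent" contract.

Confidence intervals are linearised Wald intervals,
$\hat k \pm z_{0.975}\,\mathrm{SE}$, from the covariance
$(J^\top J)^{-1}$ of the $\sigma$-weighted residuals: the per-point sigmas
are treated as *known* measurement errors (they are, both for the synthetic
generator and for SNR-derived NMR error bars), so the covariance is not
rescaled by the reduced chi-square (`sigma_known = FALSE` restores the
rescaling convention for data with merely relative weights).
Profile-likelihood intervals are out of scope. Coverage of the whole
construction is measured, not assumed: the acceptance suite fits 100 noisy
replicates ($\sigma = 0.5$ mM, 19-point schedule) and checks how often the
nominal 95% intervals cover the generating truth per constant. For the
well-identified constants coverage sits near nominal; for the binding
constant $k_2$ it does not — under this noise level the maximum-likelihood
estimate of $k_2$ is strongly biased low (the nearly-saturated binding step
lets a low-$k_2$ configuration absorb noise), a classic sloppy-model
pathology that no symmetric linearised interval can repair. The coverage
test reports this honestly rather than papering over it.

## Synthetic tube data

The raw tube time series are not deposited, so `generate_tube_timeseries()`
stands in for them: it integrates the clamped model at given "true"
constants on the experimental schedule (19 samples, 40 s cadence, 0–720 s;
$[3]_0 = 20$ mM, $[1]_0 = 5$ mM, clamp 20 mM), maps to the four
observables, adds independent Gaussian noise and truncates at zero (peak
integrals are non-negative). Defaults emulate the experiment:
$\sigma = 0.5$ mM for every observable — the published error bars are small
but unquantified; 0.5 mM visually matches their scatter and is an admitted
free knob.

What the generator does **not** emulate: the intermittent bubbling cycle
(10 s bubble / 25 s settle) — the steady clamp is the same idealisation the
calibration itself makes; catalyst degradation visible after 460 s
(unmodelled); and any spectral artefacts (the generator produces
concentrations, not spectra). Passing the recovery and coverage tests
therefore shows the estimator is correct *for data generated by the model*,
not that the model is a complete description of the real tube experiment.

## Chip transport model

### Geometry and mesh

The unrolled 2D domain: a 55 × 0.1 mm liquid channel with a 25 mm-long,
0.4 mm-thick membrane band on one wall and a 2 × 0.5 mm chamber pocket,
out-of-plane depth 1.4 mm. Axial positions are not part of the fabricated
chip's published description, so they are parameters. The defaults —
membrane at x = 2–27 mm, chamber at x = 48–50 mm — were chosen once so that
the liquid volume (8.82 µL) and the pre-chamber residence volume sit close
to the real device's 8.5 µL; both are config-overridable, and the
"chamber moved upstream" scenario shifts the chamber to x = 35.5–37.5 mm
with everything else fixed.

The mesh is structured finite-volume: by default 250 µm axial spacing,
8 cells across the 0.1 mm channel (12.5 µm) and 8 cells across the 0.4 mm
membrane/pocket band — 1824 liquid plus 800 membrane cells. Axial transport
is overwhelmingly advective (cell Péclet ≫ 1 and upwinded), so axial
refinement barely moves the answers, while the transverse resolution
controls the membrane flux and the parabolic profile; the refinement test
(halving both spacings) requires chamber means to move by < 2%.

### Flow

The channel Reynolds number is ≪ 1 and the geometry is a straight channel,
so the velocity field is prescribed rather than solved: plane Poiseuille
across the local liquid width, rescaled in the wider chamber so the
volumetric flux through every cross-section equals the inlet flow rate.
Discretely, axial face flows follow the parabola normalised per
cross-section and transverse face flows are recovered from cell-by-cell
continuity, giving an exactly divergence-free discrete field (closure at
the walls is asserted). The membrane subdomain carries no flow.

### Transport, boundary conditions, reaction

Each species obeys the steady balance
$\nabla\!\cdot\!(u c_i) - D \nabla^2 c_i = R_i(c)$ with $D = 10^{-9}$
m²/s for all species. Discretisation: upwind advection, central (two-point)
diffusion, which is robust at the prevailing cell Péclet numbers at the
cost of some numerical diffusion — acceptable because axial spreading is
advection-dominated anyway, and quantified by the refinement test.

Boundary conditions: Dirichlet inlet composition (5 mM `1`, 20 mM `3`)
carried in by pure upwind inflow; zero-diffusive-flux outflow; no-flux
walls. Hydrogen alone also lives in the membrane subdomain, with diffusive
transport (same $D$; the membrane's internal diffusivity is not published
separately, so the single listed value is used), a Dirichlet boundary
$h_\mathrm{pdms}$ (default 20 mM) on the outer membrane edge, and flux
continuity at the membrane/channel interface. All other species treat that
interface as a wall. Reading the membrane coupling as a Dirichlet condition
*at the inner interface* would render the membrane subdomain inert and was
rejected: diffusion through the membrane is the only reading that
reproduces a finite uptake at high flow and closes the global mass balance,
which the tests check (membrane influx = outlet advective flux to 0.5%
with reactions off).

Kinetic source terms enter every liquid cell with hydrogen free; the
relaxation sink acts on free `4` only. For the oracle tests the solver can
instead clamp the hydrogen field, which reduces the chip to the tube model
evaluated at the residence time (transverse diffusion mixes the 0.1 mm
channel in ~2.5 s, far below residence times, so the plug-flow comparison
is tight).

### Steady solver

The coupled nonlinear system (≈ 19 000 unknowns at default resolution) is
solved by damped Newton iteration on the assembled residual
$F(c) = Mc - b - V R(c)$, with an analytic reaction Jacobian and sparse LU
solves. When a plain Newton step with backtracking fails, the solver falls
back to pseudo-transient continuation (implicit-Euler diagonal
augmentation) whose pseudo-timestep follows switched evolution relaxation —
it grows as the residual falls, returning the iteration to Newton near the
solution. Dirichlet-pinned rows are scaled to the transport-operator
magnitude so the relative residual (tolerance $10^{-8}$) weighs all
equations comparably. Flow-rate sweeps solve from high flow to low and
warm-start each solve from the previous solution: the short-residence end
is mildly nonlinear, and continuation keeps the stiff low-flow solves
(residence times of minutes against a 0.1 s binding timescale) inside the
Newton basin.

### Read-outs

The chamber read-out is the volume-weighted mean over all liquid cells in
the chamber's axial interval (pocket plus the channel strip beneath it) —
whether the published read-out was a volume average or a point probe is
unstated, and the volume average is the convention a detection coil
integrating the chamber would realise. Axial profiles are width-averaged
per column. The optimum of a sweep is the grid argmax refined by a
quadratic through the top three points; a maximum on the grid boundary is
flagged and not interpolated.

## Study conditions and problem sizes

The flow sweeps use 2–20 µL/min in 0.5 µL/min steps (37 points), the
uptake scan 0.5–2.5 µL/min in 0.5 steps, all at the default mesh; the
calibration study uses the 19-point schedule with 100 noisy replicates.
These are the sizes at which every number quoted here is computed by the
test suite and the acceptance script.

## What the model predicts (as recomputed here)

* Reactions off, 20 µL/min: chamber hydrogen ≈ 4.3 mM; the stream stays
  saturated (≥ 99% of 20 mM) only up to ≈ 1 µL/min on the 0.5-step scan.
* Full kinetics: the product curve rises from 2 µL/min to an interior
  optimum at ≈ 4.9 µL/min (peak ≈ 0.59 mM hyperpolarised allyl acetate)
  and tails off to ≈ 0.05 mM at 20 µL/min.
* Doubling the membrane hydrogen to 40 mM raises the peak to ≈ 1.35 mM
  (2.3×); moving the chamber 12.5 mm upstream at 40 mM adds ≈ 0.48 mM.

## Known limitations

* The model reproduces the *2D model's* published predictions, not the
  experiment: the measured optimum sits near 8 µL/min (chip-volume
  uncertainty from imperfect layer bonding) and the measured uptake
  collapses above 10 µL/min (possibly membrane deformation); neither
  discrepancy is modelled here, by design.
* The exact axial layout of the published 2D domain is unknown; the default
  layout is this package's own choice, and layout-sensitive quantities
  (notably the uptake at a given flow) carry that uncertainty.
* Bound complexes are excluded from the NMR observables; the relaxed
  product is excluded from rebinding; catalyst degradation beyond ~460 s is
  unmodelled.
* The doubled-hydrogen scenario scales the peak by ≈ 2.3 on the default
  mesh, at the upper edge of the "approximately doubles" expectation —
  slightly superlinear because the catalyst-activation step is itself
  hydrogen-limited at 20 mM.
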