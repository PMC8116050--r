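---
title: "Mass-conserved activator-substrate models of cell polarity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-conserved activator-substrate models of cell polarity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The models

Rho-GTPase polarity circuits are modelled here as mass-conserved
activator-substrate (MCAS) reaction-diffusion systems: a protein
interconverts between a slow-diffusing membrane-bound "activator" form and a
fast-diffusing cytosolic "substrate" form, with positive feedback in
activation and no synthesis or degradation. Because total protein is fixed,
growth of an activator peak depletes cytosolic substrate globally, and that
depletion is what couples distant peaks to each other. The package
implements four such models.

**Minimal model** (`minimal_model()`), dimensionless, one space dimension:

$$\partial_t u = a u^2 v - b u + D_m \partial_x^2 u, \qquad
  \partial_t v = -a u^2 v + b u + D_c \partial_x^2 v,$$

with defaults $a = b = 1$, $D_m = 0.01$, $D_c = 1$. The quadratic term
$a u^2 v$ is the implicit positive feedback; $u + v$ is conserved.

**Indirect-substrate model** (`indirect_model()`) adds a mobile
intermediate $v_i$: the activator converts to $v_i$ at rate $c\,u$
(default $c = 0.01$) and $v_i$ converts to substrate at rate $d\,v_i$
(default $d = 1$), with its own diffusivity $D_{vi}$. The delayed,
diffusible return path from activator to substrate is the single feature
that enables *equalization* of unequal peaks: a larger peak exports more
intermediate, which converts to substrate far from its source and can feed
the smaller peak.

**Mechanistic yeast models** (`mechanistic_model()`), in µM/s/µm units,
describe the budding-yeast circuit: Cdc42 in GTP-bound (`Cdc42T`),
membrane GDP-bound (`Cdc42Dm`) and cytosolic GDP-bound (`Cdc42Dc`) forms,
and a PAK-Bem1-GEF complex ("BemGEF") that shuttles between cytosol and
membrane and binds `Cdc42T` to form `BemGEF42`, which activates
neighbouring Cdc42 (positive feedback, rates $k_{2a}, k_3$). Membrane to
cytosol exchange is weighted by the volume ratio $\eta = 0.01$, so
conserved totals count cytosolic species at weight $1/\eta$. The
negative-feedback variant adds phosphorylated GEF species
(`BemGEFm_p`, `BemGEFc_p`, `BemGEF42_p`): Cdc42-bound complexes
phosphorylate the GEF of other complexes in an ultrasensitive manner
(Hill coefficient 6), and dephosphorylation happens only in the cytosol.
The phosphorylation rate constant saturates at
$k_{8,\max} = 0.0063\ \mu M^{-1} s^{-1}$ and the dephosphorylation rate at
$k_{9,\max} = 0.0044\ s^{-1}$.

Two readings of the published Hill-function arguments are possible because
the printed formulas are typographically ambiguous. The package defaults to
$k_8 = k_8(\mathrm{BemGEF42}_t)$ — consistent with the requirement that
both kinase and target complexes be Cdc42-bound — and
$k_9 = k_9(\mathrm{BemGEF}^*_c)$ — dephosphorylation being cytosolic. Both
arguments are configurable (`k8_arg`, `k9_arg`) to allow the alternative
literal readings.

Every constructor records its conservation groups, and
`reaction_rates()` satisfies $\sum_i w_i\, r_i = 0$ per group to machine
precision at any state; the test suite checks this over thousands of random
states.

## Reference amounts ("1x")

Amounts are specified as multiples of a reference composition. For the
dimensionless models 1x is a uniform substrate concentration $v = 2$ — the
threshold at which the uniform state becomes Turing-unstable in the
minimal model. The mechanistic models' absolute copy numbers are not fixed
by the published tables; the package adopts cytosolic concentrations of
5.0 µM Cdc42 and 0.017 µM BemGEF as its 1x reference, values typical of
measured yeast abundances, and exposes them as configuration
(`model$one_x`).

# Numerical scheme

`integrate_model()` advances the PDEs with an IMEX finite-difference
scheme: linear diffusion is treated implicitly (backward Euler;
tridiagonal solves per direction, with Sherman-Morrison corner corrections
for periodic boundaries and ADI-style direction splitting in 2D) and the
nonlinear reaction term explicitly. The time step adapts to the relative
error in the reaction term, estimated by step doubling: a step is accepted
when $\max_i |I_{2}-I_{1}|/\mathrm{scale}$ is below `rtol` (default
$10^{-4}$), halves on rejection and at most doubles on success. Because
every sweep matrix has unit column sums and the reaction kinetics conserve
each group's algebra exactly, conserved totals drift only at round-off
(observed $\lesssim 10^{-11}$ relative over full runs; the contract is
$10^{-8}$).

Design choices that the published description leaves open, fixed here once:

* **Boundary conditions**: periodic for production 1D/2D runs (avoids
  boundary-pinned peaks); no-flux available via `mcas_grid(bc =)`.
* **Domain**: 1D length 10 (dimensionless models, 500 grid points by
  default); mechanistic runs use an 8.86 µm domain — the side of a square
  with the surface area of a 2.5 µm-radius spherical cell.
* **Insulation**: internal no-flux walls are implemented as operator
  modifications (zeroed couplings across an interface), so
  `remove_insulation()` restores the original operator exactly and
  per-subdomain totals are conserved while walls are present.
* **Negativity**: small undershoot below zero (relative $10^{-9}$) is
  tolerated but never clamped; worse violations trigger step reduction.

A deSolve method-of-lines integration at tight tolerance serves as an
independent cross-check of the solver in the test suite, and diffusion-only
runs are validated against closed-form heat kernels.

# Simulation protocols

**Single-peak preparation.** The standardized initial condition for all
competition experiments is a pair of insulated subdomains (equal halves)
brought to single-peak steady states holding specified amounts, after which
the walls are removed at $t = 0$. Preparations start from a localized
raised-cosine activator bump holding half the conserved mass
(`seeded_initial_condition()`), plus 1% multiplicative seeded noise on the
substrate, renormalized so totals are exact. The seeded route is used
because the polarized branch of MCAS models is subcritical: below the
Turing onset (e.g. any amount below 1x in the minimal model) the uniform
state is linearly stable and noise alone never polarizes, yet the
single-peak state exists and is reachable from a finite stimulus. A
noise-only route (`method = "noise"`) is retained; preparations report
"no peak" explicitly when the seeded bump also collapses (strongly
sub-critical amounts).

**Peak analysis.** `detect_peaks()` finds local maxima, discards peaks
whose separating minimum is shallower than 5% of the field range, and
partitions the domain by watershed at inter-peak minima (steepest-ascent
basins in 2D); mass fractions are exact partitions of the activator mass.
Basal substrate is read at the point of a peak's region farthest from the
peak — for an insulated single-peak subdomain, the subdomain edge, where
the profile is flat ("just outside the peak" without an arbitrary offset).
Peak identity over time is tracked by maximal region overlap.

**Outcome classification** follows fixed rules on the tracked mass
fractions over a horizon of $t_{\max} = 2000$: *competition* when one peak
reaches a $\geq$ 99% share and the run is steady; *equalization* when both
fractions end within 50% ± 1%; *coexistence* when fractions stay within
±1 percentage point of their starting values; *peaks split* when the
tracked count exceeds the initial count; *homogeneous* when the activator
range falls below $10^{-3}$ of its mean. Runs still drifting at the
horizon are labelled coexistence with a censored flag. The **competition
time** is the (linearly interpolated) time to evolve from a 70%:30% to a
99%:1% activator share; runs that never reach 99:1 are censored, never
reported as numbers.

**Phase diagram and predictor.** `phase_diagram()` sweeps the
indirect-substrate diffusivity against total amount, classifying a 0.4:0.6
competition assay per cell and recording $\Delta v = v_{P0.6} - v_{P0.4}$,
the basal-substrate difference of the two insulated starting peaks. Its
sign predicts the dynamical outcome (negative: flux toward the larger
peak, competition; positive: equalization; within $10^{-4}$: coexistence).

# FRAP simulation and fitting

`frap_geometry()` builds a two-lobed cell — a 6 µm sphere overlapping an
ellipsoid along the x axis — on a masked Cartesian voxel grid, solving the
overlap offset so the narrowest cross-section between the bodies matches
the requested 2 µm neck. The published "width 2 µm" of the ellipsoid would
make the neck as wide as the daughter body (no constriction); the package
default therefore uses a 6 × 3 µm ellipsoid so a genuine constriction
exists, and the literal 6 × 2 reading remains available through the
arguments. `simulate_frap()` zeroes a 1 µm-diameter cylindrical bleach
region and integrates free diffusion (default $D = 10\ \mu m^2/s$,
a typical cytoplasmic GFP mobility) by implicit Euler with a fixed 10 ms
step. The linear systems are solved by a sparse Cholesky factorization
computed once per geometry and reused across all steps — exact solves at
lower cost than an iterative method on this fixed grid. Intensities are
"imaged" by summing voxel columns along z, and `measure_roi()` averages
3 µm-diameter circular regions of the projection.

`fit_frap()` fits ROI traces with exponential decay $a e^{-kt} + c$,
recovery $-a e^{-kt} + c$, or their two-term combination
$a e^{-kt} + b e^{k_2 t} + d$ (the second exponent an independent,
sign-unconstrained rate) by Levenberg-Marquardt least squares with
deterministic initial guesses; half-times are $T_{1/2} = \ln 2 / k$.
`neck_slowdown()` quantifies how much the neck impedes diffusional
exchange between the lobes, in two ways. The default *flux* protocol fits
the decay of the difference between compartment-mean intensities after a
bleach — a clean single-exponential inter-compartment mode — and converts
the rate to a volume-independent neck conductance
$G = k_{eq} / (D (1/V_m + 1/V_d))$, compared against the matched
unconstricted control geometry (neck as wide as the daughter body): the
slowing $1 - G/G_{ctl}$ is exactly zero without a constriction and grows
monotonically as the neck narrows. The *ROI* protocol mirrors the
experimental measurement design instead: exponential fits of two ROI
traces equidistant from the bleach centre, one within the mother and one
across the neck, reporting $1 - k_d / k_m$. The ROI ratio conflates fast
intra-compartment redistribution with the slower cross-neck exchange and
is sensitive to where the sites are placed on an idealized small-cell
geometry; it is retained because it matches the measurement as performed
on real cells, but the flux protocol is the robust measure of the neck
effect.

# Synthetic data

All inputs are generated in code: perturbed or seeded initial fields with
exact conserved totals, exponential FRAP traces with known ground truth
and seeded Gaussian noise, schedule-driven competition traces that realize
every outcome label for classifier tests, and a YAML fixture catalogue
holding the four model parameter tables verbatim plus named assay presets.
Every stochastic operation takes an explicit seed and restores the global
RNG state. What the generators do *not* emulate: real microscopy noise
statistics, photophysics, cell-to-cell parameter variability, or cell
geometry other than the idealized two-lobe FRAP shape — so passing tests
demonstrate correctness of the methods on the models' own terms, not
agreement with any particular experimental data set.

# Problem sizes and tolerances used in the test suite

The test and acceptance suites run the full protocols at sizes chosen to
finish in minutes on one CPU while preserving the phenomenology:
dimensionless models on 1D grids of 500 points (128-256 for unit tests);
mechanistic models on 1D grids of 200 points over 8.86 µm — the
saturation, competition-slowing and equalization phenomenology of these
circuits is not specific to dimensionality, and the 2D (ADI) path is
exercised separately by conservation, symmetry and basin-assignment tests.
Saturation scans relax the steady-state tolerance to $10^{-7}$ (basal
levels equilibrate long before the final slow creep of peak shape). The
FRAP acceptance computation uses the production voxel size of 0.15 µm;
unit tests use 0.25-0.3 µm, where fitted half-times change by under 3%
relative to refinement.

# Known limitations

* The explicit reaction step makes stiff kinetics (the mechanistic
  models' fast exchange rates) the step-size bottleneck; runs to
  $t = 2000$ s take minutes, and large 2D sweeps of the mechanistic
  models are correspondingly expensive.
* Homogeneous steady states of the mechanistic models are found
  numerically (pointwise relaxation plus Newton polishing); multiple
  nontrivial roots, if any exist in exotic parameter regimes, are not
  enumerated.
* The negative-feedback model can settle into oscillatory attractors;
  `run_to_steady_state()` then reports non-convergence with an
  oscillation amplitude rather than forcing a label.
* 3D simulation is diffusion-only (FRAP); reaction-diffusion runs are 1D/2D.
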