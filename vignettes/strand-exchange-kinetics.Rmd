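---
title: "Modeling and fitting recombinase-driven DNA strand exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and fitting recombinase-driven DNA strand exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r}
library(strandex)
```

## The reaction model

Strand exchange is modeled as a closed mass-action network in which the
presynaptic filament A captures donor dsDNA B and processes it through two
three-stranded intermediates to the heteroduplex product D and the
displaced strand E:

$$\mathrm{A} + \mathrm{B}
  \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} \mathrm{C}_1
  \underset{k_{-2}}{\overset{k_2}{\rightleftharpoons}} \mathrm{C}_2
  \underset{k_{-3}}{\overset{k_3}{\rightleftharpoons}} \mathrm{D} + \mathrm{E}$$

Two assumptions shape the model. First, the filament is a *single kinetic
species*: its concentration is the ssDNA fragment concentration, not a
per-site occupancy, so capture is a simple bimolecular step. Second, step 3
reverse is treated as bimolecular (D + E → C2). The reverse direction of
the product step is not observable directly in the assays, but the
bimolecular form is the thermodynamically consistent closure of a closed
system — it gives K3 = k3/k-3 units of nM and makes
K_total = K1·K2·K3 dimensionless under the stated unit conventions — and it
is the form under which the long-time state is a true equilibrium.  A
first-order reverse would make product formation effectively irreversible
at low concentrations and was rejected for that reason.  Units are nM and
seconds throughout the kinetic core; the binding module works in μM with
explicit conversion at its boundary.

The two-step alternative collapses C1 and C2 into one intermediate and is
retained as the null model for scheme selection.

Simulation integrates the mass-action ODEs with `deSolve::lsoda` driving a
compiled right-hand side (relative tolerance 1e-8, absolute tolerance
1e-10 nM; sub-tolerance negative excursions are clamped to zero).  Two
independent oracles validate the integrator in the test suite: the closed
form $A(t) = A_0/(1 + k_1 A_0 t)$ for the irreversible equal-concentration
second-order reaction, and an algebraic equilibrium solver.  Because the
reversible chain has no cycles, its equilibrium satisfies detailed balance,
so the state can be parameterised by free filament concentration and solved
with one-dimensional root finding (`algebraic_equilibrium()`); long
simulations must relax to that root.

```{r}
r <- standard_rates()
traj <- simulate_exchange(r, times = seq(0, 1000, 2))
autoplot(traj)
algebraic_equilibrium(r)
```

## Observables

The pairing assay reports percent free substrate, $100\,A(t)/A_0$; the
heteroduplex product keeps the acceptor-labelled strand, so it stays
quenched and pairing curves do not return upward.  The displacement assay
reports percent displaced product, $100\,E(t)/B_0$.  The raw
fluorescence-to-percent maps are affine with anchors set by the maximum
FRET efficiency $E_{max}$: the instrument-specific formulas are not
dictated by the physics beyond those anchors, so the package fixes 0% and
100% at the fully complexed and fully free signals and exposes $E_{max}$
(default 0.6) and $F_0$ in the calibration object.  The 2-aminopurine
conversion is the affine map anchored at the fully quenched level, 60.1% of
the filament signal by default.

The SDS-quench abortive assay collapses C1 back to substrates and C2
forward to products.  Collapse is modeled as instantaneous, with the
post-SDS readout delay (150 s by default, configurable; reported protocols
vary between 150 and 300 s) acting only as a sampling offset on a flat
signal.  Two readings of the C1 equation exist because the printed form of
the substrate-based rule does not close with free substrate percent: the
package defaults to the mass-balance reading
$C_1 = (100 - \mathrm{substrate}_{before}) - (C_2{+}\mathrm{product})$,
which closes substrate + C1 + (C2+product) to 100 and equals the substrate
gain across SDS addition, and exposes the non-closing subtraction as
`c1_rule = "printed"` rather than switching silently.

## Fitting and scheme selection

`fit_time_course()` minimises the sum of squared residuals between the
percent series and the simulated observable.  Parameters are searched in
log10 space inside box bounds (bimolecular constants 1e-7–1e-1 nM⁻¹s⁻¹,
unimolecular 1e-6–1 s⁻¹).  The landscape is multimodal with long sloppy
valleys, and plain multistart proved unreliable, so the production search
is global-then-local: a seeded log-uniform screen ranked by SSR, LM
refinement from the best starts, then basin hops (LM restarts from the
incumbent jittered by up to 0.6 decades).  Three-step fits additionally
warm-start from a quick two-step pre-fit lifted into three-step space by a
fast-pre-equilibrium embedding.  All draws flow from the config seed, so
fits are deterministic given (data, config).  Standard errors come from the
Jacobian-based covariance at the optimum, mapped from log to linear scale;
no bootstrap by default.

`compare_models()` fits both schemes, cross-warm-starts each from the
other's optimum (embedding in one direction, intermediate lumping in the
other — stabilising the SSR gap between the nested-like pair), and reports
$AIC = m\ln(SSR/m) + 2p$ together with a Wald–Wolfowitz runs test on
residual signs at α = 0.01 as the operational meaning of "systematic
deviation".  AIC decides the selection; the runs test is diagnostic.  Note
that AIC-based selection of the simpler scheme carries an irreducible
asymptotic type-I rate of about 13% (the likelihood-ratio statistic of two
extra effective parameters exceeds its 2-point penalty with probability
$e^{-2}$), which bounds how often the two-step scheme can be expected to
win on its own data.

A practical caution established by the package's own simulation studies:
from a *single* pairing trace at realistic noise, K3 (and hence K_total) has
a heavy-tailed sampling distribution — the reverse product flux can be
pushed to its bound with little SSR cost.  Replicate averaging before
fitting (the worked example in the README averages 20 traces) restores
well-behaved recovery.  Single-replicate estimates of K1 are reliable;
single-replicate estimates of K_total are not.

## Binding and filament estimators

Steady-state titrations follow the Hill equation
$y = y_0 + a\,[\mathrm{R}]^n / (K_D^n + [\mathrm{R}]^n)$, fitted by
nonlinear least squares with $K_D$ and $n$ in log space; total recombinase
is treated as free ligand (no depletion correction), matching how such
titrations are conventionally analysed.  The printed source equation's
denominator symbol is read as $K_D$.  At $[\mathrm{R}] = K_D$ the curve
passes through half amplitude exactly.

Association traces follow the same sigmoid in time with half-occupancy time
$T_{1/2}$.  The nucleation velocity $V_N$ is the OLS slope over the first
10 s after protein injection (5 s for the faster-nucleating paralog;
caller-set), and the elongation velocity $V_E$ is the OLS slope over all
samples within $T_{1/2} \pm 2$ s — the inclusive-endpoint reading, 9
samples at 0.5 s sampling; the window is configurable because the verbal
definition ("±2 s, total 5 s") is ambiguous about endpoints.  On degenerate
traces (e.g. a purely linear rise) the sigmoid fit cannot place $T_{1/2}$
inside the observed range; the estimator then warns and returns $V_N$ with
$T_{1/2}$ and $V_E$ as `NA` instead of failing.

Dissociation traces are fitted as $a\,e^{-k_{off}t} + y_0$ with
$k_{off} \ge 0$; a non-decaying trace yields $k_{off} \approx 0$ with a
warning.  A log-linear regression on baseline-free decays serves as the
independent oracle in the tests.

```{r}
fit_dissociation(generate_dissociation(noise = noise_model(sd = 0)))
association_kinetics(generate_association(noise = noise_model(sd = 0)))
fit_hill(generate_titration(noise = noise_model(sd = 0)))
```

## What the synthetic data emulates

The generators provide every assay with attached ground truth: mass-action
exchange courses mapped to fluorescence through the inverse calibration,
abortive experiments with instantaneous SDS collapse, Hill titrations,
sigmoid association and exponential dissociation traces.  Noise is
additive, homoscedastic Gaussian on the reported signal — the instrument's
noise is not otherwise characterised — with defaults of 1 percentage point
for percent series (about 1% of dynamic range) and 0.002 anisotropy units.
All randomness flows through one seeded generator; identical configs give
identical output, and generation does not disturb the session RNG.

Default study conditions mirror the assays: 36 nM substrate fragments
(72 nM in the concentration-robustness check), 0–1000 s exchange courses
sampled every 2 s, quench schedule 150/300/600/900 s, anisotropy sampled at
0.5 s over 0–120 s (association) or 0–600 s (dissociation), titrations at
12 log-spaced concentrations from 0.05 to 5 μM.  These sizes also keep the
full simulation studies (parameter recovery, 50 + 50 scheme-selection
replicates) tractable on a single CPU.

The default three-step truth, `standard_rates()`, was chosen once by a
constrained search so the standard condition shows the features real
pairing data show: ~40% of substrate converted by 1000 s with roughly half
carried through to product, a clear three-step signature that a two-step
fit cannot absorb (SSR gap ≈ 30 over 501 points), and a product
back-reaction strong enough that K3 is determined by the data rather than
by its bound.  The matching two-step truth for selection studies is
`standard_rates("two_step")`.

What the generators deliberately do not emulate: photobleaching, signal
drift, mixing dead time, heteroscedastic or correlated noise, filament
length effects, and ATP-state-resolved sub-mechanisms.  Passing recovery
tests on this synthetic world therefore validates the estimators and the
identifiability of the design, not the photophysics of any particular
instrument.

## Numerical choices and degenerate inputs

* Solver tolerances 1e-8/1e-10; integration failures name the offending
  rate set.  Trajectory states are clamped to zero only below the absolute
  tolerance.
* LM convergence tolerances 1e-12 (1e-15 in the closed-form fitters);
  parameters within 1e-6 decades of a bound trigger a boundary warning.
* Flat (no-reaction) exchange data drive k1 to its lower bound with a
  boundary warning rather than an error.
* Abortive percentages: negative C1 within 2 percentage points is clamped
  to 0 (measurement noise); larger inconsistencies warn.
* Equilibrium constants are undefined when a reverse rate is zero; the
  functions error rather than returning infinities.

## Known limitations

* Fitting uses the pairing observable only (displacement series serve as
  validation predictions); multi-condition global fits with shared
  parameters are out of scope.
* Uncertainties are local (Jacobian-based); for the sloppy directions of
  the three-step model they understate the heavy tails described above.
* The filament is one species: no length-resolved or per-site occupancy
  modeling, no stochastic (Gillespie) simulation.
* The 2AP and FRET calibrations are affine by construction; saturation or
  inner-filter effects must be corrected upstream.
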