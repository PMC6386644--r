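---
title: "Lumped-parameter hemodynamics of zone-2 TEVAR: models, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lumped-parameter hemodynamics of zone-2 TEVAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archflow)
```

## Scope and intent

Thoracic endovascular aortic repair (TEVAR) with a proximal landing zone
covering the left subclavian artery (LSA) origin — "zone 2" — reroutes the
left-arm circulation through the left common carotid artery (LCCA) and a
surgical carotid-to-subclavian bypass. Two hemodynamic questions follow:
how does the supra-aortic flow split change, and how large is the net
hemodynamic load (the *displacement force*) pushing on the deployed stent
graft?

`archflow` answers both at desk scale with a zero-dimensional (0D,
lumped-parameter) model rather than full 3D computational fluid dynamics:
patient-specific 3D simulation requires segmented CT geometry that is not
generally available, whereas the mechanisms of interest — outlet
impedances, flow redistribution, and the surface integral of tractions —
survive the reduction to a circuit model plus idealized graft surfaces.
The package also embeds a four-patient clinical table set (flows, branch
areas, velocities, pressures, graft dimensions) and reproduces its summary
arithmetic exactly.

## The three-element Windkessel outlet

Each outflow branch terminates in a classic RCR circuit: a proximal
(characteristic) resistance $R_p$ in series with the parallel pair of a
compliance $C$ and a distal resistance $R_d$, representing the downstream
vascular bed. With the branch flow $Q(t)$ imposed, the distal (capacitor)
pressure $P_d$ obeys

$$ C\,\frac{dP_d}{dt} = Q(t) - \frac{P_d}{R_d}, \qquad
   P(t) = P_d(t) + R_p\,Q(t). $$

Units follow the clinical convention used throughout the 0D literature:
pressures in mmHg, flows in mL/s, resistances in mmHg·s/mL, compliance in
mL/mmHg. Everywhere else the package is SI (m, s, Pa, m³/s), with clinical
units (L/min, mmHg, cm/s, cm²) only at I/O boundaries; the conversion
constants are 1 L/min = 1/60000 m³/s and 1 mmHg = 133.322 Pa.

**Integration.** The ODE is linear, so the trapezoidal (Crank–Nicolson)
one-step map is used: A-stable, second-order, and exactly solvable per
step. The default resolution is 1000 steps per cycle for 6 cycles, and
downstream analyses use the last cycle only.

**Initial state.** Because the discretised system is affine, the map over
one full cycle is $P_d \mapsto A^n P_d + K$, whose fixed point
$P_d^\ast = K/(1-A^n)$ is available in closed form (and, for the arch
network below, by one small linear solve). The default initial condition
is this exact periodic state, so every simulated cycle is already the
converged periodic solution and the cycle-5 to cycle-6 mean-pressure drift
is at rounding level — comfortably below the 0.1% convergence requirement
that motivates using the final cycle. The cruder warm start
$P_d(0) = R_d\,\bar Q$ remains available as `init = "mean"`; with it, the
drift after six cycles is of order 0.1–0.3% for physiologic time constants
($\tau = C R_d \approx 1\text{–}2$ s), which is why the exact periodic
start is the default rather than an optimisation. `last_cycle()` still
checks the drift and warns when handed an unconverged trace.

## Calibration to cuff pressures

The clinically standard calibration target is a brachial-cuff systolic/diastolic
pair (sys, dia) plus the measured flow waveform. The package proceeds in
two nested stages (`calibrate_wk3()`):

1. **Compliance.** For a fixed total resistance
   $R_t = R_p + R_d$ split as $R_p = f R_t$ (default $f = 0.09$, a
   characteristic-impedance heuristic; configurable), the pulse pressure of
   the simulated last cycle decreases monotonically in $C$, so $C$ is found
   by root bracketing on $[10^{-3}, 10]$ mL/mmHg.
2. **Total resistance.** $R_t$ is initialised from the cuff mean-pressure
   estimate MAP $= (\text{sys} + 2\,\text{dia})/3$ as $R_t = \text{MAP}/\bar Q$.
   This alone is not sufficient: the simulated trace's own
   (max + 2 min)/3 need not equal its time-average, so fixing the mean at
   the cuff MAP leaves a common offset (up to ~10 mmHg in experiments) in
   *both* systolic and diastolic pressure even when the pulse pressure is
   matched. An outer Newton-type update therefore shifts $R_t$ by the mean
   of the systolic and diastolic errors divided by $\bar Q$, re-solving for
   $C$ each time, until both targets are met (tolerance 0.25 mmHg,
   typically 2–4 outer iterations).

On return, $R_t$ satisfies $R_t = \bar P / \bar Q$ exactly, where $\bar P$
is the achieved mean pressure — the physically meaningful identity — while
the one-third cuff rule is treated as an initial guess only. A flat inflow
cannot generate pulse pressure, so calibrating a constant waveform against
sys ≠ dia raises a calibration-failure error reporting the achieved pair.

## The 0D aortic arch and the TEVAR transform

The arch is a single pressure node fed by the ascending-aortic inflow
$Q_{in}(t)$ and drained by the branches (brachiocephalic trunk BCT, LCCA,
LSA, descending aorta DAo), each through its own Windkessel. At every
instant the node pressure solves the algebraic conservation constraint

$$ \sum_i \frac{P - P_{d,i}}{R_{p,i}} = Q_{in}(t), $$

after which each $P_{d,i}$ advances by its ODE. The coupled system is
linear with constant coefficients; the implementation advances all beds
simultaneously with the trapezoidal rule (the node pressure eliminated
exactly), so the flow split sums to the inflow to machine precision at
every step. No inter-branch arch resistances are modelled: the common-node
coupling is the minimal model that produces the observed redistribution
mechanism, and no patient-specific arch impedance data exist to justify
more.

`apply_tevar()` encodes zone-2 coverage: the LSA outlet is removed from the
arch and its distal bed re-attached behind the LCCA origin through a bypass
resistance $R_b$ in series. The bypass flow is counted as LCCA flow, since
it enters through the LCCA origin. Two consequences are exact in the
steady case and hold to <0.5% for pulsatile means: with $R_b = 0$ the
electrical network is unchanged, so the post-operative LCCA flow equals the
pre-operative LCCA + LSA flow; and LCCA flow decreases strictly
monotonically in $R_b$. Note that as $R_b \to \infty$ the model reduces to
the three-outlet arch *without* the LSA bed — because the inflow is
imposed, the node pressure rises and the remaining branches carry more
than their pre-operative flows; the model does not (and should not) return
to the pre-operative LCCA flow in that limit. The post-operative inflow is
an input, not a prediction: measured post-TEVAR ascending-aortic flows
differ from pre-operative ones for reasons outside a rigid 0D model.

Maximum branch velocities are estimated as
$v_{max} = k\,Q_{peak}/A$ with $A$ the lumen area just distal to the
branch origin and $k$ a profile factor (default 2, the parabolic-profile
centerline maximum; 1 corresponds to plug flow). The factor is
configurable because the mapping from a point velocity maximum to a flow
waveform is not otherwise determined.

## Displacement force on the stent graft

The hemodynamic load on the graft at the systolic peak is the surface
integral of the pressure and wall-shear tractions over the graft's wetted
(lateral) surface, discretised as a sum over triangles:

$$ \mathbf{DF} = \sum_f \left( p_f\, \hat{\mathbf n}_f\, A_f
   + \boldsymbol\tau_f\, A_f \right), $$

with $\hat{\mathbf n}_f$ the unit normal pointing outward from the lumen,
so the result is the force exerted by the blood *on* the graft. Fields are
per-face constants (piecewise-constant quadrature); accuracy is controlled
by mesh refinement and converges at second order in element size. The
pressure and shear contributions are reported separately; for physiologic
magnitudes ($p \sim 10^4$ Pa, $\tau \sim$ 1–10 Pa) the shear part is below
1% of the pressure part.

"Systolic peak" is taken as the instant of maximum pressure in the last
cycle (ties broken earliest); a configuration option allows peak inflow
instead, since the defining instant is a modelling choice.

The anatomical frame is +z cranial, +x ventral (anterior), +y patient-left,
so a *dorsocranial* force — the direction associated with distal
sealing-zone migration — has negative x and positive z. Classification
uses the sign quadrant of the (x, z) projection, flagging vectors within 5°
of a separating plane as boundary cases.

Three analytic oracles validate the integrator:

- any closed surface under uniform pressure carries zero net force
  (divergence theorem); the icosphere residual is at rounding level;
- the lateral surface of a 90° bend under uniform pressure $p$ carries
  $|\mathbf{DF}| \to \sqrt2\, p\, \pi r^2$ (the negated end-cap
  contributions), e.g. 26.66 N for $p$ = 15 kPa, $r$ = 0.02 m;
- a straight tube with analytic Poiseuille fields carries the axial shear
  force $8\mu L Q/r^2$ with wall shear $\tau_w = 4\mu Q/(\pi r^3)$.

## Synthetic data

No patient waveforms or geometries are published, so the generators emulate
structure, not any specific patient:

- **Inflow waveforms** (`gen_inflow_waveform()`): a half-sine systolic bump
  over the first 35% of the cycle plus four low-amplitude seeded harmonics,
  affinely rescaled so the trapezoidal cycle mean and the maximum hit the
  requested values exactly. This gives a smooth, periodic, PC-MRI-like
  single-peaked profile with closed-form moments. It does not reproduce
  dicrotic notches, early-diastolic reverse flow of any particular shape,
  or beat-to-beat variability.
- **Graft surfaces** (`gen_tube_mesh()`, `gen_closed_sphere()`): straight
  cylinders, torus-segment bends and icospheres with consistently outward
  orientation and known areas/volumes. Real stent grafts taper, wrinkle
  and oversize; none of that is modelled — these meshes exist to carry
  fields whose integrals have closed forms.
- **Synthetic patients** (`gen_synthetic_patient()`): draw ranges follow
  the embedded cohort tables (inflow mean 3.7–6.3 L/min, systolic 94–131 /
  diastolic 49–66 mmHg, branch areas within the measured ranges), the flow
  split is centered on the measured pre-operative split (BCT 12%, LCCA 4%,
  LSA 4.8%, DAo 79%) with log-normal-style jitter renormalised to sum
  exactly to the inflow mean, the proximal resistance fraction is
  log-uniform on (0.05, 0.2) and total compliance log-uniform on
  (0.8, 2.5) mL/mmHg apportioned by branch conductance. Every artifact is
  driven by one explicit integer seed; nothing touches the global RNG
  state.

Because the drawn branch resistance totals satisfy
$R_{t,i} = \mathrm{MAP}/\bar Q_i$, the simulated network reproduces the
drawn flow split and the ground-truth totals are recoverable from a run as
$\bar P / \bar Q_i$ — the recovery property the tests exercise.

Passing tests on these synthetic conditions validate the numerics and the
redistribution mechanism; they do not validate rigid-wall 0D modelling
against 3D patient-specific CFD, fluid–structure interaction, or any
individual patient's measurements.

## Cohort arithmetic

The embedded tables are recomputed with exact decimal arithmetic and
half-away-from-zero rounding: column means such as 16.38/4 = 4.095 and
179.4/4 = 44.85 must round to 4.10 and 44.9 as printed, which binary
doubles misround. Percent changes are computed from the printed (rounded)
column means by default, matching the published workflow; computing from
unrounded means is available and agrees for the headline values. Where the
published mean row disagrees with exact recomputation (four cells, all
rounding ties or one-digit slips), `cohort_report()` flags the cell with a
printed-vs-recomputed comparison instead of silently matching either side.
Mass conservation across each patient-phase row holds to the print
rounding (≤ 0.02 L/min).

The Pearson module returns $r$ with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom; at $n = 4$,
$r = 0.95$ sits at the 5% critical value ($t = 4.303$). An exact
permutation oracle (all 24 permutations at $n = 4$) cross-checks the
ranking behaviour in the tests; the two p-values agree strongly in rank but
not pairwise for every dataset pair, since each dataset has its own
permutation null.

## Numerical choices and problem sizes

- Time stepping: trapezoidal, period/1000 step, 6 cycles; halving the step
  changes last-cycle pressures consistently with second-order convergence.
- Compliance search: Brent root finding on the bracket (10⁻³, 10) mL/mmHg;
  calibration tolerance 0.25 mmHg on both targets.
- Meshes in tests and validation: up to 128 × 128 (32 768 faces), where the
  bend-tube force is within 0.05% of its closed form; convergence-order
  checks use 3-point refinement ladders.
- Validation batch sizes: 50 random circuits for the steady-state law, 20
  synthetic patients for calibration round-trips, 10 for drift and
  redistribution properties.

## Known limitations

- Rigid walls, Newtonian steady-profile assumptions inside branches, no
  wave propagation (no 1D effects), no coronary or distal carotid
  territories — the model cannot exhibit subclavian steal dynamics beyond
  what a static bypass resistance encodes.
- The displacement force is evaluated on idealized surfaces with imposed
  fields; reproducing a specific patient's 3D CFD force values is out of
  scope.
- The post-operative inflow must be measured or assumed; the 0D model does
  not predict cardiac adaptation.
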