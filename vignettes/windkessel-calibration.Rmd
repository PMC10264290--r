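---
title: "Windkessel calibration and haemodynamic metrics for dissected aortae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windkessel calibration and haemodynamic metrics for dissected aortae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dissectflow)
```

## The problem

Patient-specific simulations of aortic flow stand or fall with their
boundary conditions. In type-B aortic dissection (TBAD) the descending
aorta is split by an intimal flap into a true lumen (TL) and a false lumen
(FL); pressure differences between the lumina (transmural pressure, TMP),
retrograde FL flow, and wall-shear-stress patterns are all candidate
predictors of disease progression, and all of them are sensitive to how
much flow leaves the aorta along its length. Besides the major branches,
dozens of minor vessels (intercostal, subcostal and lumbar segmental
arteries, and the inferior mesenteric artery) each carry a small flow that
in aggregate approaches a fifth of stroke volume.

`dissectflow` implements the calibration and post-processing side of such
a study as reusable, tested components:

1. derivation of per-outlet **target mean flows** from grouped 4D-flow
   measurements and literature minor-branch flows, and of **aortic
   pressure targets** from a brachial cuff measurement;
2. a **0D pulsatile network** of parallel three-element Windkessel (WK3)
   outlets, integrated to cyclic periodicity;
3. **automatic WK3 tuning** against the flow and pressure targets;
4. rigid **registration and temporal resampling** of velocity samples on
   a moving measurement plane;
5. the **haemodynamic metric suite**: forward/reverse flow decomposition,
   reverse-to-forward ratio and FL ejection fraction, transmural
   pressure, TAWSS/OSI/ECAP, a Carreau–Yasuda viscosity model with a
   pulsatile transition criterion, Bland–Altman agreement and normalised
   velocity errors;
6. deterministic **synthetic-data generators** with closed-form ground
   truth, so every stage is testable without any imaging data.

The 3D Navier–Stokes solve itself is out of scope: the 0D network is the
calibration surrogate, exactly as used when tuning outlet parameters
before committing to expensive 3D runs.

## Outlet targets

Within a group $\Gamma$ of branches, measured mean flows
$\bar Q'_B$ fix the split fractions $\phi_B = \bar Q'_B / \sum_\Gamma
\bar Q'$, and targets are re-based on the more reliable inter-plane flow
loss: $\bar Q_B = \phi_B\,\bar Q'_\Gamma$. This exactly conserves the
group loss and is invariant to a common scaling of the raw measurements
(`branch_fractions()`, `target_flows()`).

Minor branches are below 4D-flow resolution, so their flows come from
published Doppler measurements, summed per group
(`minor_group_targets()`). The packaged study configuration distributes
flow equally among the branches of a group; left/right and
vertebral-level asymmetries are deliberately not modelled, consistent
with treating all minor branches of a group as one lumped outlet.

Pressure targets use the standard brachial-to-aortic back-transform:
diastolic pressure is taken as unchanged along the arterial tree while
systole amplifies peripherally, so the aortic systolic target is
$P_s = 0.83\,P'_s + 0.15\,P'_d$. Values are kept at full precision
internally (126.69 mmHg for a 138/81 mmHg cuff measurement) and rounded
to integer mmHg only in the presentation helper
(`format_pressure_targets()`), which is what clinical tables print
(127/81, pulse 46).

## The 0D network

Each outlet is a WK3: proximal resistance $R_p = \rho R_{tot}$ in series
with distal $R_d = (1-\rho)R_{tot}$ in parallel with a compliance $C$,
referenced to venous pressure. The branches share one inlet node driven
by a periodic inflow $Q_{in}(t)$:

$$C_i \frac{dP_{c,i}}{dt} = \frac{P - P_{c,i}}{R_{p,i}}
  - \frac{P_{c,i} - P_{ven}}{R_{d,i}}, \qquad
  P = \frac{Q_{in} + \sum_i P_{c,i}/R_{p,i}}{\sum_i 1/R_{p,i}}.$$

The algebraic node closure means mass is conserved identically at every
step — the test suite asserts this to $10^{-8}$ relative. At periodic
steady state the capacitor's mean current vanishes, so each outlet's
cycle-mean flow is $(\bar P - P_{ven})/R_{tot,i}$: the **mean flow split
depends only on the total resistances**, not on $\rho$, $C$ or the
waveform shape. This structure carries the whole calibration strategy.

Numerical choices:

* **Integrator**: BDF2 (implicit second-order backward differentiation,
  backward Euler for the first step). The system is linear, so the
  implicit update is a closed-form rank-one solve per step, and
  unconditional stability holds. Second order matters: at a 1 ms step
  the simulated first-harmonic pressure matches the closed-form WK3
  impedance $Z(\omega) = R_p + R_d/(1 + j\omega R_d C)$ to 0.02 %
  amplitude, and halving the step moves the converged extrema by well
  under 0.1 %.
* **Timestep**: 1 ms by default. If it does not divide the period the
  nearest exact divisor is used.
* **Cyclic periodicity**: whole cycles are run until systolic and
  diastolic inlet pressure both change by `< 1 %` between consecutive
  cycles (both in the same cycle); the final cycle is reported.
  Exceeding the cycle budget is an error carrying the cycle history.
* **Initial condition**: capacitors start at the venous reference by
  default; a diastolic or steady-state estimate (used internally by the
  tuner) removes the charging transient without changing the converged
  cycle.
* **Venous reference**: 0 mmHg. The packaged study's resistance tables
  are consistent with $R_{tot}\cdot\bar Q$ constant at the mean aortic
  pressure across outlets, which implies a zero distal reference.

## WK3 tuning

The tuning technique exploits two regularities visible in calibrated
parameter tables of this kind: resistances inversely proportional to
target flows at a common perfusion pressure, and a common $R C$ time
constant across outlets.

1. $R_{tot,i} = \bar P_0 / \bar Q_i$ with
   $\bar P_0 = P_d + (P_s - P_d)/3$, so the flow split is exact by
   construction and remains exact under any common scaling;
2. $C_i \propto 1/R_{tot,i}$ (equal time constants), normalised to a
   total compliance $C_{tot}$;
3. two global scales alternate until both pressure targets are met: all
   resistances are multiplied by the ratio of target to simulated mean
   pressure proxy $(P_s + 2P_d)/3$, and $C_{tot}$ by the ratio of
   simulated to target pulse pressure, re-simulating to periodicity each
   iteration.

Because $(P_s, P_d)$ and (mean proxy, pulse) are linearly equivalent,
meeting both scales meets both pressure targets; on this linear network
the alternation contracts and converges in a handful of iterations
(budget 30, asserted on randomised specifications). $\rho$ is
configuration, never tuned; defaults follow the packaged study's
classes: 0.030 supra-aortic, 0.280 renal, 0.056 elsewhere. The equal
time-constant distribution rule is an interpretation inferred from the
regularity of the packaged parameter table, not a printed prescription —
it is isolated in one step and easily replaced.

The default tolerances (pressures within 1 mmHg, mean flows within 3 %
relative) mirror the fidelity reported for calibrated simulations of
this kind. In the packaged 16-outlet worked example the tuner lands
within 0.8 % on all targets.

## Inlet-plane mapping

Measurement planes from time-resolved imaging move and deform with the
aorta; solver inlets are static. `register_frame()` maps each frame onto
the reference by the least-squares rigid transform on corresponding
points (orthogonal Procrustes for the rotation, centroids for the
translation), rotating the velocity vectors with the geometry; per-frame
transforms are retained for audit. Point correspondence carries both the
plane attitude (equivalently: centroid plus orthogonal-regression
normal) and the residual in-plane rotation, so a single Procrustes solve
realises the mapping; whether the original acquisition allowed non-rigid
in-plane deformation is unknowable from the data used here, and only
rigid mapping is implemented. Registration is an isometry — pairwise
distances are preserved to $10^{-9}$ — and plane flow is invariant under
any rigid motion applied jointly to points, normals and velocities.

`resample_series()` interpolates per-point velocities periodically onto
a uniform grid (linear by default, optional periodic cubic), wrapping the
last-to-first interval with the period. The sample count is
$\lceil T/\Delta t\rceil$ so the realised step never exceeds the request.
Weak velocity divergence in measured data is not corrected; the
`flux_imbalance()` diagnostic reports it instead.

The orientation convention fixing every sign in the package: the
reference normal points along the bulk systolic flow, so forward flow is
positive at peak systole.

Spatial interpolation onto an arbitrary solver point set is a
convenience helper (`interp_to_points()`) using inverse-distance
weighting over the nearest neighbours with exact pass-through at
coincident points; it is not part of the quantitative pipeline.

## Metrics

With $\vec v = \mathbf v\cdot\vec n$ and per-sample areas $A$ (velocity
m/s, area mm², flow mL/s — one m/s over one mm² carries one mL/s):

* $Q = \sum \vec v A$; forward/reverse components sum strictly positive
  and strictly negative projections separately, zero projections count
  to neither, and $Q = Q_F - Q_R$ identically.
* $R/F = Q_R/Q_F$ instantaneously; the cycle value averages it over the
  period by trapezoid with periodic closure. Instants with no forward
  flow leave the ratio undefined: the default policy excludes them with
  a warning and averages over the covered duration; a strict mode
  errors. FLEF is the cycle value on the primary-entry-tear plane in
  percent.
* $\mathrm{TMP}(t) = P_{TL} - P_{FL}$; the mean is the periodic
  trapezoidal average and the peak is the instantaneous value of largest
  magnitude with sign preserved — on ties the earliest extremum wins (a
  documented convention; any choice is defensible).
* $\mathrm{TAWSS} = \frac1T\int|\boldsymbol\tau|dt$,
  $\mathrm{OSI} = \frac12\bigl(1 -
  |\int\boldsymbol\tau dt| / \int|\boldsymbol\tau|dt\bigr)$,
  $\mathrm{ECAP} = \mathrm{OSI}/\mathrm{TAWSS}$, all by periodic
  trapezoid on the (default 5 ms) metric grid. Nodes with zero unsigned
  integral are $0/0$: OSI and ECAP are defined as 0 there and flagged —
  a no-shear node is not oscillatory. OSI is clamped to $[0, 0.5]$
  against roundoff. On smooth histories the 5 ms cadence agrees with
  1 ms within 1 %. The `ecap_exceeds()` helper marks the conventional
  1.4 Pa⁻¹ thrombotic-susceptibility threshold.
* Blood rheology is Carreau–Yasuda,
  $\mu = \mu_\infty + (\mu_0-\mu_\infty)[1+(\lambda\dot\gamma)^a]^{(n-1)/a}$,
  with editable literature defaults ($\mu_0 = 0.056$,
  $\mu_\infty = 0.00345$ Pa·s, $\lambda = 3.313$ s, $a = 2$,
  $n = 0.3568$; density 1056 kg/m³). The transition check computes the
  peak Reynolds number at a nominal shear rate (default $V/D$) and a
  critical Reynolds number as a configurable power law in the Womersley
  number, $Re_c = k\,\alpha^b\,St^c$ with defaults $k=169$, $b=0.83$,
  $c=-0.27$ from the pulsatile-transition literature. The correlation
  constants are configuration, not truths, and externally estimated
  $Re_p$/$Re_c$ values can be supplied directly.
* Agreement: `bland_altman()` (bias and $\pm1.96$ SD limits) and
  `velocity_errors()` (peak and mean pointwise discrepancies as a signed
  percentage of mean inlet velocity). The exact peak/mean error
  definition varies between studies; this one is isolated behind a
  single function so alternates can be swapped.

## Synthetic data

The generators emulate the *study conditions*, not images: a 94 bpm
heart rate, a truncated-Fourier half-sine systolic lobe whose cycle mean
is exactly $SV\cdot HR/60$ (default stroke volume 70 mL, i.e.
~110 mL/s), 16 plane timeframes per cycle, a 20 mm disc sampled by a
sunflower layout with equal-area weights, a reverse sector whose
realised area fraction is exactly $\mathrm{round}(f n)/n$, rigid plane
motion with known per-frame transforms, WSS node populations with
analytic indices (constant: OSI 0; reversing sinusoid: OSI 0.5, TAWSS
$2\tau_0/\pi$; partial reversal $m + a\sin\omega t$ with
$\overline{|\tau|} = \tfrac2\pi(m\arcsin\tfrac ma + a\cos\arcsin\tfrac
ma)$), and paired lumen pressures with prescribed mean offset and
oscillation. Optional zero-mean Gaussian noise emulates the poor
low-velocity signal of phase-contrast imaging; ground truths are stored
pre-noise. Fixed seeds give identical output.

What passing the round-trip suite does **not** show: generators share the
package's containers and conventions, so they cannot detect convention
errors that cancel (e.g. a global sign flip applied consistently), nor do
they reproduce imaging artefacts (partial-volume averaging, velocity
aliasing, eddy-current offsets) or wall motion beyond rigid plane
transport. Agreement with real 4D-flow data is a separate, clinical
validation question.

## Problem sizes

The shipped tests and the acceptance script use the packaged study
tables directly (11- and 16-outlet networks at 1 ms over a 0.638 s
cycle), plane discs of 40–3000 points over 4–16 frames, and WSS
populations of tens of nodes — sizes chosen so the full suite runs in
well under a minute while every assertion stays at its stated numerical
tolerance.

## Known limitations

* No wave propagation, inter-outlet aortic resistance, compliant walls
  or flap mechanics: the 0D surrogate calibrates mean flows and inlet
  pressure extrema, nothing between the inlet and the outlets.
* Grouped minor branches share one WK3 by design; per-branch flows
  inside a group are not individually constrained.
* The packaged iliac rows of the minor-branch variant imply a slightly
  different perfusion pressure (~92 vs ~99 mmHg) than every other
  outlet; consistency checks anchor to the rows following the dominant
  pattern, and the discrepancy is surfaced rather than hidden.
* Equal per-branch minor flows and the equal-time-constant compliance
  rule are documented interpretations, adjustable through configuration.
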