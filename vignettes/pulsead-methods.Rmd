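---
title: "Reduced-order compliant haemodynamics of aortic dissection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order compliant haemodynamics of aortic dissection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsead)
```

## The problem

Type B aortic dissection separates the descending aorta into a true lumen
(TL) and a false lumen (FL), divided by an intimal flap and communicating —
in the case modelled here — through a single entry tear of about 18.5 mm².
Clinically relevant quantities (false-lumen pressurization, transmural
pressure across the flap, wall-shear indices) cannot be measured
non-invasively; simulation fills that gap, provided the boundary conditions
are tuned to the patient and the wall is allowed to move. `pulsead`
implements that workflow at reduced order: a lumped-parameter (0D) network
and a quasi-one-dimensional compliant pulse-wave solver replace the 3D
computational fluid dynamics domain, and synthetic generators replace
imaging-derived inputs. Every stage — Windkessel tuning, the
moving-boundary wall law, the dissection with its tear, and the clinical
post-processing indices — is retained.

## Models

### Three-element Windkessel outlets

Each outlet couples to an RCR Windkessel: proximal resistance $R_1$, distal
resistance $R_2$, compliance $C$, with
$$P + R_2 C \frac{dP}{dt} = (R_1+R_2)\,Q + R_1 R_2 C\frac{dQ}{dt}.$$
The relation is discretized with first-order backward differences
(`wk3_step`) with a 1 ms time step as the default everywhere. Inside the pulse-wave solver the discrete WK3 relation is
solved *simultaneously* with the outgoing characteristic at each substep.
A purely lagged update (pressure from last step's flow) becomes unstable
exactly when $R_1$ reaches the characteristic impedance $\rho c/A$ of the
coupled vessel — and step 4 of the tuning procedure imposes
$R_1 = \rho\,\mathrm{PWV}/A_0$ by design — so the simultaneous scalar
Newton solve (the converged limit of the coupling iterations a 3D solver
performs within each time step) is the only consistent choice.

### The moving-boundary wall law

Wall motion is modelled by a linear nodal law: displacement along the
outward normal $\delta = (p - p_{ext})/K$, with the stiffness derived from
the area compliance under a circular cross-section,
$K = 2\sqrt{\pi A_0}/C_A$. In this axisymmetric embodiment the law becomes
a pressure–area tube law $A(p) = \pi\,(r_0 + (p-p_{ext})/K)^2$, which is
exactly the standard $p \propto (\sqrt{A}-\sqrt{A_0})$ law of 1D
haemodynamics; its linearization at $p_{ext}$ reproduces $C_A$ and its wave
speed at $A_0$ is the Bramwell–Hill speed $1/\sqrt{\rho D}$ with
$D = C_A/A_0$. The external pressure default is 76 mmHg (the mean
diastolic pressure over the wall).

### Quasi-1D pulse-wave solver

Cross-sectionally averaged mass and momentum,
$$\partial_t A + \partial_x Q = 0, \qquad
\partial_t Q + \partial_x(Q^2/A) + \frac{A}{\rho}\partial_x p = f,$$
are closed by the tube law and integrated with the two-step
(Richtmyer) Lax–Wendroff scheme, sub-stepped to keep the Courant number
below 0.9. Friction assumes a Poiseuille profile,
$f = -8\pi\mu(\dot\gamma_w)Q/(\rho A)$, with the Carreau–Yasuda viscosity
evaluated at the wall shear rate; at the Womersley number of the aorta
(about 23) the profile detail is secondary, and the momentum flux
coefficient is 1. Junctions enforce mass conservation and static-pressure
continuity through Riemann invariants ($u \pm 4c$ for this tube law),
solved by a scalar Newton iteration per junction; invariants are
extrapolated from the freshly updated interior state, which removes a slow
energy input that otherwise destabilizes short side branches. Blood:
$\rho = 1056$ kg/m³; Carreau–Yasuda defaults $\mu_0 = 22$, $\mu_\infty =
2.2$ mPa·s, $\lambda = 0.110$ s, $a = 0.644$, $n = 0.392$ (the widely used
whole-blood fit; the solver also accepts a Newtonian limit for
verification).

A small Voigt wall viscoelasticity is included: $p = p_{el} + \Gamma\,
\partial_t A$ with $\Gamma = \Gamma_w/A_0^{3/2}$ and $\Gamma_w = 0.3$
Pa·s·m by default. Through mass conservation this acts as an implicit
axial diffusion of $Q$ (solved by a cached tridiagonal sweep). The scaling
concentrates damping in small, stiff vessels: the viscoelastic fraction of
the aortic pulse stays below 0.1 % — consistent with treating aortic
viscoelasticity as minor — while the otherwise *undamped* quarter-wave
resonance of short branches terminated by prescribed flows (a genuine
artifact of reduced-order prescribed-flow boundaries, not of the anatomy)
acquires a physical decay channel. Without it, grid refinement makes those
stubs ring without bound.

### Dissection and entry tear

The FL runs parallel to the TL, closed at its distal end (no re-entry
tear). The intimal flap is rigid and transmits no displacement; the
external-wall compliance of the dissected region — estimated from the
*combined* TL+FL area — is split between the lumina in proportion to their
reference areas. The tear is a quasi-steady sharp-edged orifice,
$Q = \mathrm{sign}(\Delta P)\,C_d A_t \sqrt{2|\Delta P|/\rho}$ with
$C_d = 0.6$ and $A_t = 18.5$ mm²; the discharge model (and $C_d$) is a
modelling choice of this package — a 3D solver resolves the jet instead.
The coupling to both lumina is lagged by one substep and under-relaxed
(factor 0.3), which bounds the chatter of the square-root law near
$\Delta P = 0$ at a sub-pascal level. In rigid mode the FL is a closed
incompressible cavity: the solver then assembles the network into its 0D
limit, where zero FL flow holds exactly rather than to solver tolerance.

### The 0D network

Vessel segments reduce to inertance–resistance blocks, $L = \rho\ell/A_0$
and $R = 8\pi\mu\ell/A_0^2$, assembled with Kirchhoff current balance at
nodes, WK3 terminals, and prescribed-flow sources, all advanced by backward
Euler. The step matrix is constant, so it is factored once per solve.
These identities also generate the 0D analogue used by tuning step 2;
lumped parameter values are not measurable from imaging, so they are
always derived from segment geometry this way.

## The four-step tuning procedure

1. **Whole-system WK3.** A single WK3 driven by the inflow waveform is
   iterated until its periodic response matches the systolic/diastolic
   targets (150/80 mmHg): an inner bisection on $C$ matches the pulse
   pressure, an outer update of $R_{tot}$ matches the level. The periodic
   response is obtained exactly as the fixed point of the one-cycle affine
   map, so each evaluation costs one filtered pass over the cycle. The
   fitted $C$ is the total systemic compliance $C^{sys}$.
2. **Distribution.** $C^{sys}$ is split over the outlets proportionally to
   their target mean flows; each outlet's $R_{tot,i}$ starts at
   $\bar P_i/\bar Q_i$ (venous reference 0 mmHg — consistent with the
   tuned outlet table, where $R_{tot}\bar Q \approx 113$ mmHg across all
   outlets) and is iterated to a fixed point under repeated 0D solves
   until achieved mean flows are within 1 % of target. The seed ratio
   $R_1/R_{tot} = 0.056$ is configurable; it only seeds steps 1–2 because
   step 4 overwrites $R_1$.
3. **Compliance estimation.** A rigid network run provides segmental
   systolic–diastolic pressure variations $\Delta P$; synthetic
   cine-MRI-like area waveforms (generated from regional distensibility
   defaults) provide $\Delta A^* = (A - A_{min})/A_{min}$, and
   $D = \Delta A^*_{peak}/\Delta P$. The peak is extracted by projecting
   the area signal onto the pressure waveform (least squares), which
   coincides with the plain peak ratio for clean data but stays unbiased
   under measurement noise, where a max/min estimator is biased upward by
   construction. Branch distensibility comes from the population law
   $\mathrm{PWV} = 13.3/d^{0.3}$ (d in mm) and Bramwell–Hill
   $D = 1/(\rho\,\mathrm{PWV}^2)$. Integrating $C_A = D A_0$ along the
   modelled vessels gives $C^{aorta}$.
4. **Re-tuning for the compliant model.** Only
   $C^{per} = C^{sys} - C^{aorta}$ is distributed over the outlets (same
   flow weights; the budget closes exactly by construction); $R_{tot,i}$
   is kept from step 2 while $R_1$ becomes the characteristic impedance
   $\rho\,\mathrm{PWV}/A_0$ of the coupled vessel to minimize artificial
   reflections.

## The synthetic fixtures and what they do not show

The inflow generator produces a half-sine ejection over one third of the
cycle, a 2 % early-diastolic backflow lobe, and zero diastolic flow,
renormalized so the cycle integral is exactly the stroke volume
(107.6 ml at 75 bpm, giving a mean of 134.5 ml/s and a cardiac output of
8.1 l/min). The idealized geometry has literature-typical adult
dimensions — not patient values, which are unavailable — chosen so the
32 mm inlet reproduces the study's nondimensional regime (mean Reynolds
≈ 1408, Womersley ≈ 23). Regional distensibility defaults (1.18×10⁻⁵ /Pa
ascending, 0.42×10⁻⁵ in the dissected region on the combined lumen area,
1.78×10⁻⁵ abdominal) reproduce the reported area-variation magnitudes over
a 70 mmHg pulse. Carotid branch flows are scaled low-pulsatility copies of
the inflow envelope with exact prescribed means (12.7/8.9 ml/s).

Two consequences of the stand-in inflow deserve emphasis, because they
bound what agreement with the source study's printed values can mean:

- **Total compliance from step 1 is strongly waveform-shape dependent.**
  The half-sine with a one-third systolic fraction is peakier (peak
  646 ml/s) and its diastolic decay window longer than the patient's
  measured waveform. Fitting 150/80 mmHg then *uniquely* determines
  $C^{sys} \approx 1.40$ ml/mmHg — confirmed against a dense independent
  ODE integration — versus 0.99 ml/mmHg with the patient's curve. An
  effective systolic fraction near 0.45 would be needed to reproduce
  0.99, which is neither the generator's stated condition nor a
  physiological ejection duration. The generator's defaults are kept as
  stated; the fitted value is reported as computed.
- **Target agreement of the full pipeline.** After the four steps, the
  compliant simulation reproduces the mean-flow targets to well under 1 %,
  but the inlet pressure extremes carry a wave-dynamic signature the
  single-WK3 fit cannot represent (inertial overshoot of the peaky
  inflow, multi-exponential diastolic decay of the distributed
  compliances). On this fixture the maximum relative deviation over all
  targets is about 5–7 %, dominated by the pressure extremes — an honest
  property of the desk-scale surrogate rather than of the tuning logic,
  whose flow matching is exact to tolerance.

## Numerical choices

- Default time step 1 ms (output grid), internally sub-stepped to CFL 0.9.
- Fixture grid: 16 nodes per segment by default; inlet pressure extremes
  change by about 1.5 % between 16 and 32 nodes, and a two-segment
  refinement study in the test suite bounds waveform changes at halved
  spacing below 2 %.
- Periodicity: initialization at the diastolic pressure with zero flow;
  cycles are discarded until the cycle-to-cycle maximum relative pressure
  change falls below 1 % (0.5 % in the 0D solver), with a configurable
  cycle cap and a flagged partial result on non-convergence.
- Tuning tolerances: 0.5 mmHg on pressures (the internal fit targets
  0.05 mmHg), 1 % on mean flows; all loops are deterministic bisections
  or fixed-point iterations — no randomness anywhere in the solvers. The
  only stochastic element in the package is the seeded noise of the
  synthetic area generator.
- Degenerate inputs are rejected with explicit messages: constant inflow
  (compliance unidentifiable), non-positive areas, characteristic
  impedance at or above $R_{tot}$ (named outlet), CFL violation
  (suggested step), wall collapse (named segment).
- Foot detection for PWV: the cycle is rotated to centre the systolic
  peak, the wrap interface of an imperfectly periodic cycle is excluded
  from the slope search, and the minimum preceding the maximal upstroke
  slope is refined by parabolic interpolation; ties break to the earliest
  time.

## Worked example

```{r example, eval = FALSE}
geom   <- idealized_dissected_aorta(fixture_config())
inflow <- synth_inflow(inflow_spec())
report <- tune_pipeline(geom, inflow, tuning_targets())
report
report$budget          # C_sys / C_aorta / C_per (ml/mmHg)
round(report$achieved, 2)

indices <- index_report(report$simulation, pwv_segment = "asc")
indices
```

The run takes roughly half a minute at the default sizes (16 nodes per
segment, 1 ms step, up to 12 cycles).

## Known limitations

- No 3D flow features: tear jet impingement, secondary flows and the
  spatial TAWSS/OSI maps of the patient anatomy are out of reach; shear
  indices are per-node values under the Poiseuille closure.
- The intimal flap is rigid; flap motion and its effect on TL/FL flow
  split are not modelled.
- Prescribed-flow boundaries reflect incoming waves totally; their
  quarter-wave stub resonance is controlled by the viscoelastic term, not
  eliminated.
- The orifice discharge coefficient is a fixed modelling constant, not a
  calibrated quantity.
- Segments are uniform; geometric taper must be approximated by chaining
  segments of stepwise-different calibre.
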