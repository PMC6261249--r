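---
title: "Methods: a desk-scale coupled electromechanical ventricle with CRT and LVAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale coupled electromechanical ventricle with CRT and LVAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardioem` asks a treatment-effect question — what do CRT and a
continuous-flow LVAD, separately and combined, do to the electrical and
mechanical activation and the hemodynamics of a failing ventricle with a
bundle branch block — on a fully synthetic, deterministic, desk-scale
model. This vignette records the model in enough detail to re-derive every
equation, the parameters that matter, the numerical choices, and the
boundaries of what the desk-scale results can and cannot say.

## Cell electrophysiology

The membrane model is the ten Tusscher–Noble–Noble–Panfilov human
ventricular formulation in its 2004 single-cell form: twelve currents
(fast Na⁺, inward-rectifier K⁺, transient-outward K⁺, rapid and slow
delayed rectifiers, L-type Ca²⁺, Na⁺/Ca²⁺ exchanger, Na⁺/K⁺ pump, plateau
Ca²⁺ and K⁺, background Ca²⁺ and Na⁺), and an SR calcium subsystem with

* leak `I_leak = V_leak (Ca_SR − Ca_i)`,
* SERCA uptake `I_up = Vmax_up / (1 + K_up²/Ca_i²)`,
* gated release `I_rel = d·g·(a_rel Ca_SR²/(b_rel² + Ca_SR²) + c_rel)`,

with instantaneous cytosolic and SR buffering. This 2004 calcium subsystem
(no dyadic subspace; `I_CaL` enters the cytosolic balance directly; release
gated by `d·g`) is the formulation the package implements throughout —
the calcium equations and the release-gate pair `d`, `g` are its defining
features. All maximal conductances, calcium-handling constants, volumes and
buffer capacities are plain entries of `cell_params()` and can be swapped
wholesale (e.g. for another parameter generation) through YAML configs.

Transmural heterogeneity follows the standard three-variant scheme:
endocardial cells have low `g_to` (0.073 nS/pF) and slow `s`-gate
kinetics, mid-myocardial cells a reduced `g_Ks` (0.062 vs 0.245 nS/pF,
hence the longest action potential), epicardial cells the fast `s`-gate.
Currents are expressed per unit membrane capacitance (pA/pF), so `cm = 1`
in the voltage equation while `cm_ca = 0.185` µF converts currents to
ion-flux units in the concentration balances.

Two printed-formula quirks are handled explicitly. First, the steady state
of the Ca-dependent inactivation gate `fCa` slightly exceeds 1 at
diastolic calcium in the published rate functions; the implementation
clamps it at 1 so gate variables remain fractions — the effect on the
action potential is negligible. Second, `fCa` and `g` only relax downward
while the membrane is depolarized (above −60 mV), as in the reference
model; in the pure-ODE right-hand side used for solver cross-checks this
appears as a zeroed derivative.

Failing myocytes keep unmodified ionic parameters: the heart-failure
phenotype of the study enters through passive mechanical stiffening only
(below), so every scenario, including "normal sinus rhythm", is the same
stiffened ventricle with a different activation pattern.

## Numerical scheme for the cell and tissue

Gates use Rush–Larsen exponential updates; voltage and concentrations use
forward updates. The default step is `dt = 0.02` ms for single cells and
`0.05` ms in tissue, with an accuracy safeguard: each step is internally
substepped so no substep changes the voltage by more than `dv_max = 0.2`
mV (bounded at `dt/64`). This concentrates effort in the ~1 ms upstroke
and is what lets the fixed-step integrator track an `lsoda` reference
solution of the same right-hand side to within 1 mV pointwise over a full
paced beat — a test the suite runs on every build.

Tissue propagation is the monodomain equation with axis-aligned diffusion
coefficients `D_a = 1/(ρ_a S_a C_m)` (helper `conduction_coefficient()`).
The solver operator-splits: a reaction step per node, then diffusion
advanced implicitly (backward Euler) with Jacobi-preconditioned conjugate
gradients on the fixed sparse operator — unconditionally stable in the
diffusion part at any lattice spacing. The finite-difference operator is
symmetric with zero row sums on the no-flux boundary, so diffusion
conserves total voltage exactly; both properties are asserted in the
tests. EAT is recorded online at the first upward −50 mV crossing with
linear interpolation between steps.

Rather than prescribing a literature diffusion coefficient, the package
calibrates: `calibrate_cv()` measures planar velocity between probes at
25 %/75 % of a 1-D cable and iterates on the quadratic CV–diffusion
scaling until the target (60 cm/s by default) is met within 0.5 %. The
study calibrates on a cable with the *same lattice spacing as the tissue
mesh*, so the numerical dispersion of the coarse lattice is absorbed into
the coefficient instead of biasing the velocity.

## Synthetic anatomy and Purkinje network

No anatomical mesh is used. `make_biventricular_mesh()` samples a regular
lattice (spacing chosen to hit a target node count, default ≈ 3000 at
≈ 0.24 cm) inside a two-ellipsoid wall: an LV shell (outer semi-axes
2.0 × 2.0 × 2.6 cm, inner shell at 0.62 of the outer) and a thinner RV
shell (2.1 × 2.0 × 2.3 cm at scale 0.82) shifted toward +x, cut by a basal
plane. Nodes carry transmural depth (0 = epi, 1 = endo), a layer label
assigned by wall-volume thirds with a cleanup pass forbidding direct
endo–epi lattice adjacency, wall region (LV free wall / septum / RV free
wall; the septum is the LV wall adjacent to the RV ellipsoid) and
apex/mid/base levels by height quartiles. The RV is deliberately smaller
than the LV: that asymmetry — not any tuned electrophysiology — is what
makes the left block the worst-case activation pattern, as in real
anatomy. Coordinates may carry a small seeded jitter for realism; the
connectivity, the conduction operator, and hence the physics live on the
unjittered lattice.

Purkinje trees are grown per bundle by farthest-point sampling of
endocardial nodes (16 left / 12 right terminals by default) and
shortest-path-aware greedy insertion, so root-to-terminal paths are close
to geodesic. Terminals bind one-to-one to endocardial tissue nodes; a
junction fires as a suprathreshold current injection over a small
neighbourhood (1.6 lattice spacings, restricted to the terminal's own
ventricle) with zero junction delay — a point source on a coarse lattice
cannot overcome the diffusive sink, so the finite footprint is the
lattice analogue of a physical junction's coupling area.

The network conduction velocity defaults to 300 cm/s — the physiological
His–Purkinje range — while the myocardium is calibrated to 60 cm/s. With
both at 60 cm/s the His-to-terminal transit (50–100 ms on this tree)
dominates activation dispersion and a t = 0 CRT stimulus *adds* early
dispersion, inverting the expected CRT effect; the fast network restores
the physiological regime in which dispersion is set by myocardial spread.
Both velocities are configurable (`purkinje_config(cv=)`,
`study_setup(purkinje_cv=)`).

Scenarios: sinus uses both bundles; LBBB/RBBB drop the respective bundle's
terminals (`purkinje_activation()` marks them unactivated); CRT adds a
pacing site — LV lateral free wall at mid-height for LBBB, RV endocardial
apex for RBBB, with the RV-side basal septum available as a named
alternative — at the same instant as the His activation (configurable
delay, default 0). Blocked territory is still reachable retrogradely
through the myocardium; that emerges from the monodomain solve with no
special handling. The +LVAD variants reuse their CRT counterpart's
electrical solution: the device enters the mechanical computation only.

## Myofilament mechanics and ATP economy

Each wall segment runs a Rice-type approximate cross-bridge model:
troponin Ca²⁺ binding (low/high-affinity pools), a steeply cooperative
nonpermissive→permissive transition (`perm50 = 0.5`, Hill exponent 15), a
three-state cross-bridge cycle (attachment `fapp`, power-stroke `hf`/`hb`,
detachment `gxb`) with strain-dependent rates, mean-distortion ODEs, and
sarcomere-overlap geometry giving the single-overlap fractions. Rates are
body-temperature values with Q10 factors exposed; the species factor
`xbmodsp = 0.2` slows cycling to the large-mammal range (twitch peak
~120 ms after the Ca rise at 600 ms pacing). Integration uses per-state
exponential updates (each linear-in-state rate equation advanced
analytically with frozen coefficients), which is what keeps the model
stable at `dt = 0.05` ms despite 10⁴ s⁻¹-scale rates.

The sarcomere-length state follows the printed integral formulation:
`dSL/dt = (Integral_Force + (SL0 − SL)·viscosity)/mass` with
`Integral_Force = ∫(F_active + F_passive − F_preload − F_afterload) dt`
and series-elastic afterload `F_afterload = K_SE (x − SL0)`. As printed,
a positive net force lengthens; the implementation therefore evaluates the
integrand over *signed* normalized forces (lengthening-positive: the
contractile element contributes −tension, the passive element −(restoring
force), the preload is the passive force at the initial length so rest is
an exact equilibrium). Isometric mode pins `dSL/dt = 0`. Defaults:
`SL0 = 2.2` µm, `K_SE = 4` (normalized force/µm), `viscosity = 3`,
`mass = 50` (normalized force·ms²/µm, ms·units of the published values);
viscosity and mass are not printed anywhere in the source material and are
flagged as assumed.

The passive element is titin + collagen exponentials
(`0.002·(e^{10|SL−1.9|}−1)` signed, plus a collagen term above 2.25 µm).
Heart failure multiplies it by the passive scaling constant
(`apply_hf_stiffening()`, factor 5 in every study condition); the chamber
passive P–V curve inherits the same factor, so the stiffening acts at both
the sarcomere and the cavity level. Segment strain is defined as
`(SL − SL0)/SL0` (the source figure's "strain" is not formula-defined; this
is the natural reduced-order reading), and the ATP consumption rate is the
printed product `E = g_xbT · SOVF_thick`, reported in s⁻¹; cycle ATP is
the wall-volume-weighted trapezoidal integral of `E` over the analysis
beat.

## Order reduction: segments, coupling, chamber pressure

The full-resolution study solves 3-D orthotropic hyperelastic mechanics;
at desk scale each ventricle is instead 18 wall segments (3 longitudinal
bands × 6 sectors). A segment's activation delay is the mean EAT of its
member nodes, its Ca²⁺ drive is the paced endocardial cell's steady-state
transient shifted by that delay (the reduced counterpart of Gaussian-point
Ca interpolation), and its wall-volume weight is its node fraction.
Segments with no activated node are flagged, excluded from averages, and
driven at diastolic calcium. Average MAT and EMD are taken over all
mechanically activated segments of both ventricles, with exclusions
counted and reported.

Two couplings close the loop:

* **Inter-segment prestretch.** Segments of a ventricle share a mean-field
  elastic constraint: segment `s` feels an external load
  `k·(SL_s − SL̄)` (k = 2 normalized force/µm, below the `K_SE = 4`
  stability bound), so early-shortening segments stretch still-passive
  ones — the lumped analogue of fiber continuity, and the mechanism by
  which dyssynchrony raises average EMD and CRT lowers it. A
  cavity-pressure-based load was evaluated and rejected: it loads all
  segments simultaneously and cannot produce the differential prestretch
  that drives the EMD effect.
* **Chamber pressure.** `P = P_passive(V) + c_act·T̄·(V − V_d)/(V_ref −
  V_d)`, with `P_passive` exponential and `T̄` the weighted mean active
  tension. The linear volume factor is a tension-scaled end-systolic
  pressure–volume relation — the minimal representation of
  length-dependent pressure generation; a pure thick-sphere geometric
  factor lacks it and produces runaway ejection.

The circulation is the eight-compartment closed loop of the schematic
(passive atria `C_LA`/`C_RA`, systemic and pulmonary artery/vein
compartments, diode valves `R_MI`, `R_AO`, `R_TR`, `R_PU`), advanced with
conservative forward updates at the mechanics step; total blood volume is
conserved to floating-point accumulation and asserted over the full 20 s.
The source study cites but does not print its circulation constants, so
the defaults here were hand-tuned — preload volume, systemic resistance
(2300 mmHg·ms/mL), arterial compliance (0.85 mL/mmHg, giving a realistic
~1.3 s arterial time constant) and `c_act` — until the failing no-LVAD
baseline at BCL 600 ms sits near the published normal row: EDV ≈ 88 mL,
EF ≈ 37 %, CO ≈ 3.3 L/min, peak LV pressure ≈ 148 mmHg. Absolute
hemodynamic numbers are therefore calibration-dependent and are treated as
qualitative anchors; only directional statements are asserted.

The LVAD is a constant-flow generator, default 3 L/min, withdrawing from
the LV volume balance continuously (diastole included — no suction guard
beyond the negative-volume abort) and delivering to the systemic artery.
Under support, CO = forward aortic + device flow and EF is reported as
`NA` (the loop shape is device-distorted).

## Study protocol and reported quantities

Each condition runs: electrical activation for 250 ms (one beat at the
calibrated CV; EAT maps saturate well before this), segment mapping, then
34 mechanical beats at BCL 600 ms (20.4 s) with metrics from the final
beat — end-diastole/end-systole defined as the volume extrema of that
beat, tension/ATP snapshots at end-systole, strain at end-diastole.
`pv_metrics()` reports EDV, ESV, SV, EF, CO, peak LV pressure and its
time, and aortic-valve open duration (time with positive aortic flow).
`summarize_effects()` computes percent reductions with the untreated
scenario as denominator, rounded to one decimal, and CO deltas in L/min —
the same arithmetic that, applied to the transcribed published
per-condition table (`reference_hemodynamics()`), reproduces the published
effect sizes exactly (a frozen test).

Determinism: every stochastic choice (lattice jitter, terminal placement)
derives from the configuration seed through a package-local xorshift
stream; the global RNG is never touched, and identical configurations give
bit-identical results.

## Problem sizes

Default sizes were chosen so a full build-and-verify cycle fits
comfortably on one CPU: ≈ 3000 tissue nodes at 0.24 cm spacing (five
unique electrical solves of 250 ms at dt 0.05 ms), 2 × 18 myofilament
segments over 34 beats at dt 0.05 ms, 20-beat cell pre-pacing, and
2 cm/201-node calibration cables. The whole seven-condition study runs in
roughly two minutes; all sizes scale up through configuration
(`study_setup(target_nodes=, n_segments=)`).

## What the synthetic setting does and does not show

The generator reproduces the *structure* of the study — transmural
layering, two chambers with region labels, two Purkinje bundles with
endocardial terminals, block/CRT/LVAD interventions, a stiffened failing
baseline — but not human anatomy: no imaging-derived fiber/sheet
orthotropy (diffusion is axis-aligned), no anatomical wall-thickness
distribution, a lattice two orders coarser than the full-resolution mesh,
and hand-tuned circulation constants. Consequently absolute activation
times, pressures and ATP units differ from the published absolute values,
and passing tests certify the directional physics (activation orderings
across rhythms, CRT and LVAD effect signs, conservation laws, calibrated
CV, device flow contract) plus exact reproduction of the published effect
sizes from the published table — not quantitative prediction for real
ventricles. Known limitations shared with the source study: single-site
CRT without AV/VV-delay optimization, no right-sided assist device, no
mechanoelectric feedback, no long-term remodeling, and EF undefined under
LVAD support.
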