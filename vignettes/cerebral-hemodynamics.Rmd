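---
title: "Quantifying cerebral hemodynamics with a reduced-order, ASL-calibrated network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral hemodynamics with a reduced-order, ASL-calibrated network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowflow)
```

## The problem

In cerebrovascular occlusive disease, the hemodynamic burden of a carotid
stenosis is poorly captured by its anatomical grade: two patients with the
same "70–99%" lesion can have entirely different cerebral pressures, flows
and collateral recruitment, depending on the Circle of Willis (CoW) anatomy,
the patency of communicating arteries and the autoregulatory state of the
distal microvasculature. `cowflow` implements a strategy for making that
burden quantitative: a patient-specific blood-flow model of the aorta, neck
arteries and CoW whose outflow boundary conditions are *calibrated* from
perfusion MRI (arterial spin labeling, ASL), phase-contrast MRI (PC-MRI)
flow waveforms and a brachial cuff pressure, then *validated* through the
fractional blood supply (FBS) each vascular territory receives from each
neck artery, and finally *interrogated* for stenosis severity metrics.

## The model

### Reduced-order network solver

The vasculature is a directed graph of lumped segments from the ascending
aorta to 13 outlets (descending aorta, two subclavians, two external
carotids, and eight intracranial arteries: RACA, LACA, RMCA, LMCA, RPCA,
LPCA, RSCA, LSCA). Each segment carries a Poiseuille resistance
$R = 8\mu L/(\pi r^4)$ and an inertance $L_I = \rho L/(\pi r^2)$; blood is
Newtonian with $\mu = 0.004\ \mathrm{kg\,m^{-1}s^{-1}}$ and
$\rho = 1060\ \mathrm{kg\,m^{-3}}$. A focal stenosis adds a nonlinear
element
$$\Delta P(Q) = K_v Q + K_t\, Q\,|Q|,$$
with $K_v$ the Poiseuille resistance of the minimal lumen and $K_t$ a
Borda–Carnot expansion loss computed from the minimal and reference lumen
areas. Junctions enforce pressure continuity and mass conservation with no
junction losses — the standard lumped-network closure.

Each outlet is coupled to a three-element Windkessel: proximal resistance
$R_p$, distal resistance $R_d$, compliance $C$, with the distal (venous)
reference pressure fixed at 0. No venous pressure is available from the
measurement set this package targets, and the outlet-resistance check
$R = \bar P/\bar Q$ used in reporting is consistent with a zero reference;
this is a deliberate, documented choice.

The solver advances the network with backward-Euler steps (default
$\Delta t = 1$ ms — adequate for a non-stiff lumped system; halving the step
changes outlet mean flows by well under 0.5%). Inertance is folded into an
effective per-step conductance, the stenosis nonlinearity is
Picard-linearized within each step, and the Windkessel capacitor pressures
are solved monolithically with the nodal pressures, so junction mass
conservation holds to machine precision at every step. Whole cardiac cycles
are repeated until the relative $L_2$ cycle-to-cycle change of every
monitored signal falls below $10^{-3}$ (default cap 20 cycles). This 0D
solver replaces a 3D finite-element computation deliberately: everything the
calibration and supply-tracking stages consume is the periodic
pressure/flow state per segment, and that contract is solver-agnostic. What
is lost is genuinely 3D physics — secondary flows, basilar stream crossing,
wall shear stress — and no claim is made about those.

### From images to target flows

Non-selective ASL perfusion signal (voxelwise control − label, averaged over
pairs) is integrated over each territory $j$ of a 7-territory vascular atlas
to give perfusion splits
$$ps_j = \frac{\int_{V_j} s\, dV}{\int_{\mathrm{brain}} s\, dV},$$
where "brain" is the union of the seven territories (background excluded).
Splits are turned into per-artery target flows by
$\bar Q_{\mathrm{target},i} = \bar Q_{\mathrm{CoW}} \cdot ps_j \cdot
w_{ij}$, where $\bar Q_{\mathrm{CoW}}$ is the summed PC-MRI mean flow of the
two ICAs and two VAs and $w_{ij}$ maps territories to arteries (each
cerebral territory to its artery; the cerebellum split evenly between the
two superior cerebellar arteries). External carotid targets come directly
from PC-MRI; each subclavian is assigned 5.6% of cardiac output (the cited
branch-flow distribution is interpreted per subclavian — an explicit,
configurable choice, since the source is ambiguous); the descending aorta
receives the remainder.

Total arterial resistance and compliance come from cuff pressures and the
aortic inflow waveform:
$$R_T = \frac{P_{\mathrm{mean}}}{Q_T},\quad
P_{\mathrm{mean}} = \tfrac13 P_{\mathrm{sys}} + \tfrac23 P_{\mathrm{dia}},
\qquad
C_T = \frac{Q_{T,\max} - Q_{T,\min}}{P_{\mathrm{sys}} - P_{\mathrm{dia}}}\,
\Delta t,$$
with $\Delta t$ the lapse from the aortic flow maximum to its minimum
(wrapping across the period). Initial per-outlet parameters distribute these
totals: $R_i = P_{\mathrm{mean}}/\bar Q_{\mathrm{target},i}$ (so the
parallel combination is exactly $R_T$ and each outlet draws its target at
mean pressure) and $C_i = C_T R_T / R_i$ (compliance proportional to flow
share). The initial $R_p{:}R_d$ split is 6%/94%; the proximal share
approximates a characteristic impedance and is re-tuned in stage 2. These
identities are asserted to $10^{-12}$ in the test suite.

### Three-stage calibration

1. **Mean flows.** After each simulated cycle, every outlet's distal
   resistance is updated proportionally to its relative flow error,
   $R_d \leftarrow R_d\,(1 + g\,(\bar Q - \bar Q_t)/\bar Q_t)$ with gain
   $g = 0.5$, until the maximum error on a *fully periodic* solution is
   below 1%. Updates are applied per cycle using cycle means rather than per
   time step: the cycle mean is the controlled quantity, and per-step
   updates destabilize the lumped system. The update factor is clamped to
   [0.2, 5] and $R_d$ floored at a small positive value (an exactly-zero
   resistance would make the boundary condition singular).
2. **Pulsatility.** A single scalar factor on the $R_p/R_d$ ratio of all
   cerebral/cerebellar outlets is bisected until the mean absolute mismatch
   of the pulsatility index $PI = (Q_{\max}-Q_{\min})/\bar Q$ between
   simulated and measured ICA/VA waveforms is below tolerance (0.02).
   "Similar pulsatility" names no metric in the source methodology; PI is
   the standard clinical choice. Every candidate preserves each outlet's
   $R_p + R_d$ bit-exactly, so stage-1 flows are untouched. If no factor in
   the bracket crosses zero error, the best factor found is returned with a
   warning.
3. **Pressures.** $R_T \leftarrow R_T (\bar P_{\mathrm{meas}}/\bar
   P_{\mathrm{sim}})$ and $C_T \leftarrow C_T
   (\mathrm{pulse}_{\mathrm{sim}}/\mathrm{pulse}_{\mathrm{meas}})$, each
   relative change applied multiplicatively to every outlet (preserving its
   $R_p{:}R_d$ split), with pressures read at the subclavian outlet as the
   brachial surrogate. Both sides of the mean-pressure ratio use the cuff
   formula $\tfrac13 P_{\mathrm{sys}} + \tfrac23 P_{\mathrm{dia}}$: the
   (mean, pulse) pair then pins systolic and diastolic individually at the
   fixed point. Three consecutive error increases trigger a damped retry.

Stage 3 rescales $R_T$ and can therefore perturb stage-1 flows; the
orchestrator re-checks them afterwards and repeats stage 1 once if any
outlet drifted beyond tolerance. The source describes no re-iteration; one
re-check is this package's resolution of that ordering conflict.

### Fractional blood supply

Two independent routes compute, for each territory $j$ and neck artery $k$,
the fraction $FBS_{j,k} = Q_{j,k}/\sum_k Q_{j,k}$ of the territory's supply
originating at that artery:

- **Junction mixing (deterministic).** On the cycle-mean flows, each labeled
  neck segment carries a pure composition and every junction outflow is the
  flow-weighted mixture of its inflows. The outlet rows of the resulting
  linear system are probability vectors by construction. Complete mixing is
  the only defensible closure in 0D — a lumped model carries no secondary
  flow structure, so phenomena like vortex-driven crossing of the two
  vertebral streams in the basilar artery are explicitly not reproducible.
- **Particle routing (stochastic).** Massless particles are injected at the
  neck arteries at a rate proportional to instantaneous source flow over 4
  cycles, advected with transit time = segment volume / time-resolved flow,
  and routed at junctions with probabilities proportional to instantaneous
  outflows. Because routing uses time-resolved rather than cycle-mean
  splits, particle FBS can differ slightly from mixing FBS when junction
  splits vary over the cycle; both are reported. Segments whose flow
  reverses during the cycle are traversed with signed flow and flagged.
  Routing is reproducible for a fixed seed.

On the measurement side, vessel-selective ASL volumes are divided by their
labeling efficiencies, summed into a total perfusion image, divided
voxelwise into FBS maps (voxels whose total is below $10^{-9}$ of the
maximum are masked rather than divided — the source never specifies this
case), and summarized per (territory, artery) by the median and the *raw*
median absolute deviation (no 1.4826 consistency factor: the methodology
names the statistic, not a normal-consistent estimator). Negative voxel
values are legitimate ASL noise and are retained in the statistics; any
clipping of FBS maps to [0, 1] is a visualization device only.

### Stenosis metrics

From the periodic solution: mean trans-stenotic pressure drop
$\Delta\bar P = \bar P_{\mathrm{prox}} - \bar P_{\mathrm{dist}}$ over the
nodes bracketing the lesion, fractional flow $FF = \bar
P_{\mathrm{dist}}/\bar P_{\mathrm{prox}}$ evaluated at baseline
(non-hyperemic) flow, and per-outlet distal resistance $\bar P/\bar Q$
(zero venous reference). The conventional $FF = 0.8$ significance threshold
is attached as an annotation, never as a classification.

## The synthetic cohort

The generator states a world and inverts the measurement pipeline over it:

- Anatomy: a 35-segment template (aorta, arch branches, neck vessels, CoW
  ring) with literature-plausible adult dimensions and ±3% seeded jitter.
  Variants mirror the three study anatomies: complete CoW; bilateral
  posterior-communicating hypoplasia; right P1 plus distal right vertebral
  hypoplasia. Hypoplasia is segment *removal* — never a zero radius.
- Truth: resting flows (cardiac output 83 ml/s, CoW inflow ≈ 14 ml/s,
  5.6% of cardiac output per subclavian, MCA ≈ 3.2–3.4 ml/s) distributed
  into a ground-truth Windkessel set under a 120/80 mmHg cuff pair, then
  simulated to periodicity.
- NS-ASL: 8 label/control pairs (the consensus protocol count) on a
  64×64×24, 3 mm grid; each territory's mean signal difference is
  proportional to its true blood flow — the premise that perfusion signal
  integrates to territory supply — with additive Gaussian voxel noise, the
  simplest model consistent with the observed negative-FBS noise in real
  data. Default noise is 5% of the mean within-brain signal, the level at
  which the robustness properties are stated.
- VS-ASL: per artery, the NS signal times the territory's true FBS from
  that artery times a labeling efficiency (defaults 0.85 carotid, 0.80
  vertebral — typical measured pCASL efficiencies), plus noise.
- Waveforms: simulated aortic/neck/ECA series downsampled to 40 frames
  (PC-MRI-like) with 2% additive noise; brachial pressures are the
  simulated subclavian extrema rounded to 1 mmHg (cuff resolution).
- Images are generated directly on the atlas grid; template registration is
  an external preprocessing step and out of scope. The atlas is a labeled
  block partition, not brain-shaped.

A green test on this cohort establishes that the *pipeline* is
self-consistent — that calibration recovers the stated world and the two FBS
routes agree — not that the model reproduces any particular patient's 3D
hemodynamics, which depend on geometry and physics deliberately excluded
here.

## Numerical choices and degenerate inputs

- Time step 1 ms; periodicity tolerance $10^{-3}$ relative $L_2$; at most 20
  cycles, then a classed convergence error with diagnostics.
- Stage tolerances: 1% (flows), 0.02 mean |ΔPI| (pulsatility), 1 mmHg
  (pressures). Controller gain 0.5.
- Degenerate inputs raise classed conditions: flat inflow waveforms, zero
  whole-brain perfusion, nonpositive targets, stenosis on a removed
  segment, atlas labels outside 0–7, mismatched grids.
- Near-zero total perfusion voxels are masked in FBS maps; particles in
  stagnant segments are retired and counted in the ledger.
- mmHg ↔ Pa uses 133.322 exactly; all internal computation is SI.

## Known limitations

No 3D/1D distributed physics (wall shear stress, secondary flows,
fluid–structure interaction); no leptomeningeal collaterals; no absolute
perfusion quantification (ml/min/100 g) — targets require PC-MRI inflow; no
hyperemia model for FF; complete junction mixing in the deterministic FBS
route. The block atlas ignores border-zone uncertainty, which is a real
issue for measured ASL.
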