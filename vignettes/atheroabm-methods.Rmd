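---
title: "Modeling leukocyte transendothelial migration and plaque growth with atheroabm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling leukocyte transendothelial migration and plaque growth with atheroabm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`atheroabm` simulates early atherogenesis in a straight, left-anterior-
descending-like coronary segment as a coupled agent-based / hemodynamic
system. The artery is voxelized into cubic patches of 100 um: a lumen of
radius 1800 um, a one-patch endothelial (EC) shell, a 600 um wall and an
exterior margin; each time tick is one hour. Five soluble species
(TNF-alpha, IL-1beta, IL-10, LDL, oxidized LDL) live on the wall voxels;
discrete leukocyte agents (neutrophils, monocyte-derived M1/M2
macrophages, lymphocytes, foam cells) occupy wall patches subject to a
capacity constraint: 60% of every patch is fixed extracellular matrix,
so 40% of the patch volume (4% in accelerated mode) is available to
cells.

One tick applies, in fixed order: soluble-species transport,
recruitment and transmigration at the endothelium, chemotaxis of wall
agents, differentiation and death, compensatory remodeling, and a
conditional wall-shear-stress (WSS) update when the lumen geometry has
changed.

### Transport

Cytokines and LDL diffuse by Fick's law with diffusivities 3e-11 and
2.5e-11 m^2/s; the lumen-facing and outer-wall boundaries are perfect
sinks (convective washout). With the 1 h tick the Fourier number is
D dt / h^2 ~ 10.8, far beyond the explicit stability limit of 1/6, so a
tick is split into `ceiling(8 D dt / h^2)` sub-steps. The 1/8 bound is
deliberately inside the 1/6 limit: at alpha = 1/6 the scheme's
highest-frequency (checkerboard) mode has gain near -1 and survives a
whole tick when the field contains sharp sources; at alpha <= 1/8 all
oscillatory modes decay immediately, and at alpha near 1/6 the
sub-stepped kernel's fourth cumulant nearly vanishes, which is why the
unit suite can hold it to within 1% of the continuous heat kernel. A
dense Crank-Nicolson reference integrator over the same lattice operator
provides an independent cross-check in the tests. Localized fields are
updated only inside the bounding box of their support plus a 4.5-sigma
halo of the one-tick kernel; the truncated tail is below 1e-5 of the
field and the optimization is tolerance-tested against the full-domain
update.

Production follows the per-cell rates (TNF-alpha 5e-6 and 6.7e-4, IL-1beta
5e-7 and 5e-5 U/ml/h for neutrophils and monocyte-lineage cells; IL-10
3.75e-5 U/ml/h for lymphocytes). Monocytes differentiate at wall entry,
so the monocyte rates are carried by the M1 (pro-inflammatory)
phenotype, M2 cells produce IL-10 at the lymphocyte rate, and foam cells
are secretion-silent — the standard phenotype assignment for
lipid-laden macrophages. IL-10 removes the pro-inflammatory species as
`IL1B <- (1 - 0.0096 IL10) IL1B` and `TNFA <- (1 - 0.0095 IL10) TNFA`
per tick, floored at zero.

LDL enters through the endothelium as a shear-gated Dirichlet boundary:
the wall-surface concentration is `C_w = c0 P(tau)` with `P` the
empirical sixth-degree polynomial of WSS and c0 the luminal
concentration (960 ng/ul normal); 70% of `C_w` is imposed on each EC
voxel before diffusion. The printed polynomial carries a duplicated
cubic term; the default reading takes the second occurrence as
quadratic, completing the degree sequence 6..0 (the literal reading is
available behind a flag, `literal_cubic`). 1.2% of local LDL oxidizes
per hour; oxLDL is immobile and accumulates until macrophages find it.

### Recruitment

Each EC patch converts its stimuli — local WSS (Pa) and cytokine
exposure (U/ml) — into per-tick adhesion probabilities through the
piecewise empirical dose-response rules (quadratic/cubic in WSS with
hard domain cut-offs at 1.2, 1.0 and 0.41 Pa for neutrophils, monocytes
and lymphocytes; saturating sigmoids in TNF-alpha and IL-1beta). The
rule value `f` becomes a probability via `p = kappa f h dt / t_norm`,
clamped to [0, 1]. The exposure durations of the source adhesion assays
are not published, so the scale `kappa` is calibrated once per pathway:

* the cytokine-pathway scalar is pinned so that the neutrophil
  IL-1beta response yields p = 0.247 per tick at 0.04 U/ml, the upper
  end of the concentration range the simulated endothelium actually
  experiences;
* the shear-pathway scalar is fixed by `calibrate_recruitment()`, which
  solves (deterministically, on expected counts) for the value that
  makes the cycle-averaged hourly transmigration on the 1.0 mm
  spherical-plaque fixture equal 16 cells/hour. It is then frozen for
  every other experiment. With the default geometry this lands near
  1.8e-3, which puts the low-shear adhesion probabilities at O(0.1) per
  patch per hour — the same order as the cytokine pathway, as the
  in-vitro literature implies.

Recruitment only acts on **activated endothelium**. An EC patch is
activated when its local pro-inflammatory concentration exceeds a
threshold (5e-8 U/ml) or when it directly overlies plaque (a wall
neighbour containing leukocyte-derived cells) — the dysfunctional
endothelium covering a lesion. This gate is a deliberate design
decision: the printed cytokine dose-response fits carry non-zero
intercepts (their assayed range does not extend to zero exposure), and
without a gate any infinitesimally exposed patch would adhere at
p ~ 0.25 per hour, producing recruitment rates orders of magnitude
above every published magnitude while also breaking the homeostasis of
a healthy artery under transient WSS dips. With the gate, a quiescent
artery at 1.4 Pa recruits nothing at any spike amplitude, and
recruitment is confined to the plaque-adjacent endothelium. The
threshold value is set from the ignition scale of the standard
15-leukocyte insult, whose steady cytokine halo peaks near 1.5e-7 U/ml
at the endothelium: the default activates the order-ten nearest EC
patches.

The per-patch leukocyte supply is Poisson with mean
(blood concentration x patch volume): 7000 cells/mm^3 split
62/5.3/30% gives 4.34 neutrophils, 0.37 monocytes and 2.10 lymphocytes
per patch. Pathways combine as independent competing causes
(`1 - prod(1 - p_i)`), adherent cells are binomial draws, and each
adherent cell transmigrates with the stiffness-dependent fraction
(72.5% for monocytes/lymphocytes and 74.5% for neutrophils at the
healthy 3 kPa).

### Wall agents

Transmigrated cohorts enter through the wall voxel adjacent to their EC
patch; cells entering the same patch in the same tick reuse the first
cell's destination until it fills (the shared-path shortcut). Monocytes
draw their permanent phenotype at entry, M1:M2 = 2:1. Every mobile cell
takes at most one 100 um chemotaxis step per tick, to the 26-connected
wall neighbour with free capacity and the highest TNF-alpha + IL-1beta
concentration, stopping at local maxima; ties break uniformly at
random. Because diffusion is fast relative to the tick, the cytokine
maximum can sit one voxel off a discrete source (toward the mid-gap
between the two sink boundaries); the worked chemotaxis example in the
tests therefore checks arrival at the concentration maximum, within one
voxel of the source, by tick 8. Macrophages sitting in oxLDL above
100 ug/ml become foam cells (volume growing to the 25 um sphere;
conversion defers if the voxel cannot host the larger cell until space
frees). Neutrophils die after 72 ticks, monocyte-lineage cells and
lymphocytes after 168; foam cells persist and constitute plaque.

### Glagov remodeling

Plaque area of a plane is the number of wall patches containing
leukocyte-derived cells; lumen area is the plane's lumen patch count.
Growth demand ratchets on plaque volume: every time a plane's plaque
volume (placed cells plus cells waiting for space) has grown by one
voxel-capacity since the last remodel event, the plane adds a voxel.
Below the 40% plaque/lumen threshold the voxel is added outward
(exterior voxel adjacent to the most burdened wall sector — the lumen
is preserved); at or above 40% each event goes inward with probability
0.65 (the lumen voxel in front of the most burdened EC patch becomes the
new endothelium and the old EC patch becomes plaque-bearing wall) and
outward otherwise. Inward growth that would occlude a plane raises an
error. Because inward sites follow plaque burden, the first protrusions
appear off the centerline of an eccentric lesion, as an emergent
behaviour.

### Hemodynamics

The default waveform is a biphasic, diastole-dominant left-coronary
curve: period 0.8 s sampled at 0.01 s, peak flow ~1.85x the mean in
early diastole, a deep early-systolic trough (~0.22x) and partial
late-systolic recovery; it is normalized so the healthy artery runs at
a mean WSS of 1.4 Pa (the corresponding mean flow is 1.83e-6 m^3/s from
the Poiseuille relation with blood viscosity 3.5e-3 Pa s and density
1060 kg/m^3).

WSS comes from a pluggable backend. `poiseuille` applies
`tau = 4 mu Q / (pi r_eff^3)` per plane using the area-equivalent
radius. `axisym` (the default) solves steady laminar axisymmetric
Navier-Stokes in stream-function/vorticity form on the area-equivalent
profile, mapped to the unit-radius strip, with first-order upwind
convection, Thom wall vorticity, Poiseuille inflow, zero-gradient
outflow (standing in for a constant-pressure outlet), straight
inlet/outlet buffer extensions and a rigid wall; convergence is declared
when the wall-shear profile changes by less than 3e-4 (relative) per
hundred pseudo-time cycles. It reproduces the Poiseuille closed form
within 5% on straight tubes and captures the post-stenotic shear
undershoot and recirculation that drive distal transmigration. Repeated
solves warm-start from the previous solution scaled by the flow ratio.
Plane values map to EC voxels with an azimuthal wall-proximity
modulation (protruding patches see more shear), renormalized to the
plane mean; `imported` fields (per-voxel CSV) bypass the built-in
solvers entirely. Quasi-steadiness is assumed at every waveform phase
(no Womersley dynamics), and the area-equivalent axisymmetric surrogate
cannot reproduce the three-dimensional wake of a one-sided bump — the
known, documented fidelity limit of the built-in backends.

Evaluation policies: `peak_systole` solves one field at maximum flow,
`steady_mean` one field at the time-averaged flow, and `full_cycle`
solves one field per waveform sample; under `full_cycle` the per-tick
recruitment probability is the cycle average of the per-phase
probabilities (a stride parameter subsamples the 80 phases, default
every 8th, as a quadrature economy for long sweeps). The handshake
schedule recomputes WSS whenever the lumen voxel count changes
(`per_lumen_change`) or after a severity-class quota of cumulative
changes (80/35/10 patches, `accelerated`).

## Fixtures and experiment protocols

Spherical-plaque fixtures are lesions centred radially at the middle of
the wall: mostly intramural, bulging the wall outward (exterior voxels
inside the sphere become wall — a compensatorily remodeled lesion),
with a luminal cap that sets the stenosis. Wall voxels inside the
sphere are seeded with foam cells to capacity. Radii 0.7, 1.0 and
1.5 mm give 2.2%, 6.7% and 18.6% maximal area stenosis — the small
(0-5%), medium (5-20%) and big classes. An intramural reading is the
only one consistent with a "0-5% stenosis plaque": a lesion with
near-zero stenosis must live inside the wall, and it is also what makes
the 40% plaque/lumen threshold mechanically reachable.

The cardiac-cycle timescale experiment and the accelerated stenosis
sweeps isolate the shear pathway (recruitment restricted to the WSS
rules, on contact-activated endothelium), measuring transmigration as a
function of WSS alone; the atherogenesis, spike-stability, knockout and
stochasticity experiments run the full model. The 15-leukocyte insult
is composed per blood proportions (9 neutrophils, 1 monocyte entering
as M1, 5 lymphocytes) and placed mid-wall, half-way along the artery.

Named RNG streams (recruitment, chemotaxis, differentiation,
remodeling) derive from one master seed, so identical configurations
replay byte-identically and sub-processes can be replayed independently.

## Numerical and design choices at a glance

* Voxel membership by centre-in-region test; 0-based physical
  coordinates `(index - 0.5) x 100 um`; z is the flow axis.
* EC shell defined by face-adjacency to the lumen and re-derived after
  every geometry edit; agents reside only in wall voxels.
* Chemoattractant = TNF-alpha + IL-1beta with equal weights
  (configurable); 3D Moore neighbourhood; one step per tick.
* Tie-breaks (chemotaxis destinations, remodeling sites) are uniform
  random draws on the owning stream.
* oxLDL is immobile; foam conversion does not deplete it (no published
  stoichiometry; a per-cell uptake is available behind a config flag).
* Transient volume loss by cell death does not shrink the wall
  (growth is ratcheted; the model has no regression pathway).
* The dense Crank-Nicolson integrator exists for cross-checks on small
  domains only; production transport always uses the sub-stepped
  explicit scheme.

## What the synthetic fixtures do and do not show

The generator emulates an idealized straight segment: circular
cross-section, uniform wall composition, rigid walls, spherical
lesions, and a literature-shaped (not patient-measured) coronary
waveform. Passing tests demonstrate internal consistency of transport,
recruitment, growth and hemodynamic coupling at physiological scales —
not fidelity to any individual patient geometry, to curved or branched
vessels, to fluid-structure interaction, or to the three-dimensional
wake structure of eccentric lesions (importable external WSS fields
exist precisely for that). Smooth-muscle and ECM dynamics are out of
scope; the fixed 60% ECM fraction means simulated growth rates run
faster than in vivo.

## Known limitations

Two limits are worth stating explicitly. First, the built-in WSS
backends are axisymmetric surrogates: on mildly stenosed fixtures the
peak-flow field has no sub-1.2 Pa wake, so cycle-averaged recruitment is
carried by the low-flow phases and the single peak-flow field
under-recruits relative to the full cycle; quantities that hinge on the
three-dimensional wake of an eccentric lesion (the sharpness of the
TEM-rate transition, the pulsatile-to-steady ratio) inherit this bias.
Second, the matched-time transport makes the inflammation loop
bistable: the steady endothelial concentrations produced by the printed
per-cell rates sit orders of magnitude below the assayed range of the
dose-response fits, so depending on the low-dose taper the lesion either
goes extinct or grows as a burst that self-silences when its
macrophages convert to (secretion-inert) foam cells. The default
parameters select the self-sustaining branch; intermediate multi-month
plateau dynamics are not reachable at a fixed parameterization, and
long-horizon timing quantities should be read with that in mind.

## Problem sizes used by the shipped experiments

The worked experiments are sized for a desk machine: timescale runs use
a 24-tick transport burn-in, 80 WSS solves per fixture and 3 replicate
seeds; accelerated sweeps cap at a cumulative lumen change of ~130
patches with the stride-8 cycle quadrature; the acceptance checks of
the long-horizon behaviours (threshold onset, knockout, run-to-run
spread) run the atherogenesis preset over windows of a few hundred to a
few thousand ticks with 2-3 seeds. Larger replications change none of
the mechanics, only the statistics.
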