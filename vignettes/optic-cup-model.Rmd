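---
title: "A spring-based vertex model of optic-cup self-organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spring-based vertex model of optic-cup self-organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 7, fig.height = 5)
library(opticcup)
```

## The biological problem

The optic vesicle is a hemispherical outpocketing of the early forebrain
whose distal wall folds inward to form the two-walled optic cup: the
invaginated neural retina (NR) inside, the retinal pigment epithelium
(RPE) outside. In three-dimensional stem-cell culture this invagination
happens *without any external tissue pushing on the retina*, which raises
a mechanical question: what sequence of internal, local changes in tissue
properties suffices to fold a hemisphere into a cup?

The relaxation-expansion model answers with three local rules applied in
sequence to an initially tense epithelium:

1. **Relaxation** — the presumptive NR (the distal cap) loses actomyosin
   tone: its stored tangential tension is released and its stiffness
   drops, leaving a mechanically flexible, effectively plastic tissue.
2. **Apical constriction** — the narrow hinge band between NR and RPE
   constricts apically into wedge-shaped cells, biasing the NR rim to
   bend inward.
3. **Tangential expansion** — the NR and the distal RPE proliferate
   rapidly; the flexible NR, expanding against the stiffer RPE shell,
   buckles inward and involutes.

`opticcup` implements this as an axisymmetric spring-based vertex
simulation and classifies the outcome of a run as *invaginated*,
*evaginated*, or *flat*.

## Discretization and energies

A meridional half-section of the vesicle (a quarter-circle from the
proximal equator to the distal pole) is discretized into `n` apical and
`n` basal vertices (default `n = 100`), joined into `n - 1` quadrilateral
elements by apical, basal, and transmural springs. Proximal to distal,
elements are labelled `non_retinal`, `RPE`, `hinge`, `NR` (default arc
fractions 20 / 34 / 6 / 40 %); the labels decide which rule acts where.
Vertices move by overdamped gradient descent,
`eta dr/dt = -dU/dr`, with the proximal boundary pair pinned and the two
pole vertices held on the symmetry axis. `U` is a sum of four terms:

* **Elastic** — Hookean springs, `U_e = sum (k/2)(l - l0)^2`. The natural
  lengths and stiffnesses are what the protocol manipulates.
* **Volumetric** — `U_v = sum (k_v/2)((V - V_eq)/V_eq)^2 V_eq` with the
  axisymmetric element volume `V = 2 pi xbar A` (planar quadrilateral
  area times the circumferential weight of its mean off-axis distance).
  The `V_eq` scaling keeps `k_v` comparable across elements and while
  equilibrium volumes grow.
* **Self-righting** — `U_s = sum (k_s/2) w (theta - theta_eq)^2` over the
  four corner angles of each element, resisting shear distortion. This is
  also the term that suppresses element-scale wrinkling of a compressed
  region. The weight `w = min(1, l_u l_v / l_reg^2)` fades the penalty of
  a corner whose edges drop below a regularization length
  (`l_reg` = a quarter of the coarsest tangential spacing, fixed at
  construction): a sharply constricted hinge drives its apical edges far
  below the mesh scale, where a discrete corner angle carries no
  information and its `1/l^2` stiffness would only throttle the
  integrator. The weight is part of the energy, so forces remain exact
  gradients (the test suite checks this against finite differences in
  both the ordinary and the faded regime).
* **Hoop** — each off-axis vertex feels an apparent radial force
  `-w_h k_h (x - x0)/x0`, a linearized circumferential elasticity of the
  revolved vesicle relative to its stress-free radius `x0`. This stands
  in for the three-dimensionality that a 2D section cannot represent.
  `w_h = 1` for circumferential stretch; for compression (`x < x0`) it is
  `1 - hoop_relief`, with `hoop_relief = 0` by default (the symmetric
  linear form). Setting `hoop_relief` toward 1 yields a tension-field
  variant in which circumferential compression is shed, as
  non-axisymmetric buckling would shed it in 3D; the knob is exposed
  because the hoop term is the one part of the model with no unique
  continuum derivation.

## The phase protocol

Phases 0 and 1 are initial conditions applied before any dynamics:

* **Phase 0** (`phase0_prestress()`): apical natural lengths 14% shorter
  than basal (`l0_a = 0.86 l0_b`, equal stiffness) — the uniform
  actomyosin tension that makes the epithelium apically concave — and
  transmural springs 10 times longer and 10 times softer than basal.
* **Phase 1** (`phase1_deepen()`): apical springs of the retinal regions
  (RPE, hinge, NR) shorten a further 10% (net `0.774 l0_b`), fitting the
  deeper curvature of the evaginated vesicle.

The clock then runs through a settling window and Phases 2-4:

* **Rule 1** — from the start of Phase 2 to the end of the run, NR
  apical and basal natural lengths creep toward their current lengths,
  `l0 <- l0 + lambda (l - l0) dt`, for springs under *tension*
  (`l > l0`). This releases exactly the stored contractile prestress and
  keeps the NR plastic through invagination: a fold driven into the NR
  does not spring back elastically, which mirrors the excision behaviour
  of the real tissue. Compressed springs are left elastic by default
  (`lambda_c = 0`): letting compression creep as well makes any incipient
  fold or wrinkle ratchet itself sharper without limit (rest lengths
  chase collapsing edges toward zero), which numerically collapses
  elements and physically corresponds to no observed behaviour. Over
  Phase 3 the NR tangential stiffnesses also ramp linearly to 25% of
  Phase 0 and stay there.
* **Rule 2** — over Phase 3 the hinge apical natural lengths ramp to 10%
  of Phase 0 and the hinge apical stiffness to 10x Phase 0, then hold.
* **Rule 3** — over Phase 4 the tangential natural lengths and
  equilibrium volumes of the NR and the distal half of the RPE scale
  linearly from 1 to `G_final` (default 2), then hold. Length growth is
  applied multiplicatively so that it composes with the rule 1 creep
  acting on the same springs.

All ramps are continuous, and every printed factor (0.86, 0.90, 0.25,
0.10, 10x) is reproduced exactly at the corresponding phase boundary —
asserted to machine precision in the tests.

## Time scales and the integrator

With per-vertex drag, collective modes of a chain of `~100` elements
relax on times of order `(arc/spacing)^2 eta/k` — hundreds of spring
times `eta/k_b = 1`. Morphogenesis is quasi-static only if each phase
spans a comparable time, so the default schedule gives the settling
window and Phases 2-4 150 time units each and the final equilibration
450. (Runs at these horizons take seconds: the inner loop is compiled.)

The explicit Euler step adapts during the run: every 200 steps the core
re-estimates the largest stable step from the stiffest *positive*
per-vertex response — incident spring stiffness (longitudinal plus the
transverse stiffness of stretched springs; the transverse response of a
compressed spring has negative curvature, which descent simply follows),
the volumetric gradient, the faded corner-angle term (bounded by
`~k_s/l_reg^2`), and the hoop term — divided by a safety factor of 4.
Re-estimation matters: the folding hinge stiffens locally as it
constricts, and a step chosen from the segment-start geometry alone
becomes unstable mid-segment, which manifests as spurious element-scale
wrinkling. A pure-R reference integrator (`engine = "r"`) is kept
alongside the compiled core; at a common fixed step the two produce
identical trajectories, which the suite asserts.

Transient self-intersection of a corner at a tight fold apex is
tolerated mid-run — the volumetric penalty pushes it back out — and only
a truly inverted element (non-positive area) aborts a run, preserving
the last good snapshot and refusing classification.

## Parameter choices

The protocol ratios are fixed. The remaining constants were calibrated
once, on the following reasoning, and are not adjusted per scenario:

* `k_b = k_a = 1` define the stiffness unit; `eta = 1` the time unit;
  dome radius 1 the length unit.
* `thickness = 0.16`: with 100 vertices per half dome the transmural
  natural length (10x the basal spacing) is about 0.17, so this
  thickness makes the stress-free transmural state consistent with the
  constructed geometry; it also matches the visibly thick columnar
  epithelium of the vesicle.
* `k_v = 0.3`: strong enough that element volumes track `V_eq` to a few
  percent, weak enough that elements can re-shape through the tight rim
  fold. Larger values lock the dome's shape and suppress involution.
* `k_s = 2e-4`: of order `k_b s^2` (with `s ~ 0.016` the tangential
  spacing), making corner-angle elasticity comparable to spring
  elasticity at the element scale. Much smaller values let compressed
  regions wrinkle at the element scale; much larger ones stiffen
  tissue-scale bending and block the fold.
* `k_h = 1e-3`: the per-vertex spring force scale is `k_b s ~ 0.016`, so
  hoop forces of order `1e-3 x strain` are competitive with meridional
  elasticity without dominating it. The compression side of the hoop is
  what converts NR relaxation into Phase 2 flattening; the tension side
  is what channels Phase 4 expansion inward instead of letting the NR
  balloon outward.
* `lambda = 3`: drains the stored NR strain energy with time constant
  1/3, far inside the 150-unit Phase 2 (the suite checks
  `exp(-2 lambda T) < 0.05`), while remaining slow enough not to ratchet
  the local flow.

## Morphometrics and outcome classification

* `curvature_profile()` — signed discrete curvature of the apical chain
  (inverse circumradius of vertex triples). Positive = the osculating
  centre lies apically ("apically concave", the vesicle's resting
  state); negative = apically convex, the optic-cup signature.
* `nr_flattening_index()` — mean `|kappa|` over the NR at the end of
  Phase 2 relative to the end of Phase 1; below 1 when rule 1 flattens
  the cap.
* `hinge_apical_angle()` — mean apical corner angle of the hinge
  elements (`pi/2` for rectangular elements).
* `invagination_depth()` — displacement of the NR apical surface toward
  the vesicle interior relative to the hinge plane, as the mean over NR
  apical vertices (default) or the single pole vertex.
* `classify_outcome()` — **invaginated** if the mean-NR depth exceeds
  `d_min` (half the epithelial thickness) *and* the **median** signed NR
  curvature has flipped from positive to negative; **evaginated** if the
  depth is below `-d_min` with no flip; otherwise **flat**.

Two statistics here are deliberate robust choices. The folded rim loops
carry local curvatures an order of magnitude above the tissue scale, of
both signs, so a windowed *mean* curvature measures the fold apices
rather than the shape; the *median* asks the categorical question — is
the bulk of the NR apically convex? Likewise the evagination of the
stiff, growing NR proceeds through the second axisymmetric buckling mode
(two outward lobes with the pole in the dip between them), which a
pole-point depth cannot see; the mean-NR depth registers the displacement
whichever mode carries it. The windowed mean curvature and the
pole-point depth are still computed and reported on every outcome.

## What the model reproduces, and its limits

At the default configuration the full protocol produces, in order: a
settled apically-concave vesicle; Phase 2 NR flattening (index 0.985);
Phase 3 hinge wedging (hinge element apical/basal length ratio driven to
0.1); rim involution inside the RPE shell during Phase 4 with the NR
median curvature flipping from +1.09 to -0.74 and the NR moving 0.13
radii inside the hinge plane. Omitting rules 1 and 2 reverses the
outcome: the still-tense, stiff NR balloons outward under the same
growth (depth -0.10, no curvature flip). Omitting rule 3 leaves the
vesicle essentially unchanged — growth is necessary.

Known limitations, beyond the axisymmetry and purely elastic-plastic
constitutive choices shared with the model family:

* **Growth threshold.** A growth fold of 1.5 deposits too little
  tangential compression to carry the involution through; the categorical
  invagination requires `G_final` of roughly 2 or more in this
  implementation.
* **Mesh-resolution sensitivity.** The transmural natural length is tied
  to the tangential spacing by the 10x prescription, so changing the
  resolution changes the physical prestress state, not just the
  discretization: at 60 vertices per surface the thick, strongly
  prestressed section barely folds, and at 140 the finer rim loops carry
  enough wrinkle-scale curvature that the median does not flip. The
  categorical outcome is therefore demonstrated at the canonical 100
  vertices per surface, not claimed as resolution-independent.
* **Hinge corner angles.** The mean apical corner angle of the wedged
  hinge elements stays slightly obtuse (about 1.62 rad): a constricted
  element is a near-pie-slice whose lateral edges fan symmetrically,
  giving apical corners `90 +/- delta` degrees whose mean cannot drop
  below 90. The wedge morphology itself — the prescribed 10:1
  basal:apical length ratio — is fully attained; an acute "apical angle"
  in the tissue-level sense (the fold between the NR and RPE apical
  surfaces) is visible in the rendered sections but is not what the
  element-level metric measures.
* The hoop term is a per-vertex linearization, not a true 3D membrane;
  quantitative depths and curvatures are model-scale numbers, and only
  the categorical outcomes and their ordering across conditions are
  meant to be compared with experiment.

## A worked run

```{r run, eval = FALSE}
cfg <- sim_config()           # full default protocol, n = 100
traj <- run_simulation(cfg)   # ~10 s
classify_outcome(traj)
autoplot(traj)                # sections at every phase boundary
plot_energy(traj)

# the rules-1-and-2-omitted control evaginates instead
ctrl <- sim_config(schedule = phase_schedule(rule1 = FALSE,
                                             rule2 = FALSE))
classify_outcome(run_simulation(ctrl))
```

`sweep_outcomes()` tabulates outcomes over growth folds, resolutions,
and rule knockouts; the `inst/cli/opticcup.R` script exposes `simulate`,
`analyze`, `render`, and `sweep` from the shell.
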