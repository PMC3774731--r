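---
title: "Modelling ventral furrow formation with an apical vertex model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ventral furrow formation with an apical vertex model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(furrowvm)
```

## The model

During the first ten minutes of *Drosophila* gastrulation a band of ventral
epithelial cells constricts its apical surfaces and folds the tissue into the
ventral furrow. `furrowvm` models the apical surface of this epithelium as a
two-dimensional vertex model: a planar tiling of polygonal cells whose vertex
positions evolve by overdamped descent on the potential

$$
E \;=\; \sum_{\text{cells } i} \frac{K}{2}\,(A_i - A_0)^2
\;+\; \sum_{\text{edges } e} \Lambda_e\, l_e
\;+\; \sum_{\text{cells } i} \frac{\Gamma_i(\tilde t)}{2}\, A_i^2 ,
$$

with area elasticity $K$, preferred apical area $A_0$, line tension
$\Lambda_e$ per unit junction length, and an area-based contractility
$\Gamma_i$ (the contractile term has preferred area zero; it acts on the
whole apical surface, not the cell perimeter, because medial actomyosin
drives this constriction). Vertices obey
$\eta\, \dot{x}_v = -\partial E/\partial x_v$, integrated with an explicit
Euler scheme; the analytic force uses the shoelace area derivatives for the
two area terms and unit tangents for the tension term. Vertices on the sheet
boundary are clamped.

We keep a strict distinction between *contraction* (the intrinsic activity
$\Gamma$) and *constriction* (the resulting area change). An isolated cell
with tension removed relaxes to the force-balance area
$A^\* = K A_0/(K+\Gamma)$: constriction saturates where elastic and
contractile forces balance, which is the seed of all stagnation phenomena
below (`equilibrium_area_sweep()` reproduces this closed form to numerical
precision).

### Geometry

The standard sheet is 15 rows (latero-ventral, $y$) by 24 columns
(antero-posterior, $x$) of regular hexagons in brick-offset packing, midline
at row 8. Hexagons are built "flat-top" (two edges parallel to the AP axis),
so at rest each cell carries two *transverse* edges (within 45 degrees of
the AP axis) and four *vertical* ones. Edge classes are re-derived from the
current geometry at every evaluation, since junctions rotate as cells
deform; an edge at exactly 45 degrees is classed transverse (a deterministic
tie-break; the class intervals otherwise share that endpoint). Nothing pins
the hexagon orientation or the row-offset scheme; these are conventions, chosen so that the latero-ventral compression of the furrow is
carried by the cheap vertical-class junctions.

The outermost two columns at each AP end (one, in the sheet-geometry
variants) are the non-contractile *margin*: $\Gamma = 0$ always, and every
junction touching a margin cell uses the high margin tension. The margin
delimits the furrow and absorbs border artefacts; its own immediate
neighbour columns are visibly distorted by it, so trace analytics operate on
the *core* ventral band (five central rows, two further columns dropped next
to each margin), the same region that display panels conventionally crop.

### Mechanical parameters

| parameter | default | units | role |
|---|---|---|---|
| `K` | 2.5 | energy / length^4 | area elasticity |
| `A0` | `hex_area(1)` = 2.598 | length^2 | preferred area (initial hexagon) |
| `lambda_transverse` | 0.2 | energy / length | tension, edges within 45 deg of AP |
| `lambda_vertical` | 0.075 | energy / length | tension, steeper edges |
| `lambda_margin` | 6.0 | energy / length | tension at margin cells |
| `eps_t1` | 0.1 | length | T1 trigger distance |
| `furrow_threshold` | 0.35 | fraction of A0 | completion criterion |

The transverse/vertical asymmetry encodes the measured anisotropic cortical
tension of the ventral epithelium. The energy convention carries the factor
1/2 on both quadratic terms, which makes the printed parameter values
consistent with the $A^\* = K A_0/(K+\Gamma)$ balance. An optional quadratic
edge elasticity (`kappa_edge`) exists behind a flag and is off by default:
only $K$, $\Lambda$ and $\Gamma$ define the standard model.

### Time conventions and friction

Model time $\tilde t$ is the schedule time: contractility ramps, halt
windows and Wiener paths advance one unit per nominal model time-step, and
figure-level schedules (for example a ramp halted over
$\tilde t \in [10, 60]$) are expressed directly in these units. A run to
furrow completion takes roughly 140 units, which the normalization layer
maps onto the 10 minutes of a live recording.

The friction coefficient is `friction_eta = 60` in these units. It was fixed
by a stability argument: a literal one-Euler-step-per-unit scheme relaxes
vertices by the factor $1/\eta$ per step, and $\eta = 60$ is the smallest
value on a decade scan for which that scheme still descends the energy
cleanly through the strongly constricted late furrow at the standard
parameters. The integrator actually subdivides each unit into `1/dt`
sub-steps (default `dt = 0.5`, sub-step displacement factor
$dt/\eta \approx 0.008$) purely for topological robustness; trajectories are
unchanged. Friction sets the only free timescale of the model: the lag
between contractility rate and constriction rate scales with $\eta$, while
completion time is dominated by the ramp and barely moves.

Two bookkeeping subtleties follow from the energy definition:

* **Energy descent accounting.** Because edge classes are re-derived from
  geometry, $E$ jumps discontinuously when a junction crosses 45 degrees
  (its tension switches between 0.2 and 0.075). The descent property of the
  integrator is therefore monitored with the classification frozen over the
  step being checked; class flips and T1 swaps may legitimately jump the
  recorded energy, exactly like topology changes. Under this accounting the
  default integrator descends in 100% of steps, and `run_simulation()` warns
  if more than 1% of steps ever increase.
* **Embedding guard.** The shoelace energy is blind to self-intersection, so
  a cell crushed between the stiff margin and the contractile band can
  genuinely fold through itself (at any step size - it is a property of the
  trajectory, not of discretisation). After each sub-step the integrator
  detects rings with proper segment crossings and bisects the offending
  vertices' displacements, so that vertices stall at contact instead of
  inverting; a whole-cell revert is the final fallback. Guard activity is
  counted in the archive (`guard_events`).

### Contractility programs

All variants compose a spatial weight, a temporal-stochastic scalar and
(for the *twi* variant) a per-cell attenuation:

* **Spatial weight.** Gradient variants use the Gaussian
  $w(i) = \exp\!\big(-(i - Z)^2 / 2\sigma^2\big)$ in the row distance to the
  midline $Z$ ($\sigma = 2$ rows; presets at 1.25, 3.0 and 4.25 narrow or
  widen the furrow). Cutoff variants use an indicator over the five central
  rows. Margin cells always weigh zero. The *alternative* gradient instead
  evaluates the same Gaussian on the cell's current centroid distance to a
  midline coordinate frozen at the first step, so cells grow more
  contractile as they approach the midline - a non-cell-autonomous reading
  of the gradient; row indices are otherwise assigned at construction and
  never change.
* **Temporal-stochastic scalar.**
  $g(\tilde t) = \mathrm{clamp}\big(\Gamma_{\text{init}} + \alpha \tilde t +
  \sigma_W W_{ij}(\tilde t),\ 0,\ \Gamma_{\max}\big)$ with
  $\Gamma_{\text{init}} = 0$, $\alpha = 0.15$, $\Gamma_{\max} = 25$ and
  Wiener amplitude $\sigma_W = 0.3$; each cell owns an independent standard
  Wiener path. The clamp at zero is applied after adding noise (negative
  contractility would be expansile); the cap is applied to the shared scalar
  before spatial weighting, so off-midline cells follow proportionally
  scaled copies of the midline schedule. With $\sigma_W = 0$ the stochastic
  variant reduces *exactly* to the deterministic timed one.
* **twi attenuation.** Each cell draws once, at $\tilde t = 0$, a uniform
  factor $U(i,j) \in [0, 0.5]$ that multiplies its contractility for the
  whole run - weak, patchy apical myosin recruitment frozen per cell, not
  re-drawn per step.

Per-cell noise streams are derived from the master seed keyed on the cell's
(row, column) index, so changing the sheet size does not silently reshuffle
the paths of cells that keep their indices. All increments are stored in the
run archive; replay consumes the stored increments, which is what makes
replays bit-exact and lets `replay()` apply declarative modifications (e.g.
forcing $\Gamma = 0$ on a neighbourhood) against an otherwise identical
realisation.

The preset with globally reduced contractility (`reduced_contractility`,
half the standard peak and cap) is a qualitative illustration - its
parameterisation is not fully pinned down - and is the one
preset whose numbers should be treated as user-tunable rather than
calibrated.

### T1 transitions

When an interior junction between two free, trivalent vertices drops below
`eps_t1 = 0.1`, the two cells sharing it lose adjacency, the two flanking
cells gain it, and the junction re-opens perpendicular through its midpoint
at length 0.15. Swaps are processed shortest-first; a just-swapped pair is
immune for 10 model-time units to prevent flip-flopping. Edges touching
fixed vertices or the outer boundary are skipped and logged, never errors.
A swap whose re-opened junction would twist a flanking ring in the current
crowded geometry is deferred the same way; it usually becomes admissible
after local relaxation. Every executed swap preserves the vertex, edge and
face counts, hence the planar Euler relation $V - E + F = 1$, which
`validate_topology()` asserts together with ring simplicity, incidence
consistency and the gap/overlap-free tiling of the outer boundary polygon.

## Metrics

* **Eccentricity** fits the ellipse with the polygon's area-weighted second
  central moments and reports the ratio of its AP to LV axis-aligned
  extents, $\sqrt{\mu_{xx}/\mu_{yy}}$ (not the principal-axis ratio: the
  measure is defined as the AP-to-LV dimension ratio). A regular hexagon
  gives 1; the standard furrow run drives ventral cells to about 2.
* **Rates** are centered differences of a moving-average-smoothed series
  (default window 5 samples, shrinking symmetrically at the ends so linear
  series pass through exactly).
* **Rate-lag analysis** resamples the archived traces onto a fixed 1 s
  cadence of normalized time before differentiating, so results do not
  depend on the integrator step, then shifts each core ventral cell's
  contractility rate forward by candidate offsets, averages Pearson
  coefficients across cells per offset and reports the maximising offset.
* **Stagnation periods** are maximal intervals in which the smoothed area
  rate stays within a tolerance of zero for a minimum duration, *after*
  constriction has begun (the pre-onset plateau is excluded) and *before*
  it recommences (the terminal approach to force balance is excluded; the
  defining feature of a stagnation is that area reduction resumes). The
  operational thresholds are a free choice; the defaults are a rate within
  2% of $A_0$ per 10 normalized seconds sustained for 30 s, both
  configurable and reported alongside results.
* **Normalization** maps the span of a completed run onto 600 s and model
  areas onto square micrometres via a configurable scale (the initial
  hexagon corresponds to the mean apical area at the end of
  cellularization); eccentricity is scale-invariant.

## What the simulations show - and what they cannot

The generator *is* the study system here: there is no external data path.
The synthetic runs emulate the spatial organisation (graded, ventrally
peaked contractility between stiff margins), the temporal programme (slow
ramp with per-cell stochastic fluctuations) and the mechanical couplings
(elastic resistance, anisotropic junctional tension, neighbour exchange) of
the ventral epithelium. They do not emulate: curvature of the embryo or any
out-of-plane deformation (no invagination), cell division or extrusion,
mechanochemical feedback of strain on myosin, or signalling dynamics.
Passing tests therefore support the mechanical sufficiency arguments - that
a gradient plus noise yields a realistic furrow, anisotropy, stagnations and
the *twi* phenocopy - not any claim about molecular mechanism.

Reproduced, and continuously verified by the test suite: the cutoff model's
artificial band-edge jump against the gradient model's smooth monotone
constriction profile; anisotropic constriction and its dependence on
tension asymmetry (band T1 exchanges become more frequent and eccentricity
drops when tension is symmetric or vertically biased), on sheet geometry
(square vs AP-elongated) and on the gradient; stagnation periods as passive
force-balance episodes - absent without noise, absent in a steadily driven
reduced seven-cell model, present under a halted ramp, removable by
switching off neighbour contractility in an otherwise identical replay, and
temporary dilation under strong neighbour contraction; the forward lag of
roughly 4 normalized seconds at which the contractility-rate /
constriction-rate correlation peaks; and the *twi* attenuation's random
patchwork of constricted and unconstricted cells with raised area variance
and lowered eccentricity.

Known limitations:

* Under symmetric tension, ventral cells keep most of their eccentricity
  (about 1.9 vs 2.0 for the standard asymmetry). The orderings - more band
  T1s, lower eccentricity - hold, but cells do not
  round to eccentricity near 1: at `eps_t1 = 0.1` neighbour exchange is too
  rare to relax the gradient-imposed strain fully.
* "Identical" within-row traces of the deterministic run hold only in the
  core band: areas vary by a few percent with column distance to the
  margins (brick-offset parity plays no role).
* The outermost rows press against the clamped sheet boundary, so the final
  area profile is monotone across the constricted rows but not across the
  dilated boundary rows.
* The lag magnitude is set by the friction coefficient, for which no
  reference value exists; the stability-derived default yields 4 s, below
  the roughly 8 s reported by live-imaging analyses of apical constriction.

## Problem sizes

The test suite runs the full 15 x 24 standard sheet for all figure-level
properties (about 280 integrator sub-steps to furrow completion, a few
seconds per run), five seeds for the lag target, three seeds for each
dichotomy, a refined-step descent check at half the default sub-step, and
small perturbed meshes (3 x 3 to 8 x 10) for the geometric, force-gradient
and T1 property tests. The acceptance script repeats the five-seed lag
measurement from scratch.
```{r example, eval = FALSE}
arch <- run_preset("gradient_stochastic", master_seed = 1)
rate_lag_analysis(arch)$best_offset_s
```
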