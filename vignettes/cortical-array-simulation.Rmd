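---
title: "Simulating the plant cortical microtubule array with local density-dependent nucleation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the plant cortical microtubule array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Cortical microtubules in plant cells are confined to the inner face of the
plasma membrane. `cortarray` represents them as oriented polylines of
straight segments on a closed or periodic surface, and simulates their
collective dynamics with an exact event-driven algorithm.

Individual microtubules follow two-state dynamic instability with hybrid
treadmilling. The plus end grows at `v_plus` (0.05 um/s) or shrinks at
`v_minus` (0.08 um/s), switching stochastically with catastrophe rate `r_c`
and rescue rate `r_r` (0.001 1/s); the minus end retracts steadily at the
treadmilling speed `v_tm` (0.01 um/s) regardless of the plus-end state. In
the bounded-growth regime (negative control parameter G, see below) each
microtubule has a finite intrinsic mean length
`(r_c/(v_plus - v_tm) - r_r/(v_minus + v_tm))^-1` and lifetime; all sweeps
in this package stay in that regime. The catastrophe rate is the natural
tuning knob and has no default: every configuration states it explicitly.

When a growing plus end runs into the lattice of another microtubule the
outcome depends on the collision angle, folded into [0, 90] degrees:

* at most `theta_c` = 40 degrees: *zippering* — the tip reorients alongside
  the encountered microtubule (sign chosen to minimize the turning angle),
  creating bundles;
* above 40 degrees: *induced catastrophe* with probability `P_cat` = 0.5,
  otherwise *crossover* (the tip grows straight through).

Collisions with a bundle count as one collision with a single microtubule,
and a microtubule inside a bundle is unaffected by its bundle partners.
Katanin severing, microtubule flexibility and edge-induced catastrophes are
outside the scope of this package.

## Geometries

Three surfaces are supported, all built from flat faces with isometric
transition maps (`domain_spec()`):

* a periodic rectangle (L x H);
* a capped cylinder: one periodic rectangular mantle of width `2*pi*R` plus
  two disk caps. A trajectory crossing the cap rim continues along the
  geodesic obtained by unrolling the cap tangent to the mantle at the
  crossing azimuth;
* a box with six faces and explicit edge unfolding.

Within a face trajectories are straight; crossing a seam or edge applies
the unfolding isometry, so direction is continuous in the unfolded plane
and edges carry no event or penalty. A trajectory hitting a box corner or a
face corner exactly is perturbed by 1e-9 um along the edge — corners are
measure-zero and this tie-break only fixes determinism. The face u-axis is
aligned with the domain's long axis wherever that axis has a projection, so
the face-local angle theta = 0 is longitudinal and theta = +/- 90 degrees is
transverse; on caps and box end faces the reference is fixed but arbitrary,
and whole-array orientation on such shapes is always judged with the 3D
metrics.

## Nucleation modes

New microtubules appear through one of three mechanisms
(`nucleation_params()`):

* **ISO** — isotropic: rate `r_n` per unit area, uniform position and
  orientation.
* **GDD** — global density-dependent microtubule-based nucleation: of the
  total rate `r_n`, a fraction `rho/(rho + rho_half)` (global density rho,
  `rho_half` = 0.1 um^-1) is bound nucleation placed uniformly along the
  existing lattice, the remainder is unbound. Because every unit of lattice
  length competes globally, dense regions attract ever more nucleation —
  the *inhomogeneity problem*: runaway positive feedback that drains the
  array into a few superbundles.
* **LDD** — local density-dependent nucleation, the algorithm at the heart
  of this package. Nucleation complexes appear on the membrane at rate
  `r_ins` (0.0045 per um^2 per s) at uniform positions. Instead of
  simulating complex diffusion explicitly, each appearance is resolved
  instantaneously through `N_meta` = 6 *meta-trajectories*: radii of length
  at most `R_max` = 1.5 um cast from the appearance point (first direction
  uniform, the rest spaced 60 degrees), each stopping at the first lattice
  intersection, at distance `d_i`. The probability that a diffusing complex
  would have reached that intersection before nucleating unbound is
  `p(d_i) = exp(-r_u d_i^2 / (4 D_nc))` with `r_u` = 0.002 1/s and `D_nc` =
  0.013 um^2/s (the expected time for a mean squared displacement of `d_i`
  is `d_i^2/(4 D_nc)`). A tentative bound nucleation on trajectory `i`
  occurs with probability `p(d_i)/N`, a tentative unbound nucleation with
  probability `1 - sum_j p(d_j)/N`. Tentative events are then accepted with
  probability `alpha_bound` = 0.24 (bound) or `alpha_unbound` = 0.02
  (unbound), reflecting the observed dissociation probabilities of
  lattice-bound versus free complexes; otherwise the complex dissociates.
  Meta-trajectories cross seams and edges by the same unfolding as
  microtubule paths, which keeps the algorithm consistent on cylinders and
  boxes.

Because the local density saturates the bound probability (all `p(d_i)`
approach 1 as soon as lattice is nearby), LDD self-limits: the nucleation
rate on an empty membrane is `alpha_unbound * r_ins` = 9e-5 and on a dense
array `alpha_bound * r_ins` = 0.00108 per um^2 per s, and homogeneous
arrays stay homogeneous.

The default parametrization is the statistically equivalent *rescaled* one
(`rescaled = TRUE`): appearance rate `alpha_bound * r_ins`, all tentative
bound nucleations accepted, unbound ones accepted with
`alpha_unbound/alpha_bound` = 0.08333. It produces the same nucleation
process at roughly a quarter of the appearance events.

Bound daughters nucleate from the parent lattice point with a relative
angle drawn from a mixture: exactly parallel with probability `f_forward` =
0.31, antiparallel with `f_backward` = 0.07, and sideways (left/right 0.31
each) from the angular density of an ellipse with eccentricity 0.89 whose
main axis makes the branching angle `theta_b` = 35 degrees with the parent.
The sideways density is sampled by a numerically inverted CDF tabulated at
0.1 degree resolution, built once per parameter set.

Design choices where the procedure is underdetermined:

* unbound LDD nucleations are placed at the complex appearance point with
  uniform orientation — the appearance point is the only distinguished
  location available;
* when a bound nucleation occurs, the hosting trajectory is chosen with
  probability proportional to `p(d_i)` among intersecting trajectories, so
  the marginal bound probability matches the sum formula above;
* complexes are memoryless and instantaneous: no complex state persists
  between events. This is what makes LDD nucleation O(1) per appearance.

Variant experiments are plain parameters: `alpha_unbound := alpha_bound`
("equal rates"), and `unbound_factor` < 1 scales only the unbound share of
GDD.

## Observables

* `s2_theta2()` — planar nematic order parameter
  `S2 = sqrt(<<cos 2 theta>>^2 + <<sin 2 theta>>^2)` (length-weighted) with
  the associated orientation `Theta2`; on cylinders it is evaluated on the
  unrolled mantle only.
* `orientation3d_r2()` — surface-corrected order for 3D shapes. The
  standard planar order parameter cannot be extended naively to closed
  surfaces: confinement alone makes an isotropic array look ordered. We
  therefore compare the length-weighted second-moment tensor `M` of the
  embedded unit tangents against the analytic isotropic tensor `M_iso` of
  the same domain (area-weighted tangent-plane isotropy per face; helical
  mantle segments are subdivided before embedding). The *most avoided
  direction* `n` minimizes the generalized Rayleigh quotient
  `n' M n / n' M_iso n`, and `R2 = 1 - min quotient`, clipped to [0, 1].
  This definition has the required anchors: a perfectly transverse array on
  a cylinder gives `R2 = 1` with `n` along the axis, an isotropic array
  gives `R2 = 0` in expectation, and directions with no isotropic support
  (the normal of a planar patch) are excluded. The exact published form of
  the surface-corrected order parameter differs in details we cannot
  reproduce here (for instance it implies a longitudinal ceiling below 1 on
  cylinders, `(1 + D/L)/2`, whereas this definition reaches 1); all
  comparisons in this package use the definition above consistently, and
  `r2_max()` computes the matching perfect-array ceilings used by the
  renormalized `R2`. Degenerate minimizers are broken deterministically
  (largest component on the lowest-index axis) and flagged.
* `classify_orientation()` — transverse below 10 degrees from the long
  axis, longitudinal above 80 degrees, otherwise other. Renormalized `R2`
  is reported only for transverse/longitudinal arrays.
* `density_profile()` — lattice length per 1 um axial bin divided by bin
  area (mantle only on cylinders); conservative by construction.
* `control_G()` — the dimensionless control parameter
  `G = (2 (v+-vtm)^2 (v-+vtm) / (r_n v+ (v+ + v-)))^(1/3) *
  (r_r/(v-+vtm) - r_c/(v+-vtm))`, the (negative) ratio of the interaction
  length scale to the intrinsic microtubule length, adjusted for minus-end
  treadmilling. Spontaneous alignment occurs above a threshold value of G.
  For LDD, where the nucleation rate is an outcome rather than a parameter,
  `effective_rn()` (nucleation count / time / area) is used in G; the count
  is measured over the whole run because it grows linearly in time after a
  short transient. G is always obtained by direct evaluation of this
  formula; approximate rules of thumb relating bias strengths to G are not
  used anywhere.
* `octant_project()` / `c2_coordinate()` — projection of the most-avoided
  direction into the positive octant for orientation-distribution plots
  (transverse arrays plot at the top, the body diagonal at the centre).

## The event-driven core

The engine (`run_simulation()`) exploits one structural fact: segment
geometry never moves. A microtubule is a static polyline plus two moving
arclength offsets (plus end, treadmilling minus end), so the covered part
of a segment is an interval that changes linearly in time between events.
A crossing of two trajectories is a fixed spatial point, and collision
timing reduces to comparing the tip's arrival time with the interval of
lattice coverage at that point.

Scheduling is lazy and conservative:

* each growing tip keeps a scanned future path (across seams, up to a
  lookahead horizon of 1.5 domain lengths) and one pending collision
  candidate, predicted with current kinematic rates;
* every event re-validates its preconditions when popped; a stale event
  triggers a fresh scan from the current tip position, so a wrong
  prediction can cost a rescan but never a wrong collision;
* events that create or restore lattice coverage (nucleation, zippering,
  seam crossing, rescue re-extension) are swept against all stored tip
  paths and may preempt scheduled collisions;
* stochastic switching uses exponential waiting times, resampled whenever
  the effective rate changes (seam crossing under the cap bias, direction
  changes under the rescue bias) — statistically exact by memorylessness.

Deterministic tie-breaks: a collision angle exactly at `theta_c` zippers;
simultaneous hits on overlapping collinear bundle members resolve once,
against the lowest microtubule id; heap ties order by (time, event class,
microtubule id). Identical seeds reproduce runs bit-exactly, and
observation frequency does not perturb the event sequence.

Two directional biases are built in for cylinder experiments: a *global*
bias multiplying `r_c` on the caps (`cap_rc_factor`, e.g. 1.08 for an 8%
increase) and a *local* bias raising the rescue rate by
`(b_max/2) (1 + cos(2 (theta - theta_r)))`, maximal for tips growing along
`theta_r`.

A configurable density cap (default 200 um^-1) aborts runs that leave the
bounded regime, with an explicit status. Runs start from an empty array
unless `initial_mts` provides a deterministic initial condition (used
heavily by the tests and oracles).

## Validation strategy and what it shows

Two independent reference implementations live in the package:

* `brute_force_collisions()` — exhaustive path/segment intersection for a
  static snapshot;
* `small_dt_reference()` — a fixed-step integrator (dt at most 0.01 s) with
  per-step collision sweeps and Bernoulli switching, sharing only the
  geometry code with the event engine. On deterministic toy configurations
  (no stochastic switching, `P_cat` 0 or 1) the two engines must produce
  identical collision sequences to within the step size; the test suite
  checks 100 seeded configurations. Near-seam floating-point stalls in the
  stepper are avoided by tracking positions with explicit seam jumps.

The toy-array generators (`toy_transverse_ring()`,
`toy_longitudinal_lines()`, `toy_uniform_isotropic()`, `toy_single_band()`)
pin the order-parameter anchors exactly and emit the same snapshot format
the simulator writes, so every observable is testable without external
data.

Statistical checks are pre-registered in the test code with fixed seeds and
thresholds (KS/chi-squared p > 0.01, 3-standard-error windows): the
daughter-angle sampler against its analytic density, exponential waiting
times and sparse-limit length distribution, LDD empty-domain and
dense-limit rates, and equivalence of the rescaled and unrescaled LDD
parametrizations.

What desk-scale runs do *not* show: the reference ensemble behaviours
(orientation fractions over thousands of replicates at 3e4 s horizons) are
reproduced only as trends at reduced problem sizes, chosen once as package
defaults — alignment-curve comparisons use a 20 x 20 um^2 periodic domain
with three replicates per G value and 5000 s horizons; homogeneity
comparisons a 32 x 32 um^2 domain at 4000 s; the LDD nucleation-rate and
bound-fraction diagnostics a single 40 x 40 um^2 run of 4000-5000 s with
the cumulative count fitted after a 1500 s transient. The GDD band on a
cylinder is followed to ~4500 s, far short of its >120 um^-1 saturation;
the test asserts monotone growth of the maximal axial-bin density instead.
None of the simulations include katanin severing, microtubule flexibility,
wall-stress coupling or edge catastrophes, so agreement here validates the
algorithms, not the full biology of any particular cell type.

The local density attached to LDD nucleation events (for the
bound-fraction diagnostic) is measured over the grid cells (1 um side)
touched by the event's meta-trajectories: lattice length clipped to those
cells divided by their area. This ties the measurement to exactly the
neighbourhood the algorithm itself explored.

## Worked example

```{r example}
library(cortarray)

dom <- domain_spec("periodic_rectangle", L = 40, H = 40)
cfg <- sim_config(dom,
                  dynamic_params(r_c = 0.0025),
                  nucleation_params("LDD"),
                  T_end = 4000, obs_interval = 50, seed = 7)
sim <- run_simulation(cfg)

ts <- sim$time_series
coef(lm(n_c ~ time, data = ts[ts$time >= 1500, ]))[2]  # nucleations per second
order_metrics(array_snapshot(sim), dom)$S2
```

Preset experiment drivers (`run_preset()`) bundle the study designs —
homogeneity profiles, alignment curves, cylinder orientation fractions with
biases, equal-area geometry sweeps and nucleation diagnostics — at
desk-scale replicate counts, and `write_bundle()` / `read_bundle()` store
results as CSV + JSON with the full configuration echoed for bit-exact
reproduction.

## Known limitations

* The surface-corrected order parameter is this package's own definition
  (anchored as described above), not a verbatim reimplementation of any
  published variant; renormalized values should only be compared within
  this package.
* Bundles are implicit (collinear co-located segments); there is no lateral
  offset bookkeeping, and a tip's own parent bundle is excluded from its
  collision targets while collinear to avoid zero-distance re-collisions.
* The fixed-step reference engine supports periodic rectangles only and is
  a test oracle, not a production path.
* Nucleation complexes never accumulate on the lattice and their appearance
  is unbiased by existing microtubules; the measured bound fraction at high
  local density is therefore expected to fall slightly below estimates that
  include microtubule-biased appearance.
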