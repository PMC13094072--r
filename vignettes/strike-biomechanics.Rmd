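---
title: "Methods: strike kinematics, power amplification and spring-model analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strike kinematics, power amplification and spring-model analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mantisstrike)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the parameters that matter, what
the synthetic-data generators do and do not emulate, and the numerical and
design choices that were genuinely open.

## The biomechanical question

An impaling predatory strike opens the coxa–trochanter (CT) joint through
tens of degrees in about 1.6 ms, accelerating the tibial tip to roughly
5 m/s. Whether muscle alone can do this is a power question: muscle tissue
delivers at most ~100–500 W per kg of muscle. If the mechanical power of
the strike, divided by the mass of the driving muscle, clearly exceeds that
band under *every* reasonable accounting, the system must store energy
elastically and release it through a latch — latch-mediated spring
actuation (LaMSA). The package's job is to compute that mass-specific
power output (mpo) from tracked video and force recordings, reproducibly
and with known error behavior.

## Kinematics

**Angles.** The CT angle is the interior angle at the CT joint between the
rays to the coxal base and to the femur–tibia (FT) joint; the FT angle is
defined analogously at the FT joint. Both use the dot-product/arc-cosine
construction, which returns values in [0°, 180°] and is invariant under
translation, rotation, reflection (so the image-style y-down convention of
tracker exports is irrelevant) and uniform scaling. Coincident landmarks
make the angle undefined; such frames abort with a frame-indexed error
rather than being interpolated, because silent repair would corrupt the
velocity estimates downstream.

**Standardized angles.** Angles are referenced to frame 0. The stored
convention is opening-positive, `θ(t) − θ(0)`, because every downstream
quantity (angular velocity during opening, power) needs opening to have a
consistent positive sign; the mirrored `θ(0) − θ(t)` reading remains
available as `convention = "literal"`, and the choice is recorded in the
series.

**Differentiation.** The default is a Savitzky–Golay filter of polynomial
order 2 and window 5 frames, appropriate at the 12,000–20,000 fps frame
rates the package targets: at those rates a 5-frame window spans well under
half a millisecond, short against a 1.6 ms sweep, so the quadratic fit
tracks the ramp while averaging landmark jitter. Central differences are
available as the no-smoothing alternative. Both reproduce the slope of a
strictly linear ramp exactly (interior frames), which is what makes
noise-free parameter recovery exact rather than approximate. Endpoints use
the filter's one-sided rows (SG) or one-sided differences.

**Tip speed** is the central-difference speed of the tarsus-base landmark
(the most distal tracked point, used as the tibial tip), converted from
pixels to meters exactly once via the mm/pixel scale. On a discrete grid a
rotating point's observed speed is the chord speed `r·sin(ω·Δt)/Δt`, not
`ω·r`; at 12,000 fps and ω = 450 rad/s the two differ by ~0.02%, and the
generators' ground truth uses the chord value so that recovery tests are
exact.

**Segmentation.** The verbal definition — the strike starts when the CT
joint begins to open after being completely closed, and ends when the spur
stops penetrating — is operationalized as:

1. *Plateau*: the longest run (≥ `min_plateau` = 5 frames) of CT angles
   within `closed_tolerance` = 1° of the running minimum.
2. *Start*: the first frame in that run whose frame-to-frame rise exceeds
   an adaptive threshold for 2 consecutive frames. The threshold is
   3 × a MAD-based estimate of the frame-to-frame noise up to the plateau
   end, floored at 10⁻⁹ deg, so noise-free ramps are caught on their very
   first rising frame while noisy plateaus do not fire early; consecutive
   rises are negatively correlated under i.i.d. landmark noise, which makes
   a double false trigger rare.
3. *End*: the first frame after the peak tip speed at which tip speed
   falls below `end_speed_frac` = 5% of that peak — penetration depth is
   not tracked, so "stops penetrating" becomes "the tip essentially
   stops". If the speed never falls below threshold the last frame is used.

All thresholds are user-configurable; frame indices are 0-based,
matching the tracker-file frame column.

## Force processing

Traces arrive in mN against seconds. Baseline correction subtracts the
median over a pre-strike window (idempotent by construction). The strike
window is the contiguous region around the peak where force stays at or
above 5% of the peak; the peak (first sample on ties, with a message) and
the window median are the two per-strike summaries, optionally normalized
by body mass. Group comparisons across animals, days and prey-size classes
use the Kruskal–Wallis rank test at α = 0.05 — a deliberately conservative,
distribution-free choice for n of a few strikes per cell; fully tied data
are reported as p = 1 (no evidence of an effect) rather than NaN.

## Power output and the LaMSA verdict

Two mpo formulations are implemented behind one interface, because a single
construction can always be argued with:

* **Approach 1 (instantaneous)**: `mpo = F_peak · v_tip_peak / m_muscle`.
  This is the peak force–velocity product — an upper-bound-flavored
  estimate that needs no inertia model.
* **Approach 2 (energetic)**: the rotational kinetic energy at peak
  angular velocity, `E = ½ I ω_peak²`, delivered over the sweep:
  `mpo = E / (T_sweep · m_muscle)`. The leg inertia I composes rods
  (`m L²/3` about the proximal end) and point masses (`m r²`) about the CT
  joint; the pipeline default is a single 1 mg point mass at the lever arm,
  measured per strike as the CT-joint-to-tarsus distance at the strike
  start.

The two approaches measure different things and are *not* expected to
agree (an order-of-magnitude spread between them is normal); no ordering
between them is asserted anywhere. What is asserted is their scaling
structure: both are homogeneous of degree −1 in muscle mass, approach 1 is
linear in F and v, approach 2 quadratic in ω and in the lever arm, and for
pure rotation `F·v` equals `(F·r)·ω` exactly (`torque_power_consistency()`
is the built-in cross-check). The verdict is conservative: `amplified`
only when *both* approaches exceed the 500 W/kg upper limit of direct
muscle performance, `within_muscle_limits` when neither does,
`indeterminate` otherwise. Muscle mass is never defaulted: it must come
from a measured value or an explicit fraction of body mass.

## Double-spiral spring geometry

The physical model's elastic element is built from Archimedean spirals
`r(θ) = r0 + kθ`. Arm one uses the two specified spirals (defaults
θ ∈ [0, 2π], k = 2, r0 = 11 and 14.5 model units); the second arm derives
spirals 3 and 4 by point reflection through the origin — the derivation of
the second arm is not uniquely determined by "derived from spirals 1 and
2", so the rule is declared, recorded in the geometry metadata, and
isolated so an alternative rule can be swapped in. Arc length uses the
closed form `∫√(r² + k²) dθ = [a/2·√(a²+k²) + k²/2·asinh(a/k)]/k` at
`a = r(θ)`, degenerating exactly to `r0·Δθ` at k = 0; the test suite pins
it against adaptive quadrature. Units are dimensionless design units
(the physical model's printed parameters carry none); exports tag them.
Shrinking θmax shortens the coil — the design handle for spring
deformability — but no stiffness model is attempted: there is no material
model to support one, and the mechanical consequence of the spring is
handled qualitatively by the generators' saturation logic instead.

## Mixed-effects analysis of model trials

Each physical trial yields a maximum tensile force (the largest force
before the release drop, detected as the first sample falling more than
50% from the running maximum) and a maximum post-release speed (largest
frame-to-frame speed of the tracked point after the release instant mapped
onto the video time base). The study models are

```
log(force) ~ type × friction + (1 | sample)
velocity   ~ type × friction + (1 | sample)
```

with force log-transformed (its residuals are heteroscedastic on the raw
scale — release forces span two orders of magnitude between friction
scenarios), natural log by convention. Fixed effects are tested with type
III ANOVA, which requires sum-to-zero factor coding to be well defined
under interactions and is then invariant to factor-level order.
Degrees of freedom use the Satterthwaite approximation. Friction effects
within each trochanter type are quantified by estimated marginal means and
unadjusted pairwise contrasts (the within-type high-vs-low comparison is a
planned, two-contrast family; the method name travels with the output so a
correction can be applied downstream if desired). Constant-response data
degenerate gracefully (zero effects, no significance), and a missing
type × friction cell is an explicit rank-deficiency error naming the cell.

One unit note: trial speeds are treated as m/s throughout. Source
descriptions of such trials sometimes print velocity means with
acceleration-style units (m s⁻²); the package treats these as speeds, and
flags the discrepancy here rather than propagating it.

## Synthetic data: what it emulates, what it does not

The generators define the study conditions the tests run under:

* **Strike tracks** (`generate_strike_track()`): planar forward kinematics
  of a three-segment leg observed at 12,000 fps as five landmarks with
  i.i.d. Gaussian pixel noise, y-down coordinates. The CT program defaults
  to a 15° closed plateau followed by a ~1.6 ms opening at 450 rad/s, with
  segment lengths giving a ~11 mm joint-to-tip distance — hence a ~4.9 m/s
  tip speed, the magnitudes of the study system. Opening ramps are
  constant-rate (linear) so the discrete ground truth — start/end frame,
  peak ω, chord tip speed — is exactly recoverable; a smooth ramp would
  make 10⁻⁶-level recovery impossible by discretization alone. One
  geometric constraint follows from planarity: an interior joint angle
  lives below 180°, so high peak ω and long sweep durations cannot be
  combined freely; sweeps are parameterized within that envelope.
* **Force traces** (`generate_force_trace()`): baseline + linear drift +
  an asymmetric pulse (linear rise, exponential decay — a shape chosen for
  its well-defined analytic peak, defaulting to 17.62 mN) + Gaussian noise.
* **Model studies** (`model_study_design()` + `generate_model_study()`):
  a 2-type × 2-friction factorial with 4 samples per type and 8 repeats,
  Gaussian per-sample intercepts on log force and speed (matching the LME
  the analysis fits), a 10 mm/s tensile ramp, and spring saturation:
  release force above the saturation force does not raise the post-release
  speed. Default cell means are at the magnitudes observed for such
  physical models (tens of newtons under high friction versus fractions of
  a newton under low friction; ~0.2 m/s for the flexible trochanter under
  high friction).

Real recordings differ in ways the generators deliberately do not model:
tracking-algorithm failure modes (dropouts, drift, correlated errors),
out-of-plane motion, transducer ringing, and day effects. Landmark and
transducer noise magnitudes are free parameters, not estimates of any
particular rig. Passing the recovery tests therefore demonstrates that the
analysis chain is correct and well conditioned under its stated model —
not that any particular laboratory's noise floor is met.

## Numerical choices and degenerate inputs

* Validation failures raise classed conditions
  (`mantisstrike_validation_error`, `_format_error`, `_configuration_error`,
  `_segmentation_error`, `_degenerate_geometry_error`) so callers can
  distinguish bad parameters from bad files from bad geometry.
* Writers print doubles with 17 significant digits; every writer→reader
  round trip (tracker, force, spiral CSV, results tables) is bit exact.
* Ties in peak detection always resolve to the first occurrence, keeping
  outputs deterministic; force-peak ties are additionally messaged.
* Seeds are explicit scenario fields; generators restore the caller's RNG
  state (`withr::with_seed`), so no global state leaks.
* `arccos` is evaluated on a clamped argument to absorb rounding outside
  [−1, 1]; its conditioning degrades only toward 0°/180°, where tracks are
  rejected as degenerate anyway.

## Problem sizes used by the checks

The shipped verification runs use 1,000 random frames for the angle
oracle, 50 noise-free strikes spanning ω ∈ [50, 1000] rad/s and sweeps of
1–10 ms, 200 noisy strikes for segmentation reliability, 10⁵-point
polylines for arc-length convergence, and 200 replicate model studies
(128 trials each) per mixed-model scenario — sizes at which the binomial
uncertainty on a 90–95% detection rate is a few percent, chosen so the
checks are informative while a full run stays comfortably interactive.

## Known limitations

* Kinematics are strictly 2-D; out-of-plane motion biases angles and
  speeds in ways the package cannot detect.
* The mpo formulations are declared stand-ins for whatever accounting a
  particular study used; they are the two standard constructions, but
  absolute mpo values depend on the muscle mass and inertia model
  supplied, so cross-study comparisons should compare formulations, not
  just numbers.
* The energetic approach's default leg model (single point mass at the
  lever arm) is intentionally minimal; supply measured segment masses via
  `muscle_model()` for anything quantitative.
* No spring stiffness or energy-capacity model for the double spiral;
  saturation is a qualitative generator-level behavior.
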