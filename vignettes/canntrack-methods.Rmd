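---
title: "Tracking with a continuous attractor network: model, quantization, and many-core mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking with a continuous attractor network: model, quantization, and many-core mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canntrack)
```

## The model

A two-dimensional continuous attractor neural network (CANN) is a sheet of
rate neurons on an H x W toroidal grid. Neuron `x` has membrane potential
`V(x, t) >= 0` and firing rate `r(x, t)`. Two interactions shape the
dynamics:

* **Local Gaussian excitation.** The synaptic weight from `x'` to `x` is
  `J(x, x') = J0/(2*pi*a^2) * exp(-|x - x'|^2 / (2*a^2))`, with `|x - x'|`
  the minimum-image Euclidean distance on the torus. A *connection field*
  (CF) restriction prunes all synapses outside the R x R square centred on
  each neuron, which is what makes the network mappable onto cores with
  bounded fan-in; the rectangle (rather than a disc) matches the
  column-slicing scheme below.
* **Divisive global inhibition.** Rates are squared potentials normalized
  by the population: `r(x) = V(x)^2 / (k * sum(V^2))`. For any non-zero
  state `sum(r) = 1/k` exactly, and the stable configuration of the free
  network is a single localized *bump* of activity.

The discretized update (unit time constant, unit step) iterates

```
V(x, t+1) = max(0, beta * sum_{x' in CF(x)} J(x, x') r(x', t) + V_ext(x, t))
r(x, t+1) = V(x, t+1)^2 / (k * sum V(,t+1)^2)
```

The `1 +` in the continuous model's denominator is dropped in the discrete
network; the all-zero state is therefore defined to have `r = 0` (and the
hardware inhibition table maps index 0 to 0 for the same reason).

The external stimulus is the *signed difference of consecutive video
frames*, resized to the grid. A moving bright object produces a
leading-edge/trailing-edge dipole that pulls the bump along; with no
stimulus the bump persists by recurrent excitation alone. The tracker
output is simply the location of the maximum rate, mapped back to native
pixel coordinates, with the first frame's ground-truth box providing the
(fixed) box size. Signed differences are retained — the ReLU in the
potential update is what clips net-negative drive; taking absolute values
would make it vacuous.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `grid` H x W | 96 x 128 (30 x 56 in the mapping study) | neurons | network resolution |
| `R` | 15 | neurons | CF side; accuracy saturates for large R, so the smallest saturating value is used |
| `a` | 2 | neurons | Gaussian interaction range; sets the bump width |
| `J0` | 1 | – | interaction strength; only `beta*J0/k` matters for the bump shape |
| `beta / k` | 50 / 0.5 = 100 | – | the ratio governs the dynamics; substituting `r` into the update shows `V` depends on `beta, k` only through `beta/k`, so the individual values are free |
| `n_iter` | 15 | iterations | settles the bump on each difference frame |
| `stimulus.gain` | 0.02 | per gray level | scales 0–255 frame differences to the potential scale; the model's dynamics make tracking insensitive to this over a wide range |

`J0`, `a` and the gain are not dictated by the tracking problem; they were
fixed once, jointly with the quantizer, by the closed-loop procedure that
hardware deployment requires anyway (run the float model, calibrate,
quantize, verify tracking) and are not tuned per sequence. `tau` is fixed
at 1 by the discretization and deliberately not exposed.

Initialization from the first ground-truth box is under-determined by the
problem statement; this package seeds `V` with the interaction-stencil
profile centred on the box centre with peak `beta/k * J0/(2*pi*a^2)`, an
amplitude at the scale of the free fixed point, which relaxes to the
attractor bump within a few iterations.

## The synthetic scene generator

Real benchmark videos cannot ship with the package, so a deterministic
generator (`generate_synthetic_video()`) stands in: a bright square or
Gaussian blob on a darker background, moving on a linear, sinusoidal or
random-walk trajectory (reflected at the borders), with additive Gaussian
pixel noise and optional occlusion episodes. Ground-truth boxes are exact
by construction. The canonical benchmark used in the tests is three 70
frame sequences (one per trajectory type) at 120 x 224 native resolution,
object size 16 px, noise sigma 4, seeds 1–3, tracked on the 30 x 56 grid.

What this emulates well: object-scale motion energy in difference frames,
boundary interactions, measurement noise. What it does not: photometric
variation, deformation, background clutter with object-like contrast,
scale changes. Passing tests therefore demonstrate the mechanics of the
tracker and the exactness of the hardware pipeline — not accuracy claims
on natural video.

## Fixed-point quantization

The hardware datapath is 8-bit I/O with 24-bit accumulation; accumulators
are truncated to a 10-bit table index before the soma lookup. Quantization
is by *scaling and rounding*: every signal `x` carries a scale `rho_x`, and
integer values are `round(rho_x * x)` clipped to the I/O range. Through a
product stage `rho_z = rho_x * rho_y / rho_F`; through a sum stage (equal
input scales required) `rho_z = rho / rho_F`, where `rho_F` is the combined
effect of the truncation shift and the lookup table.

Because the firing rate feeds back into the next iteration against static
weights, the composed scale around the five-step loop must equal 1 — the
*constant-scaling restriction*. `solve_feedback_scaling()` enforces it by
construction: the step-5 table scales its output to exactly the target
`rho_r`, and `chain_loop_scale()` verifies the closure through the chain
rule. Design choices:

* Rounding is half-away-from-zero; truncation is a pure arithmetic right
  shift (floor). One rule each, fixed for reproducibility.
* Shifts are powers of two; each stage's residual (non-power) scale factor
  is folded into its LUT contents. `beta` is folded into the stored
  weights, `k` into the inhibition table; neither exists as an integer.
* Signal scales are fitted to the ranges observed on a floating-point
  calibration run of the target sequence (`calibrate_ranges()`), with a
  1.5x head-room factor on accumulator ranges. Out-of-range values
  saturate; saturation is counted and reported, never raised.
* The inhibition division `1/(k*S)` is a 1024-entry table over the
  (non-negative, hence unsigned) truncated sum index; entry 0 is 0.

The divisive normalization makes the loop degree-0 homogeneous in `V`, so a
*static* scale error does not compound from that alone; what a broken chain
does is push the squared-potential sum outside its calibrated index range,
where the saturating table can no longer compensate — the integer/float
ratio then grows geometrically until the datapath rails. The negative
control in the tests triggers exactly this. With a correctly closed chain
the ratio fluctuates (rounding noise at the 10-bit index) but shows no
drift, and the quantized tracker's bump location agrees with the float
tracker on well over 90% of benchmark frames.

## Mapping onto constrained cores

A functional core has 256 fan-ins and fan-outs (a 256 x 256 8-bit synapse
array), dendrite operations VMM / VVM / VVA / VS / VB, and a soma with an
optional lateral accumulate, the truncation, a LUT, and packet emission.
One iteration is decomposed into five steps (recurrent input; potential +
stimulus with ReLU; squaring; inhibition factor + delayed square; rate),
each one phase of a compute-then-communicate schedule.

The step-1 multiply exceeds a single core, so the planner slices the grid:

* **Column slices** of width `w = min(floor(fan_in/H), (R-1)/2)`, snapped
  down to a divisor of W (no slicing when the whole grid fits the fan-in).
  The `(R-1)/2` cap aligns the affected span `w + R - 1` with a whole
  number of slices. For 30 x 56 with R = 15 this yields 8 slices of 30 x 7.
* **Row slices**: the affected span of a slice holds more outputs than the
  fan-out, so outputs split into the smallest divisor-of-H count of equal
  bands that fit — three 10 x 21 bands here, giving 24 step-1 cores of
  210 fan-ins/fan-outs, the three cores of a slice sharing inputs over an
  adjacent-multicast (AMC) relay chain.
* Vector steps split the 1680 neurons into `ceil(N/fan_out)` equal blocks
  (7 x 240), with two copies at steps 2 and 3 (the squaring consumes two
  operands; the square feeds both the inhibition sum and the delay), one
  inhibition core per rate core (7 copies at full-grid fan-in), 7 delay
  cores and 7 rate cores — 73 cores in total.

Multi-operand vector inputs (e.g. 4 x 240 at step 2) are held in the
dynamic synapse banks (two ping-pong chunks of 128 x 256), not the 256-entry
axon buffer, so the per-vector length and the 128-vector count are the
binding limits for element-wise cores. Grids taller than the fan-in would
need a row-wise input split that the scheme does not define; the planner
rejects them. Non-divisible widths would be padded with zero-weight
columns; the planner currently snaps to divisors instead, which covers
every grid whose width has a divisor below the cap.

The behavioral simulator executes the placement with explicit packets,
AMC relays, per-phase barriers, single-writer checks per (core, slot,
position), and accumulator-width checks. Its contract — asserted over
every placement the tests construct — is integer-for-integer equality with
the direct quantized pipeline, which in turn requires the pipeline to
truncate step-1 partials per column slice exactly as the cores do
(`solve_feedback_scaling(groups = ...)`). Timing is phase-accurate only
(five phases per iteration); clock rates, latencies and power are hardware
properties outside software scope.

## Evaluation

Standard tracking metrics over paired predicted/ground-truth boxes: centre
error (Euclidean, pixels), overlap (continuous-area intersection over
union; zero-area boxes score 0 and are flagged), the precision curve over
distance thresholds 0–50 px, the success curve over overlap thresholds
0–1 in steps of 0.05, and the AUC computed as the mean overlap (identical
to the success-curve area up to discretization, asserted in the tests).
Protocols: OPE (single run from the first-frame ground truth), TRE (20
evenly spaced segment starts, re-initialized from ground truth, averaged)
and SRE (12 first-frame perturbations: 8 shifts of 10% of the box size, 4
centre-preserving scalings x0.8/0.9/1.1/1.2, averaged). The 20/12 counts
follow the established benchmark protocol; box centres are
`(x + w/2, y + h/2)`.

## Numerical conventions and degenerate inputs

* Argmax ties break row-major (smallest row, then column); an all-zero
  rate field returns the previous location (or the grid centre, flagged).
* All internal coordinates are 0-based row/column; the OTB box files'
  1-based origins are converted on load and restored on write.
* Resizing is separable triangle-kernel resampling, widened by the scale
  ratio when shrinking (antialiased; constant images are exactly
  preserved, and 2 x 2 -> 1 x 1 averages).
* Grayscale conversion uses ITU-R 601 luma weights.
* Stimuli are held constant across the iterations of one difference frame.

## Problem sizes used in validation

The test suite exercises: brute-force pair-sum oracle equivalence on tori
up to 12 x 12; bit-exact chip-vs-pipeline equality on 16 x 16, 20 x 28 and
30 x 56 placements (the latter over 20 frames x 15 iterations); the
scaling-ratio trace over 210 driven and 200 free iterations; and the
three-sequence benchmark battery (207 tracked frames) for the
float-vs-quantized bump-location agreement. These sizes keep the full
suite in the minutes range while covering every slicing regime (single
core, aligned span, non-uniform overlap).

## Known limitations

* Fixed-scale, single-object tracking: box width and height are copied
  from the initialization; no scale or rotation estimation.
* Difference-frame drive is edge-sensitive: a perfectly static object is
  invisible (the bump then simply persists, which is the desired
  behavior) and low-contrast objects against similar backgrounds degrade.
* The planner implements the published slicing scheme; its extrapolation
  to grids far beyond the worked example is validated only for
  feasibility and monotone cost, not against external core counts.
* Weights are analytic (no plasticity), and the continuous-time ODE is
  represented only by its unit-step discretization.
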