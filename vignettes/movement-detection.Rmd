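---
title: "Detecting steps and falls from window extrema: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting steps and falls from window extrema: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepfall)
```

## The model

stepfall detects *atomic movements* -- a single step, a single fall impact --
in a uniformly sampled tri-axial accelerometer stream. The core idea is that
one short movement can be summarised by the amplitudes and times of the
maximum and minimum of the signal inside an analysis window of length
$\delta_{max}$ (the longest duration of the movement), and that these
extrema features carry enough information for Bayesian classification while
remaining cheap to compute on-sensor.

For step detection, each window yields two features from the gravity-aligned
components:

* $f_1 = \max(G_z) - \min(G_z)$, the vertical amplitude range (g);
* $f_2 = t[\max(G_y)] - t[\min(G_y)]$, the signed time between the
  longitudinal extrema (s).

Walking cadence $\mu_i$ is sampled at 60, 80 and 100 steps/min. Each cadence
class models each feature as a Gaussian $N(\lambda_{ki}, \sigma_{ki})$
(fitted by sample mean / SD), features taken independent, so

$$p(\mu_i \mid f_1, f_2) =
  \frac{p(f_1 \mid \mu_i)\, p(f_2 \mid \mu_i)\, p(\mu_i)}
       {\sum_j p(f_1 \mid \mu_j)\, p(f_2 \mid \mu_j)\, p(\mu_j)},
\qquad
p(\mathrm{step} \mid f_1, f_2) = \sum_{i > 0} p(\mu_i \mid f_1, f_2).$$

The null class $\mu_0$ ("no step in this window") gets an explicit density
with two outward exponential tails,

$$p(f \mid \mu_0) \propto \tfrac12\left[
  \lambda_{01} e^{-\lambda_{01}(f - \mu_{01})} \;[f \ge \mu_{01}]
  + \lambda_{02} e^{-\lambda_{02}(\mu_{02} - f)} \;[f \le \mu_{02}]
  \right],$$

clamped to a plateau at the larger tail boundary between the anchors. As
written, the two half-tails integrate to 1 on their own and the plateau adds
further mass, so the implementation divides by the closed-form total
$Z = 1 + (\mu_{01}-\mu_{02})\max(\lambda_{01},\lambda_{02})/2$; a quadrature
test confirms unit mass. The published source gives the tail *form* but no
estimator; `fit_null()` uses the sample quartiles as anchors and
method-of-moments on the mean excess beyond each quartile for the rates --
the simplest estimator consistent with the form, recovering known rates
within 10 % at $n = 10^4$ in the tests.

Fall detection uses the acceleration magnitude $|G|$: $f_1$ is its window
range (the impact spike above the free-fall dip, in g) and $f_2$ the
absolute min-to-max elapsed time in milliseconds. The decision is a
thresholded product of *peak-normalised* Gaussian kernels
$K(x) = \exp(-(x-\lambda)^2 / 2\sigma^2)$: a fall when
$K(f_1) K(f_2) > \tau_2$ with $\tau_2 = 0.1$. Kernels, not densities: with
the published $\sigma_{f_2} = 81.36$ ms the density product at its own peak
is $\approx 7.6\times10^{-4}$ and could never exceed 0.1, so only the kernel
reading makes the published threshold meaningful. Under it the decision
boundary is exactly the circle $z_1^2 + z_2^2 = 2\ln 10$ in standardised
units, which the tests verify numerically. Detected falls are classified
from the raw axis triple $(G_x, G_y, G_z)$ at the impact peak (the published
class parameters, e.g. $\lambda_{f_3} \approx -1.9$ to $-4.0$ g, are only
consistent with raw device axes under impact) by argmax over per-class
kernel products, ties in class order, with optional per-class thresholds and
"other fall" as the fallback.

## Signal conditioning

* **Gravity** is the centred moving average over a 2-s window, truncated at
  the edges; centred rather than trailing so the estimate is delay-free.
* **Vertical** acceleration is the projection onto the per-sample gravity
  direction minus the gravity magnitude, so a motionless sensor reads 0.
* **Longitudinal** direction is not defined by a device axis: it is the
  first principal axis of the gravity-orthogonal residuals over the whole
  recording, sign fixed so the mean cubed projection is non-negative
  (forward push skews positive). This is deterministic, orientation-free,
  and invariant under any fixed rotation of the device -- a property the
  tests check both ways.
* **Torso location**: amplitudes at the upper torso differ slightly from
  the lower torso; `compensate_location()` rescales each axis about its own
  mean by the ratio of calibrated standard deviations (y: 0.0848/0.0794,
  z: 0.0862/0.0830; no x calibration is published, so x is left unscaled).

## Detection over recordings

`detect_steps()` slides a $\delta_{max}$ window by `hop` (0.1 s), thresholds
$p(\mathrm{step}\mid f_1,f_2)$ at `theta` (0.5), anchors each candidate at
the window's vertical maximum (a heel-strike proxy) and merges candidates
within a refractory gap (0.3 s), keeping the highest probability.

**Choice of $\delta_{max} = 0.9$ s.** The window must cover the longest
single-step extrema pattern (about 0.5 s at 60 steps/min) -- but not much
more. A window of ~1.6 stride periods (e.g. 1.2 s at 80 steps/min) can
*never* isolate one step: every placement that contains a step's complete
longitudinal doublet also contains a neighbour's lobe, so whenever a
smaller step adjoins a larger one the window extrema pair across steps and
the timing feature is corrupted. At 0.9 s a clean placement exists at every
modelled cadence (stride periods 0.6-1.0 s), which is what the end-to-end
sensitivity tests rely on. The value is a config parameter, not a constant.

Steps are periodic, so `correct_periodic()` post-inserts one event at the
midpoint of any gap that is within 20 % of twice the median surrounding
interval (runs split at gaps over 3x the median), never touching original
events. `detect_falls()` uses a 2.5-s window (long enough for dip plus
spike), a 2-s refractory merge, and classifies each merged event at its
$|G|$ peak.

## What the synthetic generator emulates -- and what it does not

The generators exist so every stage is testable without hardware. They
reproduce exactly the quantities the models consume, because the movements
are *defined* through their window extrema:

* `synth_walk()` draws per-step targets $(f_1^*, f_2^*)$ from the published
  cadence Gaussians (linear interpolation of $(\lambda,\sigma)$ between the
  trained cadences), renders a biphasic raised-cosine vertical pulse whose
  sampled range equals $f_1^*$ exactly, and an equal-area unequal-height
  longitudinal doublet whose sampled extrema are $f_2^*$ apart (snapped to
  the sample grid). Steps are placed at the cadence interval with +-3 %
  timing jitter; gravity (0, 0, 1) g, white noise (default 0.02 g, a typical
  consumer MEMS accelerometer at rest) and the torso-location ratios are
  applied last. Draws infeasible on the grid (|f2*| under ~2.5 samples or
  beyond 40 % of the period) are redrawn.
* `synth_fall()` renders a free-fall dip to 0.1 g followed by an impact
  spike. The impact-axis triple is drawn from the requested class's
  published distributions (truncated +-0.5 sigma) and reproduced *exactly* at
  the impact sample; the spike height is therefore the triple's norm, and
  the implied $|G|$ range lands inside the +-1 sigma band of the published
  fall-amplitude distribution for every class (asserted in tests). The
  dip-to-spike time is a +-1 sigma draw from the published timing
  distribution, so every synthetic fall satisfies the $2\ln 10$
  detectability criterion by construction -- the generator states that
  world; the tests then verify the detector honours it.
* `synth_null()` provides sitting/standing archetypes (slow AR(1) noise,
  SD 0.012 / 0.008 g) and a broadband noise archetype (0.05 g).

Not emulated: biomechanical gait shape, double support, turning, surface
changes, sensor saturation, and the external validation datasets behind the
published headline accuracies (91.14 % / 99.45 % of steps, 100 % of falls).
A green end-to-end test therefore establishes that the pipeline recovers
movements whose features follow the published distributions -- not that it
reproduces those field accuracies.

## Numerical choices and degenerate inputs

* Posteriors are computed in log space; the prior is returned unchanged
  only when every class has literally zero mass (non-finite features).
* Fitted $\sigma$ is floored at $10^{-6}$ so constant samples never yield a
  degenerate likelihood.
* Extrema ties break to the earliest index; classification ties break in
  class order c1, c2, c3.
* A motionless recording has a degenerate residual cloud; the longitudinal
  trace is then identically zero rather than an arbitrary PCA direction.
* Extraction through the estimated (2-s moving average) gravity can shift a
  step's amplitude feature by a few percent when a small step sits between
  two large ones, because partial pulses at the averaging-window edges
  wobble the baseline. The generator-fidelity tests therefore use the
  generated world's true constant gravity; the estimated-gravity path is
  covered by the end-to-end sensitivity criteria instead.
* All generators run under an isolated RNG scope: they are bit-reproducible
  from their seed and never disturb the caller's RNG state.

## Known limitations

* The longitudinal axis is estimated per recording; recordings shorter than
  a few strides may pick an unstable direction.
* The cadence grid is 60-100 steps/min; running and shuffling fall outside
  the trained model (configurable via `speed_model_set()`).
* `correct_periodic()` repairs single misses only; consecutive misses are
  out of its design envelope, as in the published post-correction rule.
* The default null-class parameters are package choices for a torso-worn
  sensor (no published values exist); retrain with `train-steps
  --null-input` for other placements.
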