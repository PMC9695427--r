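---
title: "Measuring mixing and dissolution times: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring mixing and dissolution times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dissolvr)
```

# The measurement problem

Powder-for-reconstitution drug products — for example oxime antidotes that
are unstable in solution and must be dissolved inside an autoinjector at the
moment of use — carry dissolution specifications of a few seconds. Verifying
such specifications needs two complementary assays:

* a **decolorization (mixing-time) assay**: a dyed vessel is bleached by a
  fast redox reaction while a camera films it; the time for the liquid to
  turn colorless measures macromixing;
* a **conductometric dissolution assay**: a salt's dissolution raises the
  solution conductivity; the rise-to-plateau of an immersed probe tracks the
  dissolved fraction without needing a chromophore.

`dissolvr` implements the quantitative analysis of both, the
design-of-experiments statistics used to compare conditions, and a
synthetic-data generator with closed-form ground truth that makes the whole
chain testable without laboratory data.

# Colorimetric mixing curves

Each video frame is converted to 8-bit grayscale (ITU-R BT.601 luma weights
by default — the standard choice, and monotone for a blue-to-colorless
transition) and cropped to the region of interest. Writing $R_{x,y}^t$ for
the gray value of pixel $(x,y)$ at frame time $t$, every pixel receives an
individual threshold interpolated between its initial value $R^0$ (first
frame) and its fully-mixed value $R^\infty$ (last frame, or the mean of the
trailing $N$ frames):

$$\beta_{x,y} = R_{x,y}^0 + X\,(R_{x,y}^\infty - R_{x,y}^0),$$

with the mixing coefficient $X = 0.5$ by default: the pixel counts as mixed
once it has bleached halfway, which matches naked-eye judgement for this
assay. A pixel is classified mixed in frame $t$ when $R_{x,y}^t >
\beta_{x,y}$ (strictly; the non-strict variant is available via
`colorimetry_config(strict = FALSE)`), independently per frame and with no
latching. The percent-mixed curve is

$$M(t) = 100 \cdot \frac{\#\{\text{mixed valid pixels at } t\}}{n_\text{valid}},$$

and the discoloration time $t_{90}$ is the time of the **first frame with
$M \ge 90\%$** — no interpolation, so the resolution is one frame interval
(1/60 s at 60 fps). If the level is never reached, the result is censored at
the video duration with an explicit flag, mirroring the conductometric
window. A first-mixed map records, per pixel, the first frame classified
mixed (later flicker ignored), reproducing the contour views of spatial
mixing progress.

Key parameter choices, all configurable through `colorimetry_config()`:

| parameter | default | why |
|---|---|---|
| `mixing_coefficient` X | 0.5 | halfway threshold, matches visual endpoint |
| `mixed_level` | 90 % | standard near-complete mixing endpoint |
| `static_epsilon` | 10 gray levels | pixels with $|R^\infty - R^0| < \epsilon$ (rotor shaft, vessel wall) have noise-dominated thresholds and are excluded from the denominator |
| `reference_last_n` | 1 | the literal last frame; a trailing mean suppresses sensor noise when needed |
| `strict` | TRUE | ties count as unmixed |

Conventions: pixel coordinates are 0-based `(row, col)`; frame `k` (0-based)
has time `t0_offset + k/fps`.

A note on gray values: frame stacks store *numeric* values in [0, 255]
rather than forcing integers. Image files naturally produce whole numbers,
but the synthetic generator's noiseless videos keep full precision, so
analytic crossing times are matched exactly rather than to within a
quantization artifact; the noisy generator and all image writers quantize to
whole gray levels like a real 8-bit camera.

# Conductometric dissolution times

Raw conductivity traces are not comparable across solvents (different
baseline conductivities), so each run is rescaled to percent of its own
range, $v' = 100\,(v - \text{lo})/(\text{hi} - \text{lo})$. The dissolution
time is the first sample at or above 90 % of that range inside the
observation window (60 s by default); runs that never reach it are flagged
**incomplete** and carry the window length as a censoring time — a valid
result, never silently averaged with complete replicates.

Two numerical choices deserve explanation:

* **Anchor placement.** The anchors are taken from the *whole recorded
  trace*, not just the observation window: the high anchor must approximate
  the dissolved plateau, and a run whose plateau lies beyond the window must
  stay incomplete rather than be renormalized into completeness.
* **Anchor estimation.** The default anchors are the exact min/max of the
  (optionally median-smoothed) trace. On noisy sensors, extreme order
  statistics are biased outward — the maximum of a few thousand noisy
  samples sits 2–3 noise SDs above the plateau — which biases $t_{90}$
  late by several percent. `normalize_trace(anchor_method = "reference")`
  instead uses segment medians (leading 5 % of samples for the baseline,
  trailing 10 % for the plateau), the same idea as the trailing-frame
  reference in the colorimetric module. With 1 % noise at 100 Hz and a
  median-5 pre-smoother, this estimator recovers first-order $t_{90}$
  within 5 % (verified over 120 seeded traces; mean bias under 1 %).
  Reference anchors require the recording to include a pre-addition
  baseline segment, which a synchronized powder drop-off provides.

The colorimetric and conductometric endpoints share one crossing primitive
(`first_crossing_index()`): first sample at or above the level, no
interpolation.

# Factorial statistics

The statistics module reproduces the analyses used to compare conditions:
per-group mean ± sample SD; one-way ANOVA with Tukey HSD at family-wise
$\alpha = 0.05$; the classical pooled-variance two-sample t-test; and
full-factorial screening of rotor speed, dynamic viscosity, particle-size
class and temperature with the two mechanistically expected two-way
interactions (particle size × viscosity, rotor speed × viscosity) included
by default. The factorial model is a fixed-effects linear model with
categorical factor coding; per-term F tests come from the sequential ANOVA
table, which for the balanced full factorials generated here coincides with
marginal tests. Censored runs are excluded with a logged count — no
imputation rule is defensible for them. Zero-residual-variance fits (an
exactly constant response) report no term as significant rather than NaN
surprises. Equality of variances is an untested model assumption, as in the
classical procedures.

Temperature is retained as a design factor whose significance is left to the
data; the generator's default levels (5, 25, 45 °C) span refrigerated to
field-hot conditions.

`reynolds_speed_factor()` exposes the scale-up rule implied by holding the
impeller Reynolds number $Re \propto N D^2$ constant: a diameter ratio $r$
requires an $r^2$-fold rotor-speed change (4-fold diameter ⇒ 16-fold
speed), which is why geometrically scaled-up reconstitution chambers demand
impractical rotor power.

# The synthetic world and what a green test establishes

The generator emulates three data types with closed-form ground truth:

* **Videos** (`synth_video()`): every pixel brightens exponentially,
  $R(t) = R_\infty - (R_\infty - R_0)e^{-k(x,y)t}$, with rate
  $k(x,y) = k_0 e^{-d/\lambda}$ decaying with distance $d$ from the rotor
  center — fast discoloration above the impeller, slower at the wall.
  The threshold crossing has the closed form $t^* = \ln(1/(1-X))/k$.
  Defaults (64×64 px, 60 fps, 10 s, $R_0 = 40$, $R_\infty = 240$,
  $k_0 = 2\,\mathrm{s^{-1}}$, $\lambda = 48$ px) give $t_{90}$ near one
  second, the scale of the laboratory assay. The ground-truth object also
  carries a *windowed* crossing map,
  $-\ln\!\big(1 - X(1 - e^{-k t_\text{last}})\big)/k$, which accounts for
  the analysis taking its fully-mixed reference from the last observed
  frame rather than the true asymptote; the noiseless pipeline output
  equals the windowed map's percentile snapped up to the frame grid
  *exactly*, and the two maps coincide once $k\,t_\text{last}$ is large.
  The acceptance sweep draws rates with $k\,t_\text{last} \ge 14$ so the
  ideal formula holds to double precision.
* **Traces** (`synth_trace()`): baseline, then a first-order rise after the
  powder-addition lag, $t_{90} = \text{lag} + \tau\ln 10$. The default
  duration $\text{lag} + 12\tau$ reaches the plateau at double precision.
  Noise is i.i.d. Gaussian, a fraction of the amplitude.
* **Designs** (`synth_design()`): full factorials with planted main-effect
  and interaction shifts plus i.i.d. residual noise, replicated three-fold
  like the assay.

What this world does **not** contain: advection–diffusion flow structure,
shear-thinning rheology, particle-scale dissolution kinetics, correlated
sensor noise, lighting drift, or compression artifacts. A green test
therefore establishes that the *algorithms* implement their definitions
exactly and are robust to i.i.d. noise at realistic amplitudes — not that
the physical assay is accurate. Conversely, because every ground truth is
closed-form, any failure is an implementation defect, not simulation noise.

# Degenerate inputs and tie-breaks

* Ties at the pixel threshold count as unmixed (strict `>`), configurable.
* All-static stacks and constant traces raise typed errors
  (`dissolvr_no_dynamics`, `dissolvr_no_signal`).
* A single valid pixel is a legal denominator.
* Zero pooled variance in the t-test: equal means give $p = 1$; unequal
  means are reported as exactly significant ($p = 0$), by convention.
* Singleton groups report their SD as missing, never 0.
* Censoring (video never reaching 90 %, trace incomplete in the window) is
  a result, not an error, and is never averaged into summaries.

# Reproducibility

Every generator takes an explicit seed and restores the caller's RNG state;
identical spec + seed gives bit-identical output. `run_pipeline()` executes
declarative JSON configs and writes a manifest with digests of every input
and output, so identical config + inputs reproduce identical artifacts.
Times are serialized with 6 decimals so the 1/60 s frame grid survives CSV
round trips.

# Known limitations

* Video containers (MP4 etc.) are not decoded; use image sequences
  (text PGM, CSV, or PNG). No lighting or lens correction is applied.
* The factorial module fits fixed effects only — no mixed models,
  repeated-measures structure, or nonparametric alternatives.
* `"minmax"` normalization anchors are biased outward on noisy traces (see
  above); prefer `"reference"` anchors plus median smoothing for sensor
  data.
* The per-run 0–100 % normalization cannot, even in principle, flag a run
  as incomplete if the recording stops inside the observation window before
  any plateau: the trace must extend long enough to see the plateau.
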