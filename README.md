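# dissolvr

Mixing-time and dissolution-time analytics for powder-reconstitution
devices.

## The problem

Drug products that must be reconstituted at the moment of use — e.g. oxime
antidotes in autoinjectors, which are unstable in solution — carry
dissolution specifications of a few seconds. Two bench assays quantify
whether a stirred reconstitution chamber meets them:

* **Decolorization videos**: a dyed vessel is bleached by a fast redox
  reaction while filmed; the time to near-complete color loss measures
  macromixing.
* **Conductometry**: a dissolving salt raises solution conductivity; the
  rise-to-plateau of a probe tracks the dissolved fraction for compounds
  without a chromophore.

`dissolvr` turns both raw signals into endpoint times and provides the
design-of-experiments statistics to compare rotor speeds, viscosities,
particle sizes and temperatures, plus a synthetic-data generator with
closed-form ground truth so the entire pipeline is verifiable with no lab
data.

## The statistics at the core

For a video with per-pixel gray values $R_{x,y}^t$, each pixel gets an
individual threshold between its initial and final value,
$\beta_{x,y} = R^0_{x,y} + X\,(R^\infty_{x,y} - R^0_{x,y})$ with mixing
coefficient $X = 0.5$, and is classified mixed when $R^t_{x,y} >
\beta_{x,y}$. The percent-mixed curve
$M(t) = 100\,\cdot\,\#\{\text{mixed valid pixels}\}/n_\text{valid}$ yields
the **discoloration time** $t_{90}$: the first frame with $M \ge 90\%$.
Conductivity traces are normalized per run to 0–100 % of their range and
the **dissolution time** is the first sample at $\ge 90\%$ inside a 60 s
window (runs never reaching it are censored, not averaged). Conditions are
compared with one-way ANOVA + Tukey HSD, pooled t-tests, and full-factorial
F screening; `reynolds_speed_factor()` gives the rotor-speed multiplier
$r^2$ needed to hold the impeller Reynolds number $Re \propto N D^2$
constant under an $r$-fold diameter scale-up.

## Worked example

```r
library(dissolvr)

## a synthetic discoloration video (64x64 px, 60 fps, 10 s) with known truth
sv <- synth_video(video_synth_spec(seed = 42))
sv$truth
#> <video_ground_truth> t90 = 0.7287 s (grid 0.7333 s), 4096/4096 valid px, X = 0.5

an <- analyze_video(sv$stack)
an$result
#> <discoloration_result> t90 = 0.7333 s (frame 44, n_valid = 4096)
```

The analytic 90 %-mixed time is 0.7287 s; on the 60 fps frame grid the
first frame past it is frame 44 (0.7333 s), and the pipeline reports
exactly that — the recovery is exact, not approximate.

```r
## a noisy conductivity trace (first-order rise, tau = 1.2 s, 1 s baseline)
st <- synth_trace(trace_synth_spec(tau = 1.2, noise_sd = 0.01, lag = 1, seed = 42))
dissolution_time(normalize_trace(smooth_trace(st$trace, 5),
                                 anchor_method = "reference"))
#> <dissolution_result> t90 = 3.7200 s [run ?]
```

against a true `lag + tau*ln(10)` = 3.763 s: a 1.1 % error at 1 % sensor
noise.

```r
## comparing discoloration times across solvents (5 replicates each)
anova_tukey(list(water = c(1.72, 1.61, 1.95, 1.60, 1.74),
                 gly45 = c(2.36, 2.40, 2.28, 2.45, 2.31)))
#> $F: 82.28   $p: 1.7e-05
#> tukey: gly45-water  diff 0.636  p_adj 1.7e-05  significant TRUE

reynolds_speed_factor(4)
#> [1] 16
```

The 45 % glycerol solution mixes significantly slower than water, and a
4-fold wider chamber would need a 16-fold faster rotor at equal Reynolds
number.

## Command line

```sh
# end-to-end demo: synthetic video + traces + design -> results + manifest
Rscript -e 'dissolvr::run_pipeline(list(stage = "demo", seed = 1, out = "demo_out"))'

# individual stages (launcher: system.file("cli", "dissolvr", package = "dissolvr"))
dissolvr colorimetry   --input frames/ --fps 60 --x 0.5 --level 90 --out out/
dissolvr conductometry --input traces.csv --level 90 --window 60 --smooth 5 --out out/
dissolvr doe           --design design.csv --alpha 0.05 --out out/
```

## Layout

* `R/` — colorimetry, conductometry, DoE statistics, synthetic generator,
  pipeline/CLI
* `tests/testthat/` — unit, property and acceptance suites with independent
  brute-force oracles
* `vignettes/dissolution-mixing-methods.Rmd` — models, parameter choices,
  numerical decisions, limitations
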