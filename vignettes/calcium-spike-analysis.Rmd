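---
title: "Model-based analysis of calcium spikes in line-scan images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based analysis of calcium spikes in line-scan images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caspikes)
```

## The problem

Calcium spikes are brief, sub-micron fluorescence transients that report the
calcium release flux of a single ryanodine-receptor cluster in a cardiac
myocyte. They are recorded with a confocal microscope in line-scan (x-t)
mode: one spatial line is scanned repeatedly, so image columns are space and
rows are time. Two properties make quantitative description difficult. The
signal-to-noise ratio (SNR) is inherently low, because strong EGTA buffering
confines the signal to a small volume; and the kinetics are fast enough that
the *sequential* acquisition of pixels within each scanned line is no longer
negligible: a pixel at the right edge of a 512-pixel line is acquired
hundreds of microseconds after the line's nominal time stamp.

`caspikes` addresses both problems. Noisy dF/F0 traces are described by
fitting a kinetic model rather than by filtering (filtering distorts the
kinetics), fits are accepted or rejected on statistical grounds, and the
per-pixel acquisition times are corrected before fitting.

## The spike model and its descriptors

The fluorescence increase is modelled as an activation-termination process
with onset latency $t_0$:

$$\Delta F(t) \;=\; F_M\,\bigl(1 - e^{-(t-t_0)/\tau_A}\bigr)\,
  \bigl(\alpha + (1-\alpha)\,e^{-(t-t_0)/\tau_T}\bigr),\qquad t \ge t_0,$$

and $\Delta F = 0$ before the onset. $F_M$ (dF/F0 units) is the maximal
increase that would be reached if release never terminated; $\tau_A$ and
$\tau_T$ (ms) are the activation and termination time constants; and
$\alpha \in [0,1]$ is the fraction of the signal contributed by the slow
calcium concentration build-up, so the curve relaxes to the plateau
$F_M\alpha$ rather than to zero. The curve is continuous at $t_0$ and
evaluated pointwise, so non-uniform (corrected) time grids pose no
difficulty.

Because the model is phenomenological, spikes are reported through
descriptors computed numerically from the fitted curve
(`compute_descriptors()`): peak amplitude $A$, time to peak TTP (onset to
peak) and full duration at half-maximum FDHM (interval between the
half-amplitude crossings of the two arms). The peak is located on a 0.01-ms
grid and refined by golden-section search; the crossings by bracketed root
finding. Two degenerate geometries are handled explicitly:

* monotone or numerically flat curves (e.g. $\alpha = 1$, or termination so
  weak that the plateau saturates in double precision) report the window
  end as the peak position and an **undefined** FDHM;
* a plateau above $A/2$ means the descending arm never crosses
  half-amplitude; FDHM is again undefined. Undefined FDHM deliberately
  *fails* the duration plausibility cut below — it is never replaced by the
  window length.

## Correcting pixel acquisition times

With 1-based line index $i$ and within-line pixel index $j$, line frequency
$f$ and pixel integration time $t_p$:

* unidirectional: $t_{ij} = (i-1)/f + (j-1)\,t_p$;
* bidirectional (boustrophedon): odd lines as above, even lines
  $t_{ij} = (i-1)/f + (n-j)\,t_p$;
* uncorrected convention: every pixel of line $i$ carries
  $t_i = (i-1)/f$, the time of the line's first pixel.

The *position time error* $t_{ij} - t_i$ is $(j-1)t_p$ on odd and, for
bidirectional scans, $(n-j)t_p$ on even lines (`position_time_error()`).
Calibrated integration times are bundled for scan speeds 400/800/1000
(1.39/0.658/0.515 µs); an optional high-precision 1000-Hz value
(0.51546 µs) reconciles the rounded calibration with the predicted errors
to ±0.001 µs. Formulas are 1-based as written above; storage is an ordinary
R matrix indexed the same way, and the physical acquisition order
(row-major, boustrophedon for bidirectional) is strictly increasing in time
— a property the test suite checks for random configurations.

Fitting a trace extracted *without* correction biases exactly one
parameter: the latency. The data are acquired later than the uncorrected
axis claims, so the fitted onset appears *earlier* by the position time
error of the spike's column; all other parameters are unaffected. The
timing experiment (`timing_error_experiment()`) reproduces this with
noise-free rendered spikes at columns 4, 256 and 509 and ten latencies
spanning one sampling period; the bias is independent of the onset phase
(additive two-way ANOVA, latency factor p > 0.05) but fully determined by
the column.

One convention deserves emphasis. For bidirectional scans analysed without
correction, consecutive forward/backward line pairs are averaged and
assigned the mean of their two line times. This matches how bidirectional
data are conventionally rendered at the nominal scan speed and makes the
uncorrected latency bias a stable compromise near the mean of the odd- and
even-line errors; treating the 2f-rate lines individually instead makes the
bias strongly dependent on where the onset falls within the line period,
which is not what is observed in practice.

## Extraction

`subtract_background()` removes the mean of a non-cell region;
`estimate_baseline()` takes the pre-stimulus mean $F_0$ and per-pixel noise
SD from an in-cell region (it warns if the region extends past the
stimulus); `extract_trace()` averages 7 spatial pixels centred on the spike
(white noise SD shrinks by $\sqrt{7} \approx 2.65$), normalizes to
$\Delta F/F_0$, and attaches per-sample times. Spatial averaging incurs the
same sequential-sampling error as the centre pixel alone, so the corrected
time of the centre pixel is the right time stamp for the averaged sample.
$F_0$ is a single global mean over the baseline region; a per-column
baseline would only matter with strong spatial inhomogeneity, which the
rectangular-ROI workflow assumes away. Times in a trace are reported
relative to the stimulus onset, so the fitted $t_0$ is directly the
stimulus-to-release latency. ROIs are 1-based, inclusive rectangles in
(row, column) coordinates — ordinary R indexing.

## Fitting and statistical acceptance

`fit_spike()` minimizes the sum of squared residuals over the five
parameters, evaluated at the trace's actual sample times. Four minimization
back ends are provided: a bounded quasi-Newton trust-region method (the
default pipeline), Nelder–Mead simplex (bounds via a smooth box transform:
quadratic maps for one-sided bounds, a sine map for the two-sided
$\alpha$), Levenberg–Marquardt, and an undamped Gauss–Newton with step
halving (benchmark parity only). The last two do not support constraints
and refuse `constrained = TRUE`. Box constraints for the constrained modes
are $t_0 \ge 0$, $F_M > 0$, $\alpha \in [0,1]$, $\tau_A, \tau_T \ge 1$ ms,
with open upper ends realized as $10^6$; parameters ending on a bound are
flagged. Robust variants reweight iteratively (at most 10 rounds): LAR uses
$w = 1/\max(|r|, 10^{-3}s)$ and bisquare the Tukey weights with tuning
constant 4.685, both with a MAD-based scale $s$.

A single fixed initialization vector (the indicator preset means, or the
seeded truth in the detectability study) is used; there is no multi-start.
Multi-start would sweep the latency axis and latch onto noise, inflating
false positives, and would break comparability across algorithms.
Convergence is declared at a relative objective change below $10^{-10}$ or
400 iterations (2000 function evaluations for the simplex); hitting the
iteration cap with finite parameters is treated as a usable local minimum,
because the tight tolerance dithers at the kink the onset parameter makes
at sample boundaries. Acceptance never depends on the iteration count
alone: a fit is **accepted** when the extra-sum-of-squares F-test prefers
the spike model over a constant at p < 0.05,

$$F = \frac{(SSE_0 - SSE_1)/(5-1)}{SSE_1/(N-5)},$$

with the spike model counted as 5 parameters and the constant as 1. This
degrees-of-freedom accounting is recorded in every result object. For
robust fits the F-test is still computed on the unweighted least-squares
footing, so acceptance means the same thing in every configuration.

Two optional plausibility filters mirror common practice: Selection A
($\tau_A \ge 1$ ms, $\tau_T \ge 1$ ms, FDHM < 40 ms, $0 \le t_0 < 80$ ms,
$A \ge 0.01$) and Selection B ($A/\sigma$ above a user threshold). Both are
evaluated by the benchmark harness but neither replaces the F-test: on
pure-noise traces parameter-plausibility cuts pass a substantial fraction
of spurious fits, while F-test acceptances are rare (see Limitations).

## The synthetic-spike generator

`make_dataset()` produces the three canonical dataset types, sampled at
the corrected centre-pixel times of a configured scan (default: 512 lines
at 1 kHz unidirectional, stimulus at 50 ms, spike column 256):

1. **population datasets** — parameters drawn independently from normal
   distributions around the indicator means (invalid draws rejected and
   redrawn, so no mass piles up at the domain boundaries), plus white
   Gaussian noise of fixed RMS;
2. **pure noise** — for false-positive auditing;
3. **fixed spike, graded noise** — the mean-parameter spike with noise
   $\sigma = A/\mathrm{SNR}$ for each SNR of the indicator's grid
   ({1, 1.5, 2, 3, 5, 7, 10} for OG-5N, extended to 15 and 20 for
   Fluo-3), for detectability studies.

All randomness comes from R's Mersenne-Twister stream and every dataset is
a pure function of its recipe and seed. `render_xt_image()` additionally
renders spikes into synthetic x-t images — each pixel evaluated at its own
$t_{ij}$, a Gaussian spatial profile, optional per-pixel noise — so the
whole image pipeline can be exercised end to end.

### Indicator presets are reconstructions

The bundled OG-5N and Fluo-3 presets are **synthetic reconstructions**, not
transcriptions of an experimental calibration table. They are anchored to
published aggregate statistics of the two indicator regimes: OG-5N traces
carry 0.15 dF/F0 RMS noise and an SNR distribution of 5.39 ± 2.11
(minimum ≈ 1.7), which fixes the mean peak amplitude at
5.39 × 0.15 ≈ 0.81 and its coefficient of variation at 2.11/5.39; Fluo-3
has SNR 14.19 ± 5.60, implemented with unit mean amplitude and noise RMS
1/14.19. Kinetic time constants are set to literature-scale values for the
two indicators (OG-5N: $\tau_A$ 2.5 ± 0.8 ms, $\tau_T$ 5 ± 1.5 ms,
$\alpha$ 0.15 ± 0.05, FDHM ≈ 12 ms; Fluo-3: $\tau_A$ 3.5 ± 1 ms, $\tau_T$
12 ± 3 ms, $\alpha$ 0.10 ± 0.03, FDHM ≈ 19 ms), and $F_M$ is derived at
preset construction so that the mean-parameter curve peaks exactly at the
target amplitude. What the generator does **not** emulate: photon-counting
(Poisson) statistics, photobleaching, out-of-focus events, baseline drift,
motion, and two-spike traces. Passing tests therefore demonstrate
correctness of the estimation machinery under the stated noise model, not
robustness to every artefact of real recordings.

## What the validation studies can and cannot reproduce

The acceptance studies in `tests/testthat/test-acceptance.R` rerun the
validation programme at full scale (1000 traces per study; the
detectability sweep at 200 traces per SNR — sizes chosen so the whole suite
completes in a few minutes on one core). Three outcomes deserve honest
discussion, because they are properties of *mechanism*, not bugs:

* **Detection here is test-power-limited.** With an unbiased least-squares
  fit, the probability of detecting a spike of SNR $s$ is the power of a
  noncentral $F(4, N-5)$ test with noncentrality $s^2 E$, where $E$ is the
  spike's normalized signal energy on the sampling grid. For the preset
  kinetics $E \approx 8$–9, which puts the 50%-detection point near
  SNR ≈ 1 and leaves well under 5% of spikes undetected at SNR 3. A
  detection midpoint as high as SNR ≈ 2, with a logistic steepness around
  10, cannot be produced by this mechanism for any kinetics compatible
  with the amplitude-precision aggregates: amplitude correlation ≈ 0.99
  between seeded and fitted values requires the same $E \approx 9$ that
  forces the midpoint down. Detection thresholds reported by
  optimizer-limited pipelines (fits that fail to converge at low SNR) are
  therefore systematically more pessimistic than the statistical limit
  implemented here.
* **The false-positive rate is small but not zero.** A thoroughly
  minimized 5-parameter local fit occasionally captures enough variance
  from 512 samples of pure noise to cross p < 0.05; the measured rate is
  ≈ 1% of traces. A weaker optimizer shows zero false positives for the
  same test simply because it under-fits noise. The F-test criterion still
  outperforms the plausibility filters by a wide margin (which pass tens
  of percent of noise fits).
* **Constrained and unconstrained fits perform similarly here.** Large
  gaps between constrained and unconstrained acceptance arise from
  divergence of unconstrained optimizers into invalid parameter regions;
  the bounded-fallback behaviour of the implementations used here keeps
  the unconstrained fits comparatively healthy.

## Known limitations

Single-spike traces only (no two-release models); Gaussian noise only;
rectangular ROIs; no native microscope metadata parsing (scan parameters
come from an explicit config block); the logistic detectability fit is
flagged ill-conditioned when the SNR grid never brackets 50% undetected,
and its midpoint should not be interpreted in that case.
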