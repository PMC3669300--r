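# caspikes

Quantitative analysis of **calcium spikes** — the brief, localized
fluorescence transients that report calcium release from single
ryanodine-receptor clusters in cardiac myocytes — recorded by confocal
laser scanning microscopy in line-scan (x-t) mode.

Spikes are small and fast, and their traces are dominated by noise.
Instead of filtering (which distorts kinetics), `caspikes` fits each
dF/F0 trace with a kinetic model of the spike time course,

&nbsp;&nbsp;&nbsp;&nbsp;ΔF(t) = F_M · (1 − e^−(t−t0)/τA) · (α + (1−α) · e^−(t−t0)/τT),  t ≥ t0,

where t0 is the latency from the voltage stimulus, F_M the maximal
increase absent termination, τA/τT the activation/termination time
constants and α the fraction contributed by calcium build-up (the late
plateau is F_M·α). A fit is accepted only when the extra-sum-of-squares
F-test prefers it over a constant at p < 0.05 — which suppresses
false-positive "spikes" in pure noise far more reliably than
parameter-plausibility or amplitude thresholds. Fitted spikes are reported
through numerically derived descriptors: peak amplitude A, time to peak
TTP, and full duration at half-maximum FDHM.

Because line-scan pixels are acquired sequentially, a pixel at within-line
position j is measured (j−1)·tp after its line's nominal time stamp
(tp = pixel integration time; reversed parity on the even lines of
bidirectional scans). `caspikes` builds per-pixel acquisition-time maps,
corrects trace time stamps accordingly, and quantifies the latency bias
incurred without correction — up to ~26% of a line period at the far edge
of a 512-pixel line.

The package also contains:

* an extraction pipeline for x-t TIFF images (background subtraction,
  baseline F0 and noise estimation, 7-pixel spatial averaging),
* a synthetic-spike simulator (random-population spikes, pure noise, and
  fixed-spike/graded-SNR datasets; synthetic x-t image rendering with
  physically emulated pixel timing),
* a benchmarking harness: a 14-configuration comparison of minimization
  algorithms (trust region, simplex, Levenberg–Marquardt, Gauss–Newton ×
  robust modes × constraints), timing-error experiments, and SNR-dependent
  detectability with a logistic fit.

## Worked example

Simulate one noisy OG-5N-like spike and fit it with the default pipeline
(constrained trust region, F-test acceptance):

```r
library(caspikes)

pre <- indicator_preset("OG5N")        # synthetic low-SNR indicator preset
ds  <- make_dataset(dataset_spec(1, pre, n_traces = 1, seed = 42))
f   <- fit_spike(ds[[1]]$trace, fit_settings(init = pre$param_means))
print(f)
#> Spike fit (trust_region, constrained): accepted, F = 55.6, p = 7.6e-39
#>   t0 = 5.312 ms, FM = 1.590, alpha = 0.150, tauA = 2.489 ms, tauT = 5.602 ms
#> A = 0.7266 dF/F0, TTP = 3.442 ms, FDHM = 12.56 ms, t0 = 5.312 ms

unlist(ds[[1]]$truth)                  # seeded parameters of this trace
#>        t0        FM     alpha      tauA      tauT
#> 5.0967668 1.4580557 0.1681564 3.0062901 5.6064025
```

The fit is accepted (the spike model beats a constant, p ≪ 0.05) and the
parameters land close to the seeded truth despite an SNR near 5: the
latency is recovered within ~0.2 ms and the amplitude descriptor A within
the noise-limited precision. At the far edge of the image the uncorrected
time convention would have biased that latency by a quarter of a
millisecond:

```r
cfg <- scan_config_preset(1000, "unidirectional")
position_time_error(cfg, 509)          # microseconds
#>  odd_line_error even_line_error
#>          261.62          261.62
```

Image workflows run through a YAML config (see `?run_analyze`):
background/baseline ROIs, spike positions, fit settings in; a per-spike
results CSV out. A thin command-line wrapper ships at
`inst/cli/spikefit.R` with `analyze`, `simulate` and `benchmark`
subcommands.

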