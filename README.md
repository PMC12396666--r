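# loudsum

Excess binaural broadband loudness summation in hearing-impaired
listeners, and what it does to hearing-aid gain targets.

Even after a hearing aid normalizes *narrowband* loudness from the
audiogram, many hearing-impaired listeners rate *broadband, binaural*
sounds as louder than normal-hearing listeners do. `loudsum` is an R
package for audiology researchers that models this effect end to end:

* **Loudness functions** — the two-branch categorical-scaling model
  `CU(L) = clip[0,50](25 + m·(L − L_cut))` with slopes `m_lo`/`m_hi`
  (CU/dB) pivoting at 25 CU, optional smooth transition; exact inversion,
  normal-hearing narrowband/broadband references, and audiogram-based
  estimation of recruiting hearing-impaired functions.
* **Excess summation** — `ΔL40 = L40ref − L40`, the level difference at
  40 CU ("loud"–"very loud") between the normal-hearing binaural IFnoise
  reference (L40ref = 82.3 dB SPL) and an individual's aided measurement;
  positive values mean louder-than-normal perception.
* **Simulated adaptive scaling** — virtual listeners with CU-scale response
  noise, a two-phase adaptive procedure (bracket, then even coverage, 22
  trials), and a classed weighted-least-squares model fit
  (`fit_loudness_function()`, with `coef`/`predict`/`plot`/`simulate`
  methods).
* **Gain prescription** — the three-step loudness-normalizing
  (trueLOUDNESS-style) procedure: narrowband normalization gains from the
  audiogram, an aided broadband measurement, and a frequency-uniform
  level-dependent correction; plus compression ratios
  `CR = ΔLin/(ΔLin + G_high − G_low)` and prescription comparison by the
  mean unsigned gain difference (5-dB meaningful-difference criterion).
* **Synthetic cohort** — a calibrated generator (default 88 New + 72
  Experienced + 20 Experimenter + 20 normal-hearing participants) whose
  group-wise skew-normal ΔL40 distributions reproduce means 13.2/8.1 dB,
  pooled 2.5/97.5 percentiles −12.4/36.1 dB and the normal-hearing 95th
  percentile of 17.2 dB analytically, with audiograms around an N3-like
  sloping profile and UCL/questionnaire covariates with calibrated
  couplings.

## Worked example

```r
library(loudsum)

coh <- generate_cohort(seed = 1)        # 200 synthetic participants
rec <- coh$records[[1]]                 # a New user, latent dL40 16.91 dB

trials <- run_adaptive_scaling(rec$listener, "IFnoise")
fit <- fit_loudness_function(trials)
fit
#> Fitted categorical loudness function (weighted least squares)
#>   l_cut    m_lo    m_hi
#> 47.1337  0.7775  0.8238
#>   L40: 65.34 dB SPL   trials: 22   WSS: 330.67

delta_l40(82.3, l40(fit$fn))
#> [1] 16.96
```

The listener reaches 40 CU at 65.3 dB SPL instead of the normal-hearing
82.3 dB SPL: a measured excess summation of 17.0 dB (latent truth
16.9 dB). The prescription reacts by cutting gain, increasingly so at high
input levels:

```r
g <- prescribe_trueloudness(rec$audiogram, fit)
sapply(c(50, 65, 80), function(L) gain_at(g, 1000, L))
#> [1] 15.3  4.3  0.5        # dB insertion gain at 1 kHz
compression_ratio(gain_at(g, 2000, 50), gain_at(g, 2000, 80), 50, 80)
#> [1] 2.72
```

The full pipeline (simulate → scale → fit → prescribe → analyse) on the
default cohort:

```r
out <- run_pipeline(pipeline_config(seed = 1), out_dir = "pipeline-out")
sapply(out$summary$group_stats[1:3], `[[`, "prevalence_excess")
#>         New Experienced Experimenter
#>        0.34        0.26         0.15
out$summary$rmse_delta_l40_recovery
#> [1] 2.57                   # fitted vs latent dL40, dB
```

About a third of the simulated hearing-aid users fall beyond the
normal-hearing boundary (ΔL40 > 17.2 dB), and the measurement chain
recovers the latent effect to better than 3 dB RMSE.

See `vignettes/loudness-summation-methods.Rmd` for the model, the
calibration of the generator, and the package's assumptions and limits.

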