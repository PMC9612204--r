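# capcompare

Validation analyses for dry-electrode EEG caps against conventional
gel-based caps. Dry multipin electrodes cut cap preparation time roughly
threefold but run at electrode-skin impedances of hundreds instead of tens
of kOhm, so the practical question is whether the *signals* — resting-state
spectra, blink artifacts, pattern-reversal visual evoked potentials (VEPs)
— remain equivalent, and which channels stay reliable. `capcompare`
implements the full comparison pipeline for paired gel/dry recordings made
on different 64-channel montages (extended ten-twenty and equidistant),
plus a synthetic cohort generator so the whole chain is testable without
human recordings.

## What it computes

* **Montages on a spherical head model** — built-in extended ten-twenty and
  quasi-uniform equidistant 64-channel layouts, their 128-position union,
  and BIDS-style `electrodes.tsv` I/O.
* **Spherical-spline interpolation** (Perrin-style): kernel
  `g(x) = (1/4π) Σₙ (2n+1)/(n(n+1))ᵐ Pₙ(x)` with `m = 4`, `N = 50` Legendre
  terms, solved with a constant-offset constraint; used to map any
  recording (minus its bad channels) onto the combined 128-channel montage
  and to draw topographic maps.
* **Preprocessing** — zero-phase Butterworth band-pass 1–40 Hz (order 4)
  and 49–51 Hz notch (order 3), automated bad-channel rating (isoelectric /
  artifact windows, ≥ 50% rule), common average reference.
* **Resting state** — 30-s center windows, Welch PSD (2-s Hamming windows,
  50% overlap, µV²/Hz), alpha (8–13 Hz) mean power and topography.
* **Evoked activity** — blink overlays (2 s / 10 s), VEP epoching
  (−100…+400 ms), trial rejection, averaging, GFPt (spatial SD across
  electrodes), N75/P100 peak detection and N75-anchored latency alignment.
* **Comparison statistics** — channel reliability (good/total per channel),
  per-electrode impedance summaries, grand-average metadata with the
  dry/gel preparation-time ratio, Pearson r + RMSD agreement metrics,
  Lilliefors normality checks, and exact/approximate Wilcoxon–Mann–Whitney
  U tests.
* **Synthetic cohorts** — paired gel/dry sessions with occipital alpha,
  frontal blink transients, occipital VEP components, bad channels,
  cap-dependent log-normal impedances and subject metadata; EDF+ and YAML
  I/O; fully reproducible from one master seed.

## Worked example

```r
library(capcompare)

cfg <- sim_config(n_subjects = 3, seed = 42,
                  segment_durations = c(eyes_open = 40, eyes_closed = 40,
                                        blink = 22, vep = 45),
                  n_vep_epochs = 60)
cohort   <- simulate_cohort(cfg)            # 6 sessions: gel + dry x 3 subjects
analysis <- analyze_cohort(cohort)          # filter, rate, interpolate, analyze
report   <- build_report(analysis)
report
#> <study_report>
#>   subjects: 3, seed: 42, config: 1d2e69a4
#>   prep-time ratio dry/gel: 0.21 (79% reduction)
#>   reliability dry: 89% +- 18%
#>   reliability gel: 89% +- 26%
#> # A tibble: 4 x 7
#>   metric        unit    mean_r     sd_r mean_rmsd sd_rmsd     n
#>   <chr>         <chr>    <dbl>    <dbl>     <dbl>   <dbl> <int>
#> 1 blink_frontal uV       0.994 0.000433     2.10   0.0868     3
#> 2 psd_closed    uV^2/Hz  0.988 0.00785      0.315  0.115      3
#> 3 vep_channels  uV       0.715 0.0118       0.980  0.0153     3
#> 4 vep_gfp       uV       0.994 0.00324      0.101  0.0317     3

analysis$analyses[[1]]
#> <session_analysis S01/gel (ten_twenty): 7 bad ch, alpha peak 10.00 Hz,
#>  N75 72 ms, P100 120 ms>
```

Reading the output: the simulated dry cap needs a fifth of the gel
preparation time at this cohort size; about 89% of channel-segment
sequences rate "good" under the 10% bad-channel rate the generator
injects; and the gel-versus-dry agreement metrics (Pearson r per subject,
then averaged) are high for the blink overlay at the frontal channels, the
eyes-closed spectra, and the VEP global field power — the same pattern of
metrics a real validation study tabulates. The per-session line shows the
analysis recovering the generator's ground truth: the 10 Hz alpha peak and
the 72/120 ms component latencies.

Per-result plotting and tidying:

```r
autoplot(analysis$analyses[[1]]$psd$eyes_closed)      # spectra, all channels
autoplot(analysis$analyses[[1]]$gfp,
         peaks = analysis$analyses[[1]]$peaks)        # GFPt with N75/P100
tp <- topography(analysis$analyses[[1]]$alpha$eyes_closed$power$power,
                 analysis$layout)
autoplot(tp)                                          # alpha topography
glance(report$reliability)                            # reliability summaries
write_report(report, "report")                        # JSON + CSV bundle
```

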