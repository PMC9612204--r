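---
title: "Methods: comparing gel-based and dry EEG caps with capcompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing gel-based and dry EEG caps with capcompare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dry multipin EEG electrodes promise much faster cap preparation than
conventional gel-based electrodes, at the cost of higher electrode-skin
impedance and potentially lower channel reliability. Validating a dry cap
against a gel cap means comparing recordings made with *different montages*
(an extended ten-twenty layout and an equidistant layout) across the classic
clinical paradigm: resting state with eyes open and closed, triggered eye
blinks, and a pattern-reversal visual evoked potential (VEP). `capcompare`
implements that comparison pipeline end to end, together with a synthetic
cohort generator so every stage is testable without access to human
recordings.

## Spherical geometry and montages

The head is modeled as a unit sphere; every analysis is radius-independent.
Two built-in 64-channel layouts are provided.

* **Extended ten-twenty.** Midline sites at 18° polar steps from the vertex,
  the circumferential ring at 72° inclination, and intermediate rows placed
  by great-circle (slerp) interpolation between each row's midline and ring
  site, plus mastoids. This reproduces the conventional geometric reading of
  the 10-10 system (e.g. C3 lands at 36° left of Cz on the coronal arc).
* **Equidistant.** Concentric rings at 9°, 27°, 45°, 63°, 81° inclination
  (uniform 18° polar spacing, offset 9° from the ten-twenty grid so the two
  montages never coincide), with per-ring electrode counts proportional to
  ring circumference (3, 9, 14, 18, 20). Nearest-neighbour angular distances
  have a coefficient of variation of about 0.03 — far inside the 0.35
  quasi-uniformity bound we test.

Labelling the equidistant montage was a genuinely open design point: a
"ring + side" scheme cannot uniquely label rings holding several lateral
pairs. We number lateral pairs sequentially starting at the frontmost pair
of the *outermost* ring, so `1L`/`1R` sit over the forehead — the
equidistant counterparts of Fp1/Fp2, which is exactly how they are used in
the blink-artifact comparison. Midline sites are numbered `<n>Z`.

`combined_layout()` unions two montages by label (conflicting positions for
a shared label are an error), giving the 128-position montage all
comparisons run on.

## Spherical-spline interpolation

Scalp potentials are interpolated with the Legendre-series spline kernel

$$g(x) = \frac{1}{4\pi}\sum_{n=1}^{N}\frac{2n+1}{(n(n+1))^{m}}\,P_n(x),$$

solved once per electrode set with a constant-offset constraint, so
interpolation is linear in the data and one factorization serves every time
sample. Parameters default to the literature-standard $m = 4$, $N = 50$,
ridge regularization $10^{-5}$ on the kernel diagonal. The series has
numerically converged long before $N = 50$ (changing $N$ from 20 to 50
moves smooth-field interpolants by under 0.1% of the field range). With
zero regularization the solution interpolates exactly at the sources; the
$m = 4$ kernel is then severely ill-conditioned, so the solver uses a
pivoted LAPACK QR and refuses only numerically singular systems
(condition $> 10^{15}$). A degree-2 zonal spherical harmonic sampled at the
64 ten-twenty sites is reconstructed at all 128 combined sites with a
maximum error below 2% of the field range; a constant field is reproduced
to machine precision through the offset term.

## Preprocessing chain

1. **Filtering.** Butterworth band-pass 1–40 Hz; the conventional
   "24 dB slope" reading is 24 dB/octave, i.e. order 4. The 50 Hz notch is
   an order-3 Butterworth band-stop over 49–51 Hz. Filters are applied
   forward–backward (zero phase): component latencies are compared at 2 ms
   resolution and must not be biased by filter group delay. A side effect
   worth knowing: the 1 Hz high-pass attenuates slow, large transients —
   the ~300 ms blink template loses roughly 14% of its peak through this
   chain, which is why amplitude-recovery checks are run on raw epochs.
2. **Channel rating.** Channel quality is traditionally judged by visual
   inspection; we substitute a deterministic surrogate with exposed
   thresholds. Each 1-s
   window of a segment fails as *isoelectric* when its SD is below 0.1 µV,
   or as *artifactual* when its peak-to-peak exceeds 400 µV or its SD
   exceeds 8× the cross-channel median window SD. A channel is bad when at
   least 50% of its windows fail — the same ≥ 50% rule the channel-reliability
   definition is built on. On simulated data these thresholds
   recover the ground-truth bad channels exactly; on real data they are a
   starting point, not a replacement for expert review.
3. **Interpolation to 128 channels.** The spline is fitted on good source
   electrodes only (bad channels are excluded *before* fitting, then
   reconstructed); native good channels pass through unchanged. Fewer than
   16 good channels is an error rather than a silently bad interpolation.
4. **Common average reference**, applied after interpolation, subtracting
   the instantaneous 128-channel mean.

Whether filtering in such validation protocols is zero-phase, and whether
channels are rated before or after filtering, is rarely documented; this
pipeline rates after filtering (the rating thresholds then see band-limited data, which
is what their defaults are calibrated for).

## Resting-state, blink, and VEP analyses

* **Spectra.** A 30-s window is taken from the center of each resting
  segment (odd leftover sample goes before the window). Welch PSD uses 2-s
  Hamming windows with 50% overlap — 0.5 Hz resolution covering the 1–40 Hz
  band of interest — scaled as one-sided density in µV²/Hz so band-integrated
  power equals variance (verified against Parseval and a white-noise
  closed form). Alpha power is the per-channel mean of density bins with
  centers in [8, 13] Hz, edges inclusive by convention for determinism.
* **Blink overlays.** Short trials of 2 s centered on each beep and long
  trials of 10 s spanning 5 consecutive beeps (anchored on every fifth
  beep), averaged without baseline correction (blinks are the signal of
  interest, and a pre-trigger baseline would straddle the preceding blink).
* **VEP.** 500-ms epochs (−100 to +400 ms), per-channel pre-stimulus
  baseline correction (standard practice; switchable), whole-trial rejection when any channel's
  peak-to-peak exceeds 150 µV, arithmetic averaging, then GFPt — the
  per-sample *population* SD (divisor N) across electrodes. Component
  peaks are the GFPt argmax in 50–100 ms (N75) and 90–170 ms (P100),
  windows chosen to bracket the canonical 72/120–122 ms grand-average
  latencies; ties break to the earliest sample and flat windows are
  flagged low-confidence. A P100 candidate not later than the N75
  candidate is an error carrying both latencies. Latency alignment (used
  for multi-center trigger-delay correction) shifts the *averaged*
  waveform by whole samples with edge truncation; shifting averages rather
  than raw data is the cheaper equivalent for every statistic computed
  here.

## Comparison layer

Per subject, gel and dry sessions are compared on the combined montage:
Pearson r and RMSD of (a) the 2-s blink overlay at the frontal channels
(Fp1, Fp2, 1L, 1R), (b) the eyes-closed PSD over all channels and
frequencies, (c) the VEP waveform over all channels, and (d) the VEP GFPt.
Channel reliability is the good/total ratio of rated sequences per channel,
grouped by cap and layout; because the aggregation level of a single
"average reliability" is ambiguous, summaries report all three aggregations
(per cap × layout, per cap, overall). Impedances are averaged start/end per
session, then across subjects per electrode.

Normality of the across-subject metric samples is checked with the
Lilliefors variant of the Kolmogorov–Smirnov test: the comparison is
against a normal with *estimated* mean and SD, so the plain KS null would
be wrong. Cap differences are tested with the Wilcoxon–Mann–Whitney U test:
midranks for ties, exact permutation p-value when $n_a n_b \le 400$ and no
ties are present, otherwise a normal approximation with tie and continuity
corrections. The exact path is verified against full enumeration of all
$\binom{n_a+n_b}{n_a}$ assignments for every pair with $n_a+n_b \le 10$,
and the approximation tracks the exact p within 0.02 at $n = 8+8$.

## The synthetic cohort generator

The generator is a minimal statistical model that exposes every pipeline
feature, not a biophysical simulation:

* background: per-channel $1/f$ noise (exponent 1, SD 10 µV) plus white
  sensor noise (SD 2 µV);
* alpha: an amplitude-modulated 10 Hz sinusoid weighted by a Gaussian
  (40° width) around Oz — 20 µV at the occipital maximum with eyes closed,
  5 µV otherwise;
* blinks: a biphasic ~300 ms template (150 µV peak) at each 2-s beep,
  weighted by a 35° Gaussian around Fpz, making frontal amplitudes ≥ 5×
  occipital ones;
* VEP: Gaussian-windowed lobes (σ = 10 ms) — N75 negative at 72 ms
  (7.38 µV) and P100 positive at 120 ms (17.57 µV) at the occipital
  maximum — canonical grand-average component values for this paradigm;
* bad channels: each channel is bad for a whole session with probability
  0.1, replaced by a near-isoelectric trace or 150 µV-SD noise with equal
  probability;
* impedances: log-normal per cap (gel: median 15 kOhm, sdlog 1.0; dry:
  median 350 kOhm, sdlog 0.7) with a 1.8× centro-parietal elevation for
  the dry cap — reproducing the tens-versus-hundreds-of-kOhm contrast and
  its topography;
* metadata: normal draws per cap centered on the published grand averages
  (e.g. preparation 32.3 ± 13.8 min gel vs 12.4 ± 6.5 min dry), ratings
  rounded and clamped to their scales. The attention scale is described
  inconsistently in the source material (1–8 Stanford-type versus a 1–10
  table header); the bound is a configuration field (default 8) and the
  summaries simply report what was recorded.

Randomness uses one master seed with per-subject/per-cap/per-stage derived
streams, so any session can be regenerated independently of execution
order, and metadata can be drawn without synthesizing signals
(`simulate_cohort_metadata()`) while remaining bit-identical to the full
cohort's metadata.

Default segment durations follow the acquisition protocol the pipeline is
designed around (184.0, 183.0, 67.1, 204.8 s with 150 VEP reversals). The test suite and the acceptance script
run desk-scale conditions chosen once: 10 subjects, 40/40/22/45-s
segments, 60 reversals at ~0.74 s spacing (a realistic pattern-reversal
rate), 500 Hz. Under those conditions the pipeline recovers the configured
alpha peak to the exact 0.5-Hz bin, mean N75/P100 latencies within 4 ms,
and the blink template amplitude within 10% on raw epochs.

What passing these tests does *not* show: the generator has no EMG, line
noise bursts, electrode drift, inter-channel correlated noise, or
subject-specific spectra, so real-data performance of the bad-channel
thresholds and rejection rules still needs human review.

## Numerical and degenerate-input conventions

Constant inputs to the correlation are an error (undefined), as are
degenerate SDs in the Lilliefors test; all-rejected trial sets, empty
trigger lists, segments shorter than their analysis window, and
sub-minimum channel counts all raise informative errors instead of
propagating NaN. EDF export quantizes to 16 bits with per-channel
symmetric physical ranges; round trips are exact to the quantization step,
and segment/trigger annotations travel in an EDF+ annotations signal.

## Orchestration

The package is a library: `simulate_cohort()` →
`analyze_cohort()` → `build_report()` → `write_report()` compose the full
study, each stage returning plain R objects (tibbles wherever the result is
tabular) that can be inspected, plotted (`autoplot()` methods) or tidied
(`tidy()`, `glance()`). `scripts/acceptance.R` re-runs the main
computation from scratch and records the headline numbers as JSON.
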