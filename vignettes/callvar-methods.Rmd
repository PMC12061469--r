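---
title: "Methods: multi-level call-variation analysis with callvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-level call-variation analysis with callvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callvar)
```

## The problem

Advertisement calls of male frogs are shaped by morphology (body size
constrains dominant frequency), physiology (temperature accelerates
temporal traits), and population history. Asking *which* call parameters
could serve as individual or group signatures requires separating
variation at four nested levels: within one male across his calls
(CV~i~), among males of one locality (CV~p~), among males of one
geographic group (CV~g~), and across all males (CV~o~). `callvar`
implements that decomposition plus the downstream comparisons for
pulsatile calls — trains of amplitude-modulation bursts ("pulses") on a
tonal carrier — measured by six parameters: call duration, call
interval, dominant frequency, 5–95% bandwidth, pulse number, and pulse
rate.

## Measurement model

All spectral quantities are computed on a Hann-window short-time power
spectrum with a 512-sample window and 50% overlap (hop 256), the common
"default power" preset of interactive bioacoustics software; frequency
resolution is `sample_rate / 512` (86.13 Hz at 44.1 kHz). Where an
interactive workflow uses manual selections, `callvar` substitutes
algorithmic detectors, each validated by synthesizer round trips:

* **Noise reduction.** A 4th-order Butterworth high-pass (bilinear
  transform), default cutoff 500 Hz — below the lowest call energy of
  interest, giving ≥ 24 dB attenuation one octave below the cutoff. The
  cutoff is configurable; the filter is applied forward-only (the < 1 ms
  group delay at call frequencies is negligible against the ±5 ms
  segmentation tolerance).
* **Call segmentation.** Moving-RMS envelope (2 ms window) against an
  adaptive threshold 10 dB above the noise floor, where the floor is the
  10% quantile of envelope samples. Hysteresis (release 4 dB below the
  onset threshold) stabilises the boundary; active stretches closer than
  50 ms are merged (pulse gaps must not split a call), stretches shorter
  than 20 ms are discarded as clicks.
* **Pulse detection.** Upward envelope crossings at 50% of the per-call
  envelope peak. Two guards prevent double counting: a crossing is
  accepted only if the envelope has dipped below 80% of the threshold
  since the last accepted onset (hysteresis — otherwise noise jitter on
  the *descending* slope of a pulse re-crosses the threshold), and
  onsets are debounced at 3 ms. The constant offset between the true
  pulse onset and the 50%-crossing cancels in first-to-last onset spans,
  which is why pulse rate `(n − 1) / span` is recovered to well under
  5% in round trips.
* **Dominant frequency** is the argmax of the *time-averaged* power
  spectrum over the call (selection-wide peak, matching selection-based
  measurement), not a per-frame maximum. **Bandwidth** is the span
  between the 5% and 95% cumulative-energy quantiles of that average
  spectrum, linearly interpolated between bins. **Call interval** is
  offset-to-onset (silent gap), following call-centred terminology;
  onset-to-onset is available via `interval_mode`.
* **Call selection.** The `k = 5` *consecutive* calls maximising summed
  SNR, mirroring the field practice of measuring five continuous
  high-SNR calls; shortfalls are flagged, not fatal.

## Statistical model

**CV framework.** `CV = 100% · SD / mean` with the sample (n − 1) SD,
the default of the statistics software this analysis style comes from.
CV~i~ is computed per individual over its calls; CV~p~ and CV~g~ over
the *individual means* within each locality/group; CV~o~ over all
individual means. Using individual means (not pooled calls) at the upper
levels keeps the levels strictly nested and parallels the CV~o~
construction. All levels are scale invariant, which the suite checks as
a property.

**Classification.** Gerhardt's categories applied to the mean CV~i~:
static below 5%, dynamic above 12%, both boundaries belonging to
intermediate.

**Discriminability.** Two ratios are emitted: CV~o~ / mean CV~i~
(the headline column — the quantity that published tables of this
analysis style actually tabulate) and CV~o~ / mean CV~g~ (the quantity
the ratio is sometimes *named* for). Emitting both sidesteps the
naming/value ambiguity without guessing intent.

**Group effect.** A Model II (random-effects) one-way ANOVA on
individual means by group. For a one-way layout its F, p and
η² = SS~between~ / SS~total~ coincide with the fixed-effects
computation, so the sums of squares are coded directly — a deliberate
choice that lets a hand-computed oracle verify every number. Zero total
variance degenerates to η² = 0, p = 1 with a warning. For two groups
η² equals the squared point-biserial correlation (tested as a
property).

**Temperature.** Per-parameter OLS of individual means on air
temperature; the Platz–Forester correction is the standard linear
adjustment `x_corr = x − b (T − T_ref)`, applied only when the slope is
significant at α = 0.05 (configurable) and the parameter is not exempt.
Pulse number is exempt by default. The reference temperature is the
count-weighted mean of locality temperatures (27.6 °C under the default
study design). Correcting exactly collinear data zeroes the residual
slope to < 1e−8, and a second correction pass is the identity — both
asserted in tests.

**Geography.** Haversine distances (Earth radius 6371.0088 km) between
localities; acoustic distance is the absolute difference of locality
means, one matrix per parameter (a per-parameter univariate metric,
because the target analysis reports one Mantel r per parameter; a
multivariate Euclidean option over standardised means exists but is not
default). The Mantel statistic is the Pearson correlation of
upper-triangle entries; significance is one-tailed upper (positive r =
isolation by distance) with `p = (1 + #{r* ≥ r}) / (1 + B)` over seeded
joint row/column permutations of one matrix, or exhaustive enumeration
of all n! relabelings for ≤ 5 localities, where p needs no +1
correction because the identity permutation is enumerated.

**Group comparison.** Per group Shapiro–Wilk at α = 0.05 (per-group is
the stricter, standard reading of "each variable"); both normal →
Bartlett homogeneity + pooled-variance t-test; otherwise → Levene
(Brown–Forsythe, median-centred, implemented in-package) + Wilcoxon
rank-sum. All tests two-sided; a homogeneity failure is flagged, not
fatal. Exempt (uncorrected) parameters are compared on their raw means.

## The synthetic world

The generator states one fixed world and is never tuned to test
outcomes:

* **Audio.** Raised-cosine-enveloped carrier bursts at onsets
  `i / pulse_rate`; burst width `min(duration − span, 0.9 / rate)` so
  consecutive envelopes are separated by silence; white Gaussian noise
  at a stated dBFS floor (−50 dBFS default against ~0.9 peak amplitude,
  i.e. SNR well above the 20 dB round-trip guarantee). Ground truth
  (bounds, exact pulse onsets) is returned with every waveform.
* **Tables.** `value = group_mean + locality_effect +
  individual_effect + b (T_l − T_ref) + within_noise`, all Gaussian,
  fully seeded. Defaults mirror the motivating study design: 9
  localities in 2 groups with their published temperatures and male
  counts (33 males), 5 calls each; group means from the published NE/SW
  columns; `sd_within` from mean CV~i~, `sd_individual` from mean
  CV~p~, `sd_locality` from `sqrt(CV_g² − CV_p²)` (clamped at 0 for
  bandwidth, whose published CV~p~ exceeds its CV~g~ — a within- vs
  among-population anomaly the source itself notes). Temperature slopes
  default to 0 because no slope values are published; they are
  configurable and tested with nonzero values. A log-normal mode covers
  strictly positive parameters.

What a green test establishes: the estimators recover *known* Gaussian
variance components (10% relative at 200 individuals, 30% at the study
size) and the detectors recover *clean synthetic* calls. What it does
not: robustness to chorus overlap, propagation effects, recorder
nonlinearity, or non-Gaussian trait distributions — real-world audio
performance is out of scope by design.

## Numerical choices and edge cases

* Sample SD everywhere; CV undefined for zero means (error, not NA).
* The last call of a bout has `NA` interval; statistics exclude NAs
  pairwise, never impute.
* Localities/groups with a single individual yield `NA` unit CVs,
  excluded from level summaries with a warning.
* Constant groups make Shapiro–Wilk undefined → Wilcoxon branch with a
  warning; `wilcox.test` handles exactness/ties (exact for small
  tie-free samples, normal approximation with tie correction
  otherwise), verified against exhaustive rank enumeration.
* Mantel p is reproducible bit-for-bit given (seed, B).
* All frequency logic is parameterised by sample rate; tests run at
  44.1 kHz.

## Known limitations

Overlapping callers defeat the single-source segmentation (the
motivating field protocol likewise discarded such recordings). The
Butterworth implementation is a direct-form IIR; at cutoffs far below
1% of the sample rate, second-order-section filtering would be
numerically safer. Mantel tests with 9 localities have modest power;
none of this package's inferences should be read as spatial
autocorrelation modelling.
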