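---
title: "Methods: connectivity, directionality and statistics in meaconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity, directionality and statistics in meaconnect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaconnect)
```

## The measurement model

An assembloid fusing a midbrain organoid (MO) and a striatum organoid
(StrO) sits on an 8×8 electrode grid whose two halves are separated by a
microfluidic divider; neurites cross only through microtunnels, so any
correlated spiking between compartments reflects axonal signalling. The
pipeline reduces 64 spike trains to one interpretable object: a vector
field of signal directionality and a binary "connection established"
verdict, plus the conduction speeds along accepted paths.

Geometry is kept in **pitch units** (inter-electrode distances) end to
end; micrometres enter only where a physical speed is computed. The y
axis runs from the MO edge (row 1) towards StrO, so positive vertical
components read "signal flows MO → StrO". The physical pitch of the
plates is not part of the analysis model and is therefore a *required*
input, never a default.

## Pairwise stage

**STTC.** For trains A and B, `P_A` is the proportion of A's spikes
within ±Δt of some B spike and `T_A` the fraction of the recording
covered by ±Δt tiles around A's spikes (tiles merged and clipped to the
window). The coefficient is
½[(P_A − T_B)/(1 − P_A T_B) + (P_B − T_A)/(1 − P_B T_A)]. Δt defaults to
10 ms, small enough to favour mono-synaptic coupling. If a denominator
vanishes (only possible when P = T = 1) that term contributes 1 — the
continuous limit. Empty trains raise an error rather than silently
scoring 0, because "no evidence" and "no correlation" are different
statements. The implementation is held to a brute-force evaluation of
the same formula (dense distance matrices, sequential interval merge) to
1e−10 over random Poisson pairs.

**Cross-correlogram and delay.** Signed differences `t_B − t_A` within
±50 ms are binned at 0.5 ms (bin k covers [(k−½)b, (k+½)b), so bin
centres are exact multiples of the bin width and a planted integer-bin
delay is recovered exactly). The half-window of 50 ms is a design
choice — generous against the 10 ms synchrony scale yet short enough to
stay in mono-synaptic territory. The maximum is significant when it
exceeds the histogram mean by 5 SD of the per-bin probabilities, with
the maximal bin included in both statistics (no leave-one-out is
stated anywhere authoritative, and including it is the conservative
reading). Ties between equal maxima resolve to the smallest |delay|,
then to the positive one — determinism over elegance.

**Sparse-histogram guard.** The mean + 5 SD rule silently assumes a
well-populated histogram. Two independent 1 Hz trains over 180 s
produce only ~18 pairs across 201 bins; the SD of bin probabilities is
then so small that a bin holding just *two* chance coincidences clears
the gate, and roughly half of all independent low-rate pairs would be
called significant. A conduction-delay claim resting on two
coincidences is not evidence, so `significant_delay` additionally
requires the maximal bin to hold at least `sig_min_count = 5`
coincidences (config-exposed; reason code `"sparse"`). Well-populated
correlograms — anything with a genuine propagation path at realistic
rates, where peaks hold tens to hundreds of coincidences — are
untouched; the guard only suppresses the sparse-regime pathology. With
it, the null false-positive rate over 100 independent-pair runs is 0–2
per 100 instead of ~46.

**Speed.** `V = d/|t|` in m/s, undefined (NA) at zero delay. On the
simulator's 5-pitch connection (1.5 mm at 0.3 m/s ⇒ 5 ms, an exact bin
centre) the recovery is exact; jitter of 0.2 ms keeps the mass in the
planted bin, so errors stay within one bin (±10% at 5 ms).

**Activity floor.** Electrodes with fewer than
`min_spikes_per_electrode = 10` spikes are excluded from the pairwise
stage (both STTC and correlograms are unstable below this); exclusions
are recorded on the returned table.

## Directionality and establishment

Each accepted pair (significant delay **and** STTC ≥ 0.3) contributes
the displacement vector from its leading to its lagging electrode, full
magnitude — a "vector connecting the two electrodes" is a displacement,
not a unit direction, and longer links should count for more. Whether
the vector attaches to one or both member electrodes is genuinely open;
the default attaches to **both** (a connection is evidence about both
ends), and the assembloid-level components are normalised by the
resulting multiplicity of 2 before thresholding, so the verdict is
invariant to the attachment convention (`attachment = "lead"` switches
to single attachment; the normalised y and |x| are identical by
construction, which the tests assert). Pairs with an exactly zero delay
carry no direction and are skipped.

Establishment uses `|y| ≥ 2` pitch units: the literal reading of the
stated criterion ("a value ≥ 2, i.e. the distance between 2
electrodes"), applied to the absolute value because a net StrO → MO
flow establishes a connection just as well — the sign is reported
separately. Both the threshold and its signed/absolute interpretation
are config-exposed. The lateral component is reported as |x|, left and
right being arbitrary on this geometry. A high-STTC display cut-off
(0.8) seen in figure-level renderings elsewhere is a plotting filter,
not an analysis gate; analysis uses 0.3 throughout.

`maturation_trajectory` summarises y and |x| per developmental stage
(mean ± SD) and applies Kruskal–Wallis with Dunn's post-hoc and
Benjamini–Hochberg adjustment. Fully tied data short-circuit to
H = 0, p = 1 (base R's tie correction would otherwise return NaN).

## Spike detection

The vendor "adaptive threshold" detector is unpublished; this package's
stand-in estimates the noise scale per rolling 1 s window as
MAD/0.6745 — robust against the spikes themselves — and flags samples
exceeding k = 6 local SDs in either polarity. One event per excursion,
timed at the absolute extremum; excursions closer than 1 ms merge
(refractoriness). At 12.5 kHz and k = 6 the per-sample Gaussian tail
bound keeps false positives below ~0.002 per minute of pure noise.
Equivalence with the vendor's internals is not claimed.

## Statistics layer

Batch correction divides each value by its batch mean (idempotent;
zero-mean batches error). Outliers are removed by the IQR proximity
rule with type-7 (linear interpolation) quartiles — the fences depend
on the quartile convention, so it is fixed and documented. The filter
is single-pass: fences are computed once on the input; re-filtering the
kept set can tighten them further, so the tested invariant is subset
monotonicity, not a fixed point. The Prism-side ROUT procedure used in
some figure legends of the protocol this mirrors is deliberately not
implemented (proprietary, nonlinear-regression-based); IQR is the
single supported rule. The default order is batch-normalise → filter,
switchable.

`hypothesis_tests` routes on per-group Shapiro–Wilk normality (α =
0.05): Welch's t / one-way ANOVA + Tukey when all groups pass,
two-sided Wilcoxon / Kruskal–Wallis + Dunn + BH otherwise; groups
smaller than 3 cannot be Shapiro-tested and force the nonparametric
route with a warning. The Wilcoxon is exact for combined n ≤ 20 without
ties, normal-approximated with continuity correction above —
reproducible small-sample p-values. Because Shapiro at n = 4 can never
reject, an explicit `route` override exists for analyses where the
measurement scale, not a small-sample test, dictates the method. Stars
follow \*p < 0.05, \*\*p < 0.01, \*\*\*p < 0.001, \*\*\*\*p < 0.0001.

## The synthetic world

The generator emulates exactly the features the pipeline measures:
homogeneous Poisson background per electrode (default 1 Hz — firing
rates for real assembloids are unpublished, so this is an engineering
choice in the plausible 0.5–5 Hz range), optional renewal bursts (5
spikes at 10 ms ISI, off by default — burst frequency is reported
downstream but no generative burst model is stated anywhere, so the
simplest renewal form is used), and directed connections that copy each
source spike to its target with a transmission probability at
distance/speed plus Gaussian jitter truncated at ±3 SD (default SD
0.2 ms, within one-to-two correlogram bins). Copies landing outside the
window are dropped. The default topology couples row 2 to row 7 in
every column, both directions, with forward/backward transmission
probabilities 0.8/0.2 in the forward-biased fixture — strong enough
coupling that STTC comfortably clears 0.3 on the forward links while
the 0.2 reverse links fall below it, which is precisely the regime the
acceptance gates are meant to separate.

What the generator does **not** emulate: network bursts spanning
electrodes, rate nonstationarity, polysynaptic chains, electrode noise
and waveform shape (except in the detection-stage trace synthesiser),
or biological variability across assembloids. A green simulation test
therefore establishes parameter recovery under the stated generative
model — not performance on real recordings, whose headline statistics
(92% establishment by D40, maturation trends) come from undeposited
data and are out of desk-scale reach.

One integer seed drives the whole generator through R's default RNG
stream in fixed electrode order, so fixtures regenerate byte-identically.

## Numerical choices and degenerate inputs

- Duplicate spike times collapse to one event with a warning
  (physiologically impossible at 12.5 kHz).
- Empty trains: STTC errors; correlograms return an `empty` flag; the
  delay gate reports reason codes (`empty`, `uniform`, `sparse`,
  `below_threshold`) rather than a bare FALSE.
- Uniform (zero-SD) histograms are never significant — avoids 0/0.
- Spike-list round trips preserve times to 1e−9 s (9-digit fixed
  formatting); result CSV/JSON round trips are lossless to 1e−12.
- All geometry in pitch units until a speed is requested.

## Known limitations

Single recording per file (no multi-well bookkeeping); no proprietary
binary formats; no spike sorting; no shuffle-corrected correlograms,
coherence or transfer entropy; no graph-theoretic summaries beyond the
vector field; no mixed-effects models or power analysis.
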