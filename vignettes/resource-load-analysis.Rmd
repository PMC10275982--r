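---
title: "Quantifying gene-expression resource load with a co-transfected capacity monitor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene-expression resource load with a co-transfected capacity monitor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowCapacity)
```

## The measurement

Synthetic constructs delivered into mammalian cells do not express in
isolation: transcription and translation of every cassette draw on finite,
shared cellular machinery. A construct that expresses strongly therefore
taxes everything else the cell is making. The capacity-monitor assay makes
this visible by co-transfecting each test construct with a constitutively
expressed fluorescent reporter (mKATE driven by a strong constitutive
promoter) that carries no regulation of its own. Whatever the monitor loses
relative to a no-competition baseline — co-transfection with an empty
vector — is the test construct's *resource footprint*, and the monitor's
retained expression is the *remaining capacity*:

$$\mathrm{capacity} \,[\%] \;=\; 100 \cdot
  \frac{\overline{\mathrm{mKATE}}_{\mathrm{test}}}
       {\overline{\mathrm{mKATE}}_{\mathrm{empty}}},$$

where each bar is a mean over replicate-level gated mean fluorescence
values. `flowCapacity` implements the full path from raw per-cell events to
these percentages, together with the downstream design analyses: which part
of a construct (promoter, Kozak, polyA) buys output at what capacity cost,
and which designs are Pareto-efficient for co-expression.

## Pipeline stages and their choices

### Events and channels

Event tables come from FCS 3.0/3.1 files (`readEventsFCS()`) or CSV
(`readEventsCSV()`). All analysis happens on the linear RFU scale exactly
as stored by the instrument: no arcsinh/log transform, no compensation and
no background subtraction, because the reported quantity is a plain mean
RFU and the capacity ratio cancels any common gain. Channel roles
(test reporter, monitor, optional second reporter) are mapped explicitly
with `channelMap()` rather than guessed from FCS labels, which are
site-specific.

### Gating

Transfected cells are selected with a fuzzy OR gate (`fitControl()`,
`gateTransfected()`). Per channel, an untransfected control defines a
location (its 99.9th percentile) and a scale (the upper-tail spread,
`(location - median)/6`); each event's membership in the transfected
population is the logistic function of its distance from the location in
units of that scale, and the per-channel memberships combine by maximum
(fuzzy OR). The logistic-around-a-control-quantile form is this package's
own concrete choice of membership function: it is monotone, bounded, and
collapses to a crisp 99.9th-percentile threshold gate as the scale goes to
zero (degenerate controls are floored at
`sqrt(.Machine$double.eps) * max(1, location)`, which realises exactly that
crisp limit). Published fuzzy gating implementations differ in the exact
membership shape (trapezoidal, logistic, probabilistic sums); anyone who
needs parity with a specific external gating tool should compare on their
own controls — the `GateResult` object exposes every per-channel membership
to make that comparison direct. The decision threshold defaults to 0.5, the
logistic midpoint, giving a symmetric error trade-off; the OR means adding
a channel can only grow the gated set.

Scatter-based viability gating is deliberately not applied: acquisition
already restricts recording to viable cells on the instrument side, and the
simulator emits pre-viable events.

### Summaries, outliers, errors

`summarizeSample()` reports the arithmetic mean and *population* standard
deviation (divisor $n$) per channel over gated events — the per-event sd
describes the measured population, not an estimate from a sample of
repeats. Replicate-level spread, in contrast, uses the *sample* sd
(divisor $n-1$) throughout.

Outlier exclusion follows Tukey fences applied once, at the replicate-mean
level: one gated mean per biological repeat, quartiles by linear
interpolation, and values strictly outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ removed
(`tukeyFilter()`). Applying the fences per event instead would trim the
tails of every fluorescence distribution and bias the means systematically,
so the filter never touches events.

The capacity error bar is the quadrature combination of the two
replicate-level relative errors,
$\mathrm{err} = \mathrm{capacity}\cdot\sqrt{(s_t/\bar t)^2 +
(s_e/\bar e)^2}$. Combining both sources is this package's documented
choice; reporting only the test condition's variability would understate
the uncertainty of a ratio whose denominator is itself estimated from a
handful of repeats.

### Significance

Between-condition comparisons use the two-sided Mann–Whitney U test
(`mannWhitneyTwoSided()`), with mid-ranks. For small tie-free problems
($n+m \le 16$) the p-value is exact: twice the lower-tail probability of
the smaller U under full enumeration of all $\binom{n+m}{n}$ assignments,
clipped to 1. Larger or tied problems use the normal approximation with tie
correction and a 0.5 continuity correction. With three replicates per side
— the library screen's usual depth — the smallest attainable exact p is
$2/\binom{6}{3} = 0.1$, which is worth remembering when reading the
per-design significance columns. Star annotations follow the four-level
convention (`significanceStars()`): \*\*\*\* below 1e-4, \*\*\* below 5e-4,
\*\* below 5e-3, \* below 0.05.

### Attribution and the design landscape

`enumerateSingleFactorPairs()` forms every pair of constructs that differ
in exactly one design element and share the rest of their context,
oriented so the test-reporter difference $\Delta\mathrm{EGFP}$ is
non-negative (exact ties ordered lexicographically, so the enumeration is
deterministic). `quartileAttribution()` then bins each element's pairs into
quartiles of their own $\Delta\mathrm{EGFP}$ distribution and averages the
*signed* $\Delta$mKATE per bin: the capacity cost of a given output gain,
by element. Two choices here were genuinely open and are switch-like in the
code rather than hidden:

* quartile boundaries are computed per element (promoter, Kozak, polyA
  separately), not pooled — per-element binning keeps the four bars of each
  group equally occupied, which is how such bar groups are usually drawn;
* bars average signed differences, not magnitudes, so an element that
  *rescues* monitor expression shows as a positive bar rather than being
  folded into a loss.

`paretoFront()` formalises "designs worth choosing" as the maximal
non-dominated set under componentwise $\ge$ on (reporter mean, monitor
mean) with strict improvement in at least one coordinate; exact duplicates
are both retained. The implementation is a sort-and-scan; tests verify it
against quadratic brute force.

### Densitometry

`normalizeEbna1()` implements the western-blot normalisation arithmetic
for a payload protein quantified against a Vinculin loading control: lane
factors from Vinculin relative to the strongest lane on the blot, factor
times payload signal, then division by the blot's mean normalised signal
over non-control lanes. The negative-control lane takes part in the
Vinculin maximum (it is a real lane with real loading) but not in the mean,
so non-control finals average to exactly 1 within every blot. Band
quantification from images is out of scope; inputs are numeric lane
signals.

## The simulator

Because raw acquisition data are large and instrument-specific, the package
carries a generative stand-in (`simulateSample()`, `simulateLibrary()`)
with per-event ground truth, and every downstream stage is tested against
it. The model is deliberately minimal — two saturating resource pools in
series with proportional-share allocation:

$$m_j = \frac{A_j P_j c_j}{\kappa_T + \sum_k A_k P_k c_k}\, R_T,
\qquad
q_j = \frac{K_j m_j}{\kappa_L + \sum_k K_k m_k}\, R_L,$$

with $c_j$ the plasmid copies, $P_j$ promoter strength, $A_j$ polyA
stability, $K_j$ Kozak efficiency; optional polyA interference multiplies
competitors' $m$ by $1/(1 + w_j A_j P_j c_j)$. Pool conservation
($\sum m \le R_T$, $\sum q \le R_L$) holds for every event by
construction. This is invented scaffolding, not an estimated mechanistic
model: it is the smallest structure that reproduces the three qualitative
behaviours the analysis must be able to detect — promoter-dominated load,
near-insensitivity of the monitor to translational (Kozak) changes when
the translational pool is far from saturation, and polyA-mediated
interference. An `mrnaMode` bypasses the transcriptional pool entirely,
emulating mRNA co-transfection: cassette loads become delivered mRNA
amounts, so a 10x change in Kozak efficiency moves the reporter >5x while
the monitor stays flat within a percent.

Default study conditions, chosen once and kept: 10000 events per sample
and three biological replicates per design; transfected fraction 0.5
(typical transient transfection efficiency); per-plasmid copy numbers
log-normal with log-sd 0.8 around a median of 100, correlated at
$\rho = 0.8$ between co-delivered plasmids (plasmids enter cells together,
which is what makes OR gating across the two reporters sensible); monitor
plasmid at a quarter of the test plasmid's mass; $\kappa_T$ small relative
to typical transcriptional demand (the saturated regime the assay relies
on) and $\kappa_L \ge 100\times$ maximal translational demand (the
unsaturated regime); dox induction of the TET promoter as a Hill
multiplier with exponent 2, EC50 0.1 ng/µL and 2% basal leak;
autofluorescence log-normal around 80 RFU and 25% multiplicative
measurement noise. Promoter strengths span a 128-fold geometric series
across eight named promoters; Kozak efficiencies make two variants nearly
equivalent and one weak; polyA stabilities span 0.4–1.5 with interference
weights on two variants. Absolute copy numbers and strengths are
order-of-magnitude placeholders — every test built on the simulator checks
ranks, monotonicity, recovery of designed structure, or closed-form
identities, never absolute fluorescence values.

What the simulator does *not* emulate: cell-cycle and growth feedback,
spectral spillover between channels, instrument saturation and
digitisation, doublets, and stable single-copy integration. Tests passing
on simulated data therefore demonstrate that the analysis recovers the
structure the model encodes, not that the model is a faithful account of
any particular cell line.

Per-sample seeds derive from the run seed by a counter scheme
(`(seed mod 1e5) * 10007 + i * 7919`), so any single sample can be
regenerated without replaying the library; identical seeds give
bit-identical output.

## Numerical notes and degenerate inputs

* Quantiles everywhere (gate location, Tukey fences, quartile boundaries)
  use linear interpolation of order statistics (R type 7); attribution
  intervals are right-closed, so boundary pairs fall in the lower quartile.
* A sample whose gate retains zero events is excluded with a warning
  rather than propagating NaN means.
* A constant negative control produces a floored gate scale and hence an
  effectively crisp gate, not a division by zero.
* Fewer than three replicate values pass through the outlier filter
  unfiltered, with a warning; fewer than four attribution pairs collapse
  to a single labelled bin.
* Exact Mann–Whitney p-values are clipped to (0, 1]; the tie-corrected
  normal path returns p = 1 when the pooled variance vanishes.
* Written result tables round-trip reals to at least 12 significant
  digits; reruns of `runPipeline()` under the same config and seed are
  bit-identical.

## Problem sizes

The shipped tests run the full screen at its study scale: an
8 promoter × 3 Kozak × 2 polyA library, three replicates of 10000 events
per sample, over five seeds, verifying rank recovery of promoter
strengths, per-seed monotonicity of the monitor, the promoter-versus-Kozak
ordering of top-quartile attribution, and ≥99% gate recall and precision.
Unit tests use smaller draws (hundreds to thousands of events) where the
property under test does not need depth. The acceptance script simulates
the eight-promoter screen (28 samples, 280000 events) and recomputes the
empty-control capacity anchor from scratch.

## Limitations

The gate membership shape is a documented stand-in, not a reimplementation
of any specific published gating code. Capacity error bars assume
independent test and control replicate variability. The attribution
analysis is purely pairwise — no interaction modelling or variance
decomposition across elements. The simulator's parameters are placeholders
on an arbitrary RFU scale, and nothing in the package estimates resource
pool sizes from data.
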