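---
title: "Base calling and quantitation for single-molecule tunneling-current sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base calling and quantitation for single-molecule tunneling-current sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the model

A mechanically controllable break junction holds two gold electrodes about
0.75 nm apart in a DNA solution under a 0.1 V bias. When a base molecule of
a translocating strand resides in the gap, the tunneling conductance rises
above the baseline to a level characteristic of that base; the recorded
conductance–time trace (10 kHz sampling) therefore shows spike-like events
whose internal levels encode a partial base sequence. For the DNA analogues
of the let-7 microRNA family — 22-mers over the three letters T, A, G —
the peak conductances are approximately 45 pS (thymine), 77 pS (adenine)
and 102 pS (guanine), each well described by a Gaussian.

`tunnelcall` implements the complete computational chain around this
physics: a synthetic trace simulator with ground-truth annotations, signal
detection, probabilistic base calling, reading-direction analysis,
overlap-consensus assembly, and single-base-marker counting for mixtures of
two variants. Raw laboratory recordings of such measurements are rarely
available, so the simulator is a first-class, tested component: it
defines the conditions under which every downstream claim is checked.

## What the simulator emulates

A translocation event is modelled as a ±1-step random walk over the source
sequence:

* **Read length** (number of distinct bases visited) is geometric with
  success parameter 0.3, truncated at 12 — the electrode region admits at
  most 12 bases, and observed read-length histograms decay exponentially.
  The parameter 0.3 is the package's choice of a realistic decay; the cap
  and the exponential shape are the modelled facts.
* **Dwell** per base is a 0.5-ms floor (the minimum retention time) plus an
  exponential with mean chosen so the total mean dwell is 0.667 ms, i.e. a
  translocation velocity of 1.5 bases/ms. The memoryless form is the
  standard single-molecule assumption; only the floor and the mean are
  empirically anchored.
* **Entry and reversals.** The molecule enters from the 3′ or 5′ end with
  equal probability, and at each step the reading direction reverses with
  probability 0.05 (a qualitative phenomenon in the measured data; the rate
  is a configurable package default). A reversal re-reads bases just read,
  producing a mirrored span — a "duplicated readout" — inside the fragment.
* **Conductance.** Over each dwell, samples are drawn from the dwelled
  base's Gaussian; between events, from the baseline Gaussian (0 pS mean
  after correction, 4 pS sd). Per-base sd defaults to 8 pS. Inter-event
  gaps are exponential with a 50-ms mean — the event rate is not reported
  for the original measurements, and this default reproduces the look of
  typical recordings of this kind (a handful of events per few hundred ms).

What the simulator does **not** model: gap-distance physics (conductance
levels are empirical Gaussians, not a tunneling model), slow instrumental
drift (available as an optional sinusoid, off by default), correlated
noise, and multi-molecule co-occupancy. Consequences for interpretation:
passing tests demonstrate that the analysis chain recovers the parameters
of *this* generative model at realistic noise; they do not certify
performance on raw laboratory traces, whose artefacts are richer.

## Signal detection

The baseline ("base current") is a centred 2000-sample moving average with
truncated edge windows. Because the baseline should describe the trace
*where no molecule resides*, detection is two-pass: segments found with the
raw moving average are replaced by linear interpolation, the baseline and
noise are re-estimated on the cleaned trace, and detection is repeated.

The noise scale is estimated per one-second block: the sample standard
deviations of the 500 disjoint 20-sample windows form a set whose *most
frequent value* is taken as that second's σ. "Most frequent" is made
precise as the midpoint of the most populated histogram bin under the
Freedman–Diaconis bin width, with ties resolved toward the smaller σ
(conservative detection). The mode, unlike the mean, is insensitive to the
small fraction of windows that contain signal.

A segment opens when the baseline-corrected conductance exceeds 6σ,
extends backward to just after the most recent sample at or below 1σ and
forward to just before the first sample below 1σ (so segment indices are
half-open and every in-segment sample lies above the fall threshold),
carries the σ of the second containing its trigger, and is discarded if
shorter than the 0.5-ms minimum retention time. On a noise-free rectangular
event the recovered boundaries are exact; the unit tests hold the
implementation to a literal brute-force transcription of this automaton.

## Base calling

Segments are smoothed with a 5-sample (0.5 ms) running median — sub-
retention excursions cannot survive a median of width equal to the minimum
retention time, while genuine plateaus are preserved. The pooled smoothed
samples of all segments form a count histogram (1-pS bins) fitted by
nonlinear least squares with a Gaussian per base plus a baseline component,
initialized at the most prominent local maxima. The lowest fitted mean is
the baseline, the highest is guanine, and the remaining peaks map to the
alphabet in ascending order (thymine, then adenine, for the three-letter
default). An expectation–maximization fit of the same mixture is used in
the test suite as an independent cross-check of the peak means; the
least-squares-on-counts route is the implementation because it matches the
histogram-fitting description of the measurement.

Calls are made per 0.5-ms interval. Each label's probability density is
*integrated over the interval* — the score is the summed density of the
interval's samples under that label's Gaussian (equal priors), and the
posteriors are the normalized scores. The integral form matters at interval
boundaries, where samples from two dwelled bases mix: summed densities let
the majority base win, whereas a product of densities (summed
log-likelihood) can prefer the intermediate-conductance base and insert a
spurious letter between, say, a T and a G dwell. Ties break toward the
lower-conductance label and are flagged; calls whose top-two posterior gap
is below 0.1 are marked low-confidence and their letters are down-weighted
in the consensus.

Runs of consecutive identical calls become letters through dwell-aware
splitting: a run of duration `d` emits `max(1, round(d / 0.667))` letters.
The nominal dwell is written 0.667 ms deliberately: a two-interval (1.0 ms)
run must emit a single letter (1.0/0.667 = 1.4993 rounds to 1), and a
1.34-ms run two. This rule is what distinguishes one long dwell from a
genuinely repeated letter (the GG and TT pairs of the let-7 sequences);
it is right about two-thirds of the time for a double letter, and the
consensus stage is designed to absorb the remaining third.

## Reading direction, unfolding, velocity

With a reference available, a fragment is aligned to walks on the reference
that step exactly one base per letter, by dynamic programming over
(position, direction) states maximizing letter matches and, among ties,
minimizing direction changes. The walk's direction changes are the fold
points; fragments below 60% identity are set aside as unalignable. For
fragments up to 8 letters the DP is tested against exhaustive enumeration
of all walks.

Reference-free unfolding looks for a fold index after which the letters
mirror the letters just read (span ≥ 3, at most one mismatch), drops the
duplicated span, and repeats until no fold remains. Because every accepted
fold strictly shortens the fragment, this terminates and is idempotent —
the iteration-to-fixed-point is chosen over a hard two-fold cap precisely
so that idempotence is guaranteed. A reversed read is the reversed letter
string, never complemented: the junction reads base identity, not strand
chemistry.

Velocity is a single weighted least-squares slope of |position| versus
letter time pooled over monotone stretches of at least 4 letters
(per-stretch intercepts, common slope). Letter times are quantized to the
0.5-ms calling interval, so residuals can vanish by construction; the
residual variance is floored at the quantization variance (interval²/12
per letter) to keep the slope's standard error honest — without the floor,
zero-residual stretches acquire unbounded weight and the pooled estimate
collapses onto the quantized slope of 2 bases/ms. Across fragments, the
pooled estimate is the inverse-variance-weighted mean with a seeded
bootstrap interval.

**Read length.** The read length of a fragment is the number of distinct
base molecules it visited: the count of distinct reference positions of
its best walk. Raw letter counts overstate it — a duplicated readout reads
bases twice, and example fragments with folds can have more letters
than the 12-base admission limit. Two single-molecule quality filters
apply: segments lasting longer than 1.5× a full-length translocation
(12 × 0.667 ms) are treated as two molecules piled into one event (at a
50-ms mean gap about 0.2% of gaps are shorter than one sample), and
unalignable fragments carry no molecular read length. Even so, the
*maximum* over ten thousand noisy reads typically lands one or two above
the physical limit of 12 — a true 12-base read extended by a spurious end
letter is the expected extreme-value behaviour — while the distribution's
support is overwhelmingly (≥ 99.9%) within the limit and decays
exponentially.

## Assembly

Fragments of at least five letters (shorter ones are hard to place
unambiguously on a 22-mer and are discarded) are unfolded and
assembled into a consensus with per-position coverage and normalized
conductance — the heat-map table.

The pairwise machinery is classical overlap–layout–consensus:
`best_overlap()` finds the maximal suffix–prefix overlap over both
orientations with deterministic tie-breaks (fewer mismatches, then the
un-reversed orientation, then the smaller offset), and merging is exact
(zero mismatches) at a minimum overlap of four letters — with a three-
letter alphabet and imperfect reads, permissive overlaps misassemble.
Identical letter sequences are stacked first (the first merges any greedy
pass performs), pooling the two entry orientations into one stack keyed by
the lexicographically smaller of the sequence and its reversal.

A naive longest-overlap-first greedy is, however, not robust on this
problem, and the package's assembler goes further in three documented ways:

1. **Seed-and-extend schedule.** Miscalled fragments are *correlated*: a
   GG pair read as one G produces the same shifted sequence in every
   affected event, and these error stacks overlap each other consistently.
   An all-pairs greedy chains them into a competing chimeric contig.
   Merging stacks only into the growing layout, seeded at the most
   supported stack, prevents error-against-error chaining. A merge may
   extend the layout by at most two new letters: genuine end growth
   proceeds in small well-overlapped steps, while error haplotypes dangle
   long tails.
2. **Spectrum initialization and refinement.** When the fragment set is
   deep, the initial consensus instead comes from a 6-mer spectrum walk
   (every true 6-mer of the let-7 family is unique, and true 6-mers
   outnumber error 6-mers severalfold), beam-branched where a competing
   continuation reaches half the best count. Every fragment is then
   re-placed against the fixed consensus allowing mismatches, and votes
   are recounted (two to three rounds). Mismatch-tolerant re-placement
   breaks the order dependence of exact greedy merging: a fragment with a
   single miscall settles at its true offset instead of a coincidental
   exact one.
3. **Parsimony scoring and homopolymer polishing.** Competing consensus
   candidates — including single-copy indel variants and chimeras that
   duplicate content in both orientations — are ranked by the classic
   consensus-string objective: total fitting-alignment edit distance of
   the reads (each read's cost capped at half its length), plus a small
   per-column cost. Ungapped mismatch counting cannot separate indel
   variants, because an indel shifts rather than mismatches the reads.
   Hill-climbing over homopolymer insert/delete moves (with combined
   interior-indel-plus-terminal-letter moves, so a shifted consensus is
   repaired in one step) polishes the final sequence.

When the molecule's length is known — it is 22 for the let-7 analogues,
just as it was in the experiment that this pipeline models — the consensus
is constrained to the best-scoring window of that length
(`target_length`). Without it, terminal junk columns are nearly free under
fitting alignment (the consensus ends are free), and the de novo mode,
which trims weakly covered ends by a coverage fraction instead, is
documented as less robust on repeat-rich short targets.

The consensus letter per column is the weighted plurality (letters weighted
by posterior quality), ties resolved toward the letter whose observed
normalized conductance best agrees with its model level; coverage is the
raw count of contributing letters; the reported per-position conductance is
the mean over consensus-matching letters, normalized by the fitted guanine
mean, so guanine columns sit at 1.00 and adenine and thymine near
77/102 ≈ 0.755 and 45/102 ≈ 0.441.

A note on a small combinatorial fact discovered while testing: the multiset
of all eighteen length-5 windows of the let-7a 22-mer does not determine
the sequence uniquely — a second 22-mer tiles the same windows with the
same triangular coverage. Single-copy 5-mer tilings are therefore checked
for length, coverage profile and window-multiset preservation rather than
for one specific string; real (multi-copy, mixed-length) fragment sets do
not suffer this degeneracy because longer fragments bridge the repeats.

## Marker counting

For a mixture of two variants differing at a single base, fragments are
placed on the common scaffold allowing a mismatch only at the marker
position; a fragment is counted if it has at least five letters, places
uniquely, and spans the marker. Fragments that place equally well at two
offsets are rejected as ambiguous rather than fractionally counted, and
marker letters matching neither variant are tallied as miscalls and
excluded.

Strict ungapped placement has a subtle asymmetry: a dwell mis-split in a
homopolymer run adjacent to the marker (the let-7a marker G at position 12
sits in a GG pair; the let-7f marker A does not) shifts the read by one
letter, making it unalignable or placing it with its single conflict on
the marker itself. Both effects deplete one variant's counts. Fragments
without a clean marker letter therefore get a second chance through a
fitting-alignment edit-distance classifier against the two full variant
sequences, counted only when one variant fits strictly better within two
edits — only marker-covering reads can discriminate, since the variants
differ nowhere else. A residue of the asymmetry remains at full-pipeline
noise (a read missing one letter of the marker GG pair is *intrinsically*
ambiguous between the variants: deleting either variant's twelfth letter
yields the same string), which shrinks full-noise abundance ratios
slightly toward 1:1 — a shrinkage any counting pipeline with this error
channel will show. On ground-truth path letters (no calling noise) the
counting estimator is unbiased to within 0.02 across charged fractions
0.25/0.5/0.75, which is the property the test suite asserts.

The reported ratio is normalized so the smaller side equals 1.0, with a
seeded bootstrap interval on the first variant's fraction; the mixture
heat map lays the accepted fragments directly on the scaffold and reports
both letters' counts, weights and conductance levels at the marker column.

## Numerical and interface choices

* All stochastic entry points take an explicit integer seed and restore
  the caller's RNG state; identical inputs and seed give bit-identical
  outputs, including the pipeline's JSON summary.
* Positions are 1-based; intervals and segments are half-open.
* Velocities, dwells and intervals are in ms and bases/ms; conductances in
  pS; normalized conductances are unitless fractions of the guanine peak.
* Degenerate inputs fail loudly with classed conditions
  (`tunnelcall_input_error`, `tunnelcall_format_error`,
  `tunnelcall_insufficient_data`, `tunnelcall_fit_error`); the command-line
  wrapper maps these to exit codes 2 and 3.
* Problem sizes in the test suite are chosen to make each check
  statistically decisive at its stated tolerance: 2,000 simulated events
  for peak/velocity recovery (fit tolerances are a few percent with
  standard errors well below them), 2,500 events per variant for exact
  22-base assembly (coverage ≥ 15 at the rim), 200 replicates of 250
  events for the unbiasedness property, and 10,000 events for the
  read-length distribution in the acceptance script.

## Known limitations

* De novo assembly (no `target_length`) of repeat-rich three-letter
  targets from short noisy reads can retain weakly supported terminal
  columns or, in adversarial cases, prefer a content-duplicating chimera;
  the length constraint removes both failure modes and reflects the actual
  experimental situation.
* The full-noise abundance ratio retains a small shrinkage toward 1:1 when
  a marker sits in a homopolymer run (see above); the package reports the
  rescue and rejection tallies so the effect is visible in diagnostics.
* The simulator's noise model is deliberately simple; the thresholds used
  here (6σ/1σ, bin widths, identity floors) are the measurement
  procedure's documented defaults, not re-optimized values, and all are
  exposed in the configuration.
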