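---
title: "Methods: simulating and decoding barcoded nanopore translocations"
author: "oligopore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding barcoded nanopore translocations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligopore)
```

# The measurement being modelled

A solid-state nanopore (12–15 nm diameter) under a 500 mV bias passes a
steady open-pore current $I_0$ (several nA, pore-specific). When a
DNA-carrier nanostructure translocates, it blocks part of the pore and the
current drops by a carrier-dependent amount for the dwell time of the
molecule. The carrier encodes a binary barcode: at five evenly spaced
positions, a group of ~11 DNA dumbbell hairpins either is present (a "1",
adding a secondary downward spike inside the blockade) or absent (a "0",
a flat spacer). A protein oligomer click-coupled to the carrier's overhang
adds one further spike — deeper and at the protein end of the carrier,
outside the bit positions. Monomeric protein (~14 kDa) is below the
size resolution of a pore this large and produces no spike, which is what
makes the read-out oligomer-specific.

The analysis pipeline asks three questions of every recording:

1. *Where are the translocation events?* (detection)
2. *Which sample does each event belong to, and is an oligomer bound?*
   (decoding/classification)
3. *Per sample, what fraction of carriers carry an oligomer, and how big
   are the bound species?* (quantification)

# The synthetic-trace generator

`simulate_trace()` produces traces with complete ground truth so that
detection, decoding and quantification can be validated independently and
end-to-end. What it emulates, per `sim_config()`:

* a Gaussian-noise baseline (`noise_sigma`, default 6 pA, applied as white
  noise before filtering; currents are handled in nA internally, noise is
  configured in pA);
* rectangular carrier blockades with raised-cosine edges
  (`carrier_blockade_depth`, default 0.35 nA; `edge_width`, default 10 µs)
  and log-normal plateau durations (`duration_meanlog/sdlog`, median
  1.5 ms, truncated to `duration_range` so every event can hold its bit
  slots);
* five bit slots in the central $1 - 2 \times \texttt{margin\_frac}$ of
  the event, each "1" rendered as a raised-cosine spike of
  `bit_spike_depth` (default 0.25 nA) and width `bit_spike_frac` of its
  slot;
* an optional oligomer spike centred in the protein-end margin, with
  log-normal depth (median 0.5 nA) and width (median 0.2 ms); its true
  area against the carrier chord is recorded per event as the ground-truth
  ECD;
* random entry orientation (time reversal, probability 0.5), folded-carrier
  contaminants (`fraction_folded`, default 0.7 — matching recordings in
  which only ~30% of carrier events are unfolded and analyzable), rendered
  as a depth doubling over a random 30–70% prefix of the event;
* exponential inter-event gaps at `event_rate`, placed sequentially so
  events can never overlap (a rate incompatible with non-overlap is
  rejected up front rather than silently truncated);
* a 4th-order Butterworth low-pass at `lowpass_cutoff` (default 50 kHz on
  1 MHz sampling).

The per-sample mixture table lists each barcode with its true bound
fraction and relative abundance; the default is the triplex screen
(11111/11101/11011 at bound fractions 0.30/0.42/0.14, abundances
114:43:90). Identical configurations including the seed give bit-identical
traces and truth tables.

**What the generator does not emulate.** No electrophysics: blockade
depths are free parameters, not computed from pore geometry, and no
published value ties them to this pore/buffer combination. Dwell-time
dynamics within an event (speed-up near exit) are absent, so bit spikes
are exactly evenly spaced in time; real carriers are only approximately
so. Baseline wander is limited to what the drift-tracking baseline
estimator sees in tests; 1/f noise, clogging, and inter-event correlation
are absent. Event rates are also ~100× higher than the instrument's
(~0.5 events/s) so that desk-scale traces contain enough events to be
statistically useful; consequences for the baseline estimator are
discussed below. Passing tests therefore demonstrate correctness of the
*analysis* under the stated signal model, not robustness to every
instrumental pathology.

**Choice of low-pass filter.** The recording chain's anti-noise filter is
modelled as a 4th-order digital Butterworth: maximally flat in the
passband, −3 dB at the cutoff, and with the closed-form magnitude response
$|H(f)| = (1 + (\tan(\pi f/f_s)/\tan(\pi f_c/f_s))^{8})^{-1/2}$
that the test suite uses as an independent oracle. The filter is applied
causally with a reflected lead-in referenced to the first sample, which
suppresses the start-up transient exactly for a constant trace.

# Detection

`find_events()` implements thresholded excursion detection with the
standard operating thresholds for this read-out: minimum duration 0.3 ms,
minimum current drop 0.1 nA (`detector_params()`).

* **Baseline.** `estimate_baseline()` computes an upper quantile (default
  the upper quartile) over consecutive windows (default 20001 samples =
  20 ms) and interpolates linearly. Blockades deflect the current only
  downward, so a high quantile remains on the baseline for window
  occupancies up to $1-\texttt{prob}$ — important in compressed synthetic
  traces where Poisson clumping can push a 20 ms window past 50%
  occupancy and would collapse a windowed *median* to the carrier level.
  The price is a systematic bias of $\Phi^{-1}(\texttt{prob})\,\sigma
  \approx 0.67\sigma$ (a few pA), negligible against the 0.1 nA drop
  threshold and the ~6 nA baselines it normalizes.
* **Boundaries.** Event entry/exit are placed at the crossings of
  `threshold_frac × min_drop` (default 50%, a hysteresis band below the
  detection threshold); the event is kept only if the excursion reaches
  the full `min_drop` somewhere and lasts `min_duration`. Sub-threshold
  gaps shorter than a third of the minimum duration are merged so that a
  dumbbell spike cannot split one carrier event into several.
* **Local baseline.** $I_0$ for each event is the median of the running
  baseline over a window preceding the event. Normalized duration is
  duration (ms) divided by $I_0$ (nA); division is used because the
  normalization's purpose is to cancel the proportional effect of pore
  size on both dwell time and current.

Every returned event satisfies both thresholds by construction, and
raising either threshold can only remove events (tested as a monotonicity
property).

# Decoding

`classify_events()` assigns each detected event to `barcode_only`,
`barcode_plus_protein`, `rejected_folded` or `rejected_undecodable`.

* **Folded rejection.** A folded carrier blocks roughly twice the
  single-carrier current over a contiguous stretch. An event is rejected
  when its depth exceeds `folded_depth_factor` (1.6) × the expected
  carrier depth over a contiguous run longer than 15% of the event.
  The *contiguous-run* criterion matters: oligomer spikes
  (carrier + ~0.5 nA) also exceed that depth, but only in narrow bursts,
  and a total-fraction rule was observed to misflag ~5% of bound events,
  biasing the fraction bound low.
* **Spike candidates.** Within an event, the carrier level is the median
  of the interior depth; excursions below it deeper than the bit
  threshold (3× local noise σ, floored at 0.03 nA for near-noiseless
  recordings) and wider than `min_spike_width` become candidates. The
  noise σ is estimated from the trace as the MAD of the residual against
  the running baseline.
* **Bit calling.** The central region of the event (outside a
  `margin_frac` = 0.18 margin at each end) is divided into five equal
  temporal slots; a slot is "1" iff it contains a candidate's peak. The
  event layout uses *symmetric* margins — the carrier's geometric design
  reserves its overhang at one end, but symmetric margins make the slot
  grid invariant under time reversal, so bit calling does not depend on
  knowing the orientation first. Per-bit confidences are
  $\Phi((\text{peak} - \text{threshold})/\sigma)$ for ones and
  $\Phi((\text{threshold} - \text{max excess})/\sigma)$ for zeros,
  monotone in spike-to-noise ratio.
* **Oligomer spike and orientation.** A candidate qualifies as the
  oligomer spike if it lies in an end margin (positional criterion) *and*
  exceeds the oligomer threshold (5× noise σ, floored at 0.05 nA); either
  criterion can be disabled. If several qualify, the largest-area spike
  wins. Its end defines the protein end and hence the reading direction,
  giving exact bit recovery for bound events. Unbound events have no
  protein end; a carrier read backwards gives the reversed bit string, so
  unbound reads are reported as reversal-equivalence classes
  (`canonical_code()`: the lexicographic minimum of the string and its
  reverse; 20 classes exist for 5 bits — 8 palindromes and 12 mirrored
  pairs). The triplex barcodes 11111, 11101 and 11011 are mutually
  distinguishable under reversal, which is what makes the multiplexed
  screen decodable without orientation information.
* **Refusal over guessing.** A spike peak in a margin that does not
  qualify as the oligomer spike, or an event too short to hold the slot
  grid, makes the event `rejected_undecodable` rather than a guessed code.

# Quantification

* **Fraction bound** (per barcode class): bound events over decoded
  events; rejected events appear in neither numerator nor denominator;
  a class with zero decoded events is reported as missing, never as 0.
* **ECD**: trapezoidal integration of chord-minus-current over the spike's
  region of interest, at the native sampling rate, in nA·ms. The region
  bounds are the spike's threshold crossings padded by `spike_pad` = 25
  samples so the chord endpoints rest on the carrier shoulders; with a
  10-sample pad the chord still sat on the spike tail and produced a
  depth-dependent ~3% area deficit. Closed forms (rectangle $d\,w$,
  triangle $d\,w/2$) hold to one sample width.
* **Uncertainty**: the instrument's repeat-based standard deviations are
  an acquisition-level concept; the package replaces them with an
  event-level bootstrap (resampling decoded events with replacement,
  default 1000 replicates, seeded). Classes with fewer than 10 decoded
  events are flagged low-confidence. Per-event ECDs and their per-sample
  median/IQR are both reported, since either may be the quantity of
  interest.
* **Ranking**: samples are ordered by fraction bound ascending (lowest =
  strongest inhibitor of oligomer production); exact ties share a rank
  and are flagged rather than broken arbitrarily; a pairwise difference
  is flagged significant when the bootstrap 95% intervals are disjoint.

# Storage

Traces and event stores are single-file JSON containers with a stamped
schema version and a hierarchical layout (`trace/samples`, `trace/attrs`,
`events/*`, `provenance/*`). Numbers are written with 17 significant
digits, which round-trips IEEE doubles exactly, so stores are bit-exact
across write/read; the provenance records the detector thresholds and
every stored event is validated against them on construction. A
plain-text container keeps stored events inspectable with any JSON tool
and avoids binary-format dependencies.

# Numerical and degenerate-input choices

* Sample indices are 0-based half-open `[start, end)` everywhere.
* Noise-free operation: decoder thresholds derived from a zero noise σ
  are floored (0.03 / 0.05 nA) so noiseless renders decode exactly.
* Empty results are valid: no events detected, no spikes in an event, and
  an empty event store are all well-formed outcomes, not errors.
* Determinism: every stochastic function takes or derives a seed and
  restores the caller's RNG state; pipeline reports embed the seed and an
  analysis-config fingerprint (the output directory is excluded from the
  fingerprint so identical analyses are identical wherever they land).

# Problem sizes used in the checks

The validation suite runs at desk scale: single traces of 60–1000 events
at 1 MHz sampling; the recovery study uses 100 seeded triplex replicates
of 247 events each (per-class decoded counts ≈ 114/43/90, the scale of a
one-hour acquisition per sample), with folded-carrier generation switched
off there because folding rejection is exercised by its own
binomial-recovery test; ECD recovery uses 1000 bound events; duration
recovery uses 1000 events compared by a two-sample Kolmogorov–Smirnov
test against the injected durations.

# Known limitations

* Blockade and spike amplitudes are free parameters; absolute calibration
  to a specific pore/buffer is out of scope, as is any conversion of ECD
  to oligomer mass or monomer-equivalent concentration.
* Slot-based bit calling assumes approximately uniform translocation
  speed within an event; strong intra-event speed-up would smear bit
  positions across slots and surface as undecodable events.
* With per-class event counts of ~43 (the smallest sample in the triplex
  conditions), the binomial noise of the fraction-bound estimate is the
  dominant uncertainty: even an error-free classifier recovers the full
  three-way inhibition ordering in only ~92% of replicates at those
  counts. More events per class, not a better decoder, is the remedy.
* The event-level bootstrap quantifies counting uncertainty only; it
  cannot see acquisition-level variability (pore-to-pore differences,
  drift between repeats).
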