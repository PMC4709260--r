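---
title: "Scoring conditioned darting: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring conditioned darting: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartscore)
```

# The scientific problem

In auditory fear conditioning, a tone (CS, 30 s) co-terminates with a brief
footshock (US, 0.5 s) on the later trials of day 1 (5 habituation tones, then
7 tone–shock pairings), followed by extinction (20 tones, day 2) and an
extinction test (3 tones, day 3). The canonical conditioned response is
freezing, but a subset of animals — mostly females — instead emit *darts*:
brief, high-velocity runs across the chamber, time-locked to tone onset and
to the shock. Scoring only freezing misclassifies these animals as
non-learners.

`dartscore` operationalizes darting from the tracked velocity signal
(nominally 3.75 Hz, cm/s): a dart is a velocity peak of at least
**23.5 cm/s**, with successive peaks at least **0.8 s** apart. Darts are
registered to four analysis epochs per session — a single 60-s **pre-CS**
window ending at the first tone, the 30-s **CS**, the 5-s **shock response**
window from US onset, and the following 30-s **post-shock** window — and
summarized as darts/min. An animal is a **Darter** if it darts at least once
during the CS of conditioning trials 8–12 (the 3rd–7th pairing, when
conditioned responding is established); earlier darts, and darts in other
epochs, do not qualify.

# Detection conventions

The velocity series is sampled, so "peak" needs a convention. We use:

- a sample is a local maximum when strictly greater than the nearest
  *differing* values on both sides; a plateau of equal values counts once,
  at its first sample;
- the first and last samples are never peaks (no two-sided neighborhood);
- the interpeak rule is enforced greedily in descending peak height, ties
  broken by earlier time: a candidate is dropped if it is *closer than*
  0.8 s to an already retained peak (exactly 0.8 s is allowed).

The greedy descending-height filter is the behavior of the common
`findpeaks`-style minimum-peak-distance option and is declared canonical
here; the test suite pins it against an independent re-derivation (repeated
global-maximum extraction). Note the greedy policy does not always retain the
*largest possible number* of spacing-feasible peaks (three close peaks of
heights 30/40/30 at 0.5-s gaps keep only the 40), which is a property of the
canonical method, not a bug. No minimum dart duration or prominence is
imposed beyond the two stated criteria.

Freezing is scored from the same velocity trace as maximal runs below
**2.0 cm/s** lasting at least **2 s**. The immobility threshold is this
package's convention — the original behavioral literature typically scores
freezing with pixel-change software — so absolute freezing percentages are
comparable *within* analyses using this scorer, not across scoring methods.
Because the dart threshold far exceeds the immobility threshold, no dart can
fall inside a freezing bout (an invariant the tests verify).

# Epochs, rates and histograms

All windows are half-open `[start, end)`: an event exactly on a boundary
belongs to the later window. The shock-response window is anchored at US
onset (CS offset − 0.5 s), so it overlaps the final 0.5 s of the tone; event
assignment gives shock-response precedence there, which keeps the four
analysis epochs effectively disjoint. The alternative anchor (CS offset) was
considered and rejected because the shock-evoked burst begins at shock
onset. Pre-CS is session-level (one 60-s window before the first tone), not
per-trial. Darts between trials are labeled `iti` (or `acclimation`) and are
excluded from the four headline epochs but still count toward the session's
total dart count.

Rates are count / window-minutes (2 darts in a 30-s CS = 4 darts/min; the
full 30-s tone is the denominator even though its last 0.5 s is claimed by
the shock window). Peri-CS histograms re-time darts relative to each trial's
tone onset and bin them at 4 s; bin edges are anchored at onset (a bin
always starts at 0 s) and the requested span is widened outward to whole
bins, so the default −30 to +70 s view yields 26 bins from −32 to +72 s.
Cohort histograms are element-wise means across animals.

"Mean shock response velocity" is the across-US-trials mean of each trial's
*mean* velocity within its 5-s window; the mean of per-trial *maxima* is
available via `shock_summary = "max"` since the choice is not forced by the
quantity's name and both are defensible.

# The synthetic cohort

No public raw traces exist for this paradigm, so the package ships a
generative stand-in with planted ground truth. Each animal-session is built
in three layers:

1. **Background locomotion** — a two-state freeze/move semi-Markov process
   with exponential dwell times (defaults: mean 8 s frozen, 12 s moving).
   Moving-state speeds are log-normal with mean 4 cm/s and SD 1.2 cm/s
   (coefficient of variation 0.3, which puts the probability of a baseline
   sample crossing the 23.5 cm/s dart threshold below 10⁻⁹); frozen-state
   samples are small jitter clamped below the freezing threshold.
2. **Darts** — an inhomogeneous Poisson process: the baseline rate
   everywhere, the per-trial CS rate inside tone windows, and the post-shock
   rate inside post-shock windows. Candidate times are thinned to a minimum
   separation of 0.8 s *plus one sample period* before being snapped to the
   sample grid (snapping moves a time by at most half a period, so grid
   spacing can never fall below the detector's rule). Each dart is rendered
   as a Gaussian-shaped pulse of full width 0.5 s whose peak is drawn from
   N(35, 4) cm/s floored at 25 cm/s, combined with the background by
   pointwise maximum — every planted event is therefore a strict local
   maximum at or above threshold, and detector precision/recall can be
   scored exactly.
3. **Shock bursts** — one guaranteed pulse per US trial inside the 5-s shock
   window, peak N(55, 8) cm/s floored at 25 (both sexes dart in response to
   the shock itself). Bursts are planted events too, and random darts yield
   to them during thinning.

Default phenotypes cross sex with Darter status. Darters ramp their CS dart
rate across the pairings (1, 2, 4, 4.5, 5, 5.5, 6 darts/min on trials 6–12,
non-decreasing by construction) and dart at 3 darts/min post-shock;
non-darters stay at baseline. Tone-alone sessions (extinction, test) reuse
the terminal conditioning CS rate, a deliberate simplification — real
darting extinguishes across tone-alone trials.

Two generator choices deserve emphasis:

- **The baseline (non-CS) dart rate defaults to 0.002 darts/min** — i.e.
  spontaneous darting is essentially absent and darting is CS/shock-locked.
  This makes the planted phenotype recoverable by the Darter criterion
  (a non-darter with a realistic spontaneous rate of ~0.1 darts/min would
  have a >20% chance of one chance dart in the 2.5 min of CS 8–12 time and
  the criterion would "discover" it, by design). Real animals do dart
  spontaneously at low rates during habituation; the simulator trades that
  feature for a clean ground truth.
- **Rates are slightly sub-Poisson at high intensity** because of the
  refractory thinning; at the default rates the departure is far below
  Monte-Carlo noise (the rate-fidelity test checks 1,000 tone windows at
  1 dart/min).

Because of these simplifications, passing tests demonstrate that the
*pipeline* is correct (detection, registration, classification, statistics),
not that the simulator reproduces real rat behavior: the published
group-level F statistics and correlations are not recoverable from synthetic
data and are not claimed.

Seeding: every animal-session seed derives from the master seed by a fixed
arithmetic counter over (sex, animal index, session), so any animal's traces
are identical whatever the cohort size — cohorts are reproducible under
subsetting, and a manifest seed suffices to replay a whole pipeline run
byte-identically.

# Classification and exclusion

`classify_darter()` applies the CS 8–12 criterion literally: only events
labeled `cs` with trial index 8–12 qualify; shock-response darts on those
same trials do not. Outlier exclusion flags animals whose conditioning total
dart count exceeds the stratum mean by more than 6 SD, with mean and SD
computed *including* the candidate and the stratum defaulting to within-sex
(the study described its excluded male relative to "the mean" without
stating a stratum; whole-cohort is available by argument). A consequence of
the inclusive convention worth knowing: a single outlier among n animals can
sit at most (n−1)/√n SDs from the mean, so the 6-SD rule cannot fire in
strata smaller than ~38 animals no matter how extreme the count.

# The statistical battery

- **Chi-square** (sex × Darter): uncorrected Pearson statistic,
  df = (r−1)(c−1). No continuity correction — on the study's 24/34 vs 6/50
  table the uncorrected statistic reproduces the published 13.8 (Yates'
  correction would give ≈ 12.3).
- **Mann-Whitney U** (all pre-CS comparisons): midrank ties; the reported
  statistic is the smaller U orientation; p is exact (null U distribution)
  when the smaller sample has ≤ 8 observations and there are no ties,
  otherwise a normal approximation with tie-corrected variance, two-sided,
  without continuity correction.
- **Pearson correlation** (mean shock-response velocity vs total session
  dart count): the usual t test on n−2 df. The outlier-exclusion switch
  controls whether the flagged animal enters, mirroring the study's
  "included vs removed" contrast.
- **Mixed-design ANOVA** (group × trial, subjects nested in group): the
  classical split-plot decomposition. Between-subject SS splits into group
  and subject-within-group (error for group); within-subject SS into trial,
  group × trial and trial × subject-within-group (error for both within
  effects). The decomposition uses observation-weighted means, which is
  exactly orthogonal (total SS is conserved to machine precision, a tested
  invariant) and coincides with the Type III analysis for balanced groups;
  it also matches `aov()` with an `Error(subject)` stratum, the reference
  the tests compare against. A Greenhouse-Geisser epsilon is computed from
  the pooled within-group covariance and reported but not applied, matching
  the convention of reporting uncorrected integer df.
- **Sidak post-hoc** per-trial two-group comparisons: denominator is the
  within-subject error mean square (trial × subject-within-group), per-test
  level 1 − (1 − α)^(1/m) (≈ 0.00256 for m = 20 at α = 0.05); both raw and
  adjusted decisions are reported. Using the within error term alone is a
  declared convention; a combined between+within error (Winer) would widen
  the intervals slightly and is not currently exposed.

# Degenerate inputs and numerical tolerances

- Trace loading requires uniform sampling within a relative tolerance of
  1e-3 of the sample period; gaps of ≤ 2 consecutive samples (missing rows
  or NA velocities) are linearly interpolated, longer gaps are an error.
  This missing-data rule is the package's own — tracker software chains do
  not document theirs.
- Zero-SD outlier strata exclude nobody; `k = Inf` disables exclusion;
  strata need ≥ 3 animals.
- Single-sex cohorts cannot form the sex × Darter table (error); the
  pipeline's statistics report degrades gracefully (a "skipped" row with the
  reason) when a Darter group is empty or a variance is zero, e.g. under an
  extreme detection threshold.
- Schedules validate ordering, 2–6-min onset gaps, non-overlap through the
  post-shock windows, and the conditioning US pattern (trials 6–12).

# Problem sizes

The shipped checks run at sizes chosen to give tight Monte-Carlo error while
staying quick on a laptop: detector exactness on 100 simulated conditioning
sessions; oracle agreement on 500 random traces of up to 2,000 samples;
classification recovery on a 500-per-sex cohort at the study's Darter
proportions (0.414 female, 0.107 male), where 3 binomial SEs are ±0.066 and
±0.041; and 5,000 null replicates per test for type-I calibration (binomial
SE ≈ 0.003 at α = 0.05).

# Known limitations

- Velocity-only: no positions, postures or rearing; freezing from velocity
  is not pixel-change freezing.
- The simulator's phenotypes are stylized (no extinction of darting, no
  estrous-cycle structure, near-zero spontaneous darting); estrous phase is
  carried as optional metadata only.
- The published real-data F values, group curves and r = 0.34 correlation
  depend on the original cohort's raw traces, which are not public; this
  package reproduces the *methods* and the cohort-level chi-square, and
  validates everything else against planted ground truth.
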