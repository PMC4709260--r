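# dartscore

Detection, classification and statistics for **darting** — a rapid,
high-velocity escape-like response some rats show during auditory fear
conditioning, in place of (or alongside) freezing. Darting is far more
common in females than in males, so scoring it matters for any
fear-conditioning study that includes both sexes: an animal scored only for
freezing looks like a non-learner when it is in fact expressing an active
conditioned response.

The package is written for behavioral neuroscientists who have per-animal
locomotor **velocity traces** (e.g. exported from video tracking at 3.75 Hz)
and a **session schedule** (tone onsets, shock placement). It provides:

- **Event detection.** A dart is a local maximum of the velocity series with
  peak ≥ 23.5 cm/s, with retained peaks at least 0.8 s apart (greedy
  descending-height spacing filter — the classic `findpeaks` minimum-peak-
  distance behavior). Freezing is scored as sub-threshold immobility runs of
  ≥ 2 s.
- **Trial-epoch registration.** Each session is partitioned into the four
  analysis epochs — 60-s pre-CS, 30-s CS (tone), 5-s shock response (from US
  onset), 30-s post-shock — and every dart is assigned to its epoch, with
  darts/min computed per window (plus peri-CS histograms in 4-s bins).
- **Phenotype classification.** An animal is a **Darter** if it shows at
  least one CS dart on conditioning trials 8–12; animals whose total dart
  count exceeds the stratum mean by more than 6 SD are flagged as outliers.
- **Statistics.** Uncorrected Pearson chi-square (sex × Darter), Mann-Whitney
  U with midrank ties and an exact small-sample branch, Pearson correlation,
  classical two-way mixed-design (group × trial) ANOVA, and Sidak post-hoc
  per-trial comparisons at level `1 − (1 − α)^(1/m)`.
- **A synthetic-cohort simulator.** Seeded generative model (freeze/move
  semi-Markov background, inhomogeneous-Poisson darts, guaranteed shock
  bursts) that plants ground-truth events, so the whole pipeline is testable
  end to end without raw tracking data.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods and
ggplot2 helpers (`plot_trace()`, `autoplot()` on peri-CS histograms).

## Worked example

Simulate one female Darter's conditioning session, detect and register her
darts, and classify her:

```r
library(dartscore)

sched  <- build_schedule("conditioning", seed = 1)   # 5 habituation + 7 CS-US trials
sim    <- simulate_animal(default_phenotypes()$female_darter, sched, seed = 7)
events <- assign_events(detect_darts(sim$trace), build_epochs(sched))

dplyr::count(events, epoch)
#>   epoch              n
#> 1 cs                11
#> 2 post_shock        12
#> 3 shock_response     7

metrics <- compute_metrics(events, score_freezing(sim$trace), sim$trace,
                           build_epochs(sched))
glance(metrics)
#>   pre_cs_dart_rate total_dart_count mean_shock_response_velocity
#> 1                0               30                         5.36

classify_darter(events)
#> [1] TRUE
```

She darted 30 times in the session — 11 during tones, 7 in shock-response
windows, 12 post-shock, none before the first tone — and qualifies as a
Darter (CS darts on trials 8–12). At the cohort level, the sex-by-Darter
contingency table of the original study (24/58 females, 6/56 males) gives:

```r
chi_square_independence(matrix(c(24, 6, 34, 50), 2))
#> chi_square_independence: statistic = 13.82, df = 1, p = 0.0002015
```

i.e. the published chi-square = 13.8, p = 0.0002 association between sex and
darting. `run_darting_pipeline(darting_config(), "out/")` runs the full
simulate → detect → analyze → classify → stats chain and writes every
artifact (event/bout CSVs, metrics, cohort table, statistics report,
manifest) reproducibly.

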