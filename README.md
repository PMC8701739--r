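# adlsense

Smart-home sensor analytics for early-dementia screening from activities of
daily living (ADL).

Elderly people living alone can be monitored passively by ambient IoT
sensors — door contacts, motion sensors, vibration/tilt sensors on
appliances and faucets, temperature–humidity probes, smart plugs, and a 2-D
lidar tracking position. Instrumental ADLs (cooking, medications, grooming,
appliance use, outings, chores, indoor wandering) decline early in
dementia, so features derived from these streams can separate normal
controls from early-stage dementia. `adlsense` implements the full analysis
pipeline for researchers in digital phenotyping and remote health
monitoring:

* **Event preprocessing** — per-sensor conversions (tilt deviate/restore →
  use episodes, plug power → on-intervals, temperature rises, motion bouts,
  door openings) and time-binned count/duration series on 10-minute,
  hourly, or daily half-open bins; lidar kinematics (movement distance,
  gait speed in km/h with a 0.6 km/h floor) and six-zone visit analysis.
* **Rule-based ADL inference** — cooking requires two or more kitchen
  appliances plus a gas-stove temperature rise in a rolling 30-minute
  cluster (microwave without stove = heating food); outings are door
  toggles bracketed by interior silence, with "no lock" flagged when a
  plug stays powered throughout; plus medications, grooming, chores,
  appliance sessions and late-night wandering metrics.
* **A 195-column person-hour feature table** on the packaged reference
  household: 65 channel counts + 65 channel durations + 2 lidar features
  (132 IoT) and 31 ADL durations + 32 ADL counts (63 ADL).
* **MMSE-stratified IQR personalization** — per-person, per-feature bounds
  `Q1 − k·IQR` / `Q3 + k·IQR` with `k` = 1.5 / 1.2 / 1.0 / 0.5 for MMSE
  30 / 27–29 / 24–26 / ≤23, computed causally from each person's prior
  days; anomaly indicators and within-day counts become extra features.
* **Statistics** — Shapiro–Wilk screening, Wilcoxon rank-sum comparison
  (exact at small n), Spearman rank correlation
  `r = 1 − 6Σd²/(n(n²−1))` and per-group appliance correlation matrices.
* **Classification** — 10-fold stratified cross-validated random forest
  over {IoT, ADL, IoT+ADL} × {raw, personalized}, pooled
  precision/recall/F1/accuracy from summed confusion counts, and sampling
  Shapley feature attribution.
* **A synthetic smart-home cohort generator** — persona-driven event
  streams for a configurable cohort (default 7 normal + 6 dementia, group
  gait means 1.023 vs 1.2091 km/h, lower appliance coherence and higher
  night activity in the dementia group) so the whole pipeline runs with no
  access to clinical data.

## Worked example

```r
library(adlsense)

co   <- generate_cohort(cohort_config(7, 6, days = 14), seed = 1)
cf   <- cohort_features(co)            # 4,368 person-hours x 195 features
pers <- personalize_features(cf$features, co$profiles)

raw  <- rf_crossval(cf$features[, cf$schema$all], cf$features$label,
                    folds = 10, seed = 2, num_trees = 150)
per  <- rf_crossval(pers[, setdiff(names(pers), c("person_id", "bin_start", "label"))],
                    pers$label, folds = 10, seed = 3, num_trees = 150)
round(100 * raw$metrics, 2)
#> precision    recall        f1  accuracy
#>     77.87     57.79     66.34     72.94
round(100 * per$metrics, 2)
#> precision    recall        f1  accuracy
#>     96.60     92.91     94.72     95.22
```

On this synthetic cohort the personalized IoT+ADL model beats the raw one
by ~22 accuracy points: the dementia group's narrow IQR bounds (k = 0.5)
generate systematically more anomaly flags, which the forest exploits —
the mechanism the personalization design is built on. `spearman_r(1:5,
c(2, 1, 4, 3, 5))` returns `0.8` (Σd² = 4, 1 − 24/120), and
`classification_metrics(9, 1, 3, 7)` returns precision 0.9, recall 0.75,
F1 0.818, accuracy 0.8.

A full run — simulate → preprocess → infer → featurize → personalize →
stats → evaluate — is one call, writing CSV artifacts plus a manifest;
repeated runs with one config are byte-identical:

```r
run_all(default_run_config(), out_dir = "adlsense_run")
```

A thin CLI wrapper lives at `inst/cli/adlsense.R`
(`Rscript adlsense.R run-all --seed 1 --out DIR`).

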