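# egohand

Feature-based detection of **hand-object interactions** and classification
of **hand roles** (manipulator vs stabilizer) from egocentric video of
stroke survivors, with the subject-level evaluation protocol and
inter-rater agreement statistics that go with it.

## Who this is for

Rehabilitation-technology researchers who have egocentric (head-mounted
camera) recordings of daily activities, per-frame hand bounding boxes and
segmentation masks from upstream detectors, and who want frame-level,
per-hand measures of hand use at home: *is this hand manipulating an
object?* and, during bimanual activities, *is it the manipulator or the
stabilizer?* Because such recordings are private, the package also ships a
synthetic egocentric-scene generator that produces multi-participant
cohorts with exact ground truth, used by the tests and the analysis
scripts.

## The method

An *instance* is one hand in one frame. Its bounding box partitions the
frame into hand, non-hand (rest of the box) and background regions, and
the instance descriptor concatenates:

- **colour**: signed bin-wise differences of 16-bin L1-normalized HSV
  histograms over the three region pairs (144 values);
- **motion**: dense optical-flow magnitude and direction histograms
  (16 bins each), differenced over the same pairs (96 values);
- **shape**: a HOG of the box crop (64x64, 8x8 cells, 2x2 blocks, 9
  unsigned bins; 1764 values);
- **hand-size change** (role task only): mask-area differences over the
  ten subsequent frames, normalized by box area (10 values).

Each task uses a binary random forest with 150 trees; the hand-role task
counteracts its ~20/80 manipulation/stabilization imbalance with a class
weight of 20 on the minority class. Decisions follow three rules: multiple
predictions for one hand are averaged with an inclusive 0.5 threshold
(mean &ge; 0.5 is positive); a hand with no bounding box is no interaction
and no role; overlapping-window predictions (for windowed model variants)
combine by logical OR.

Evaluation is leave-one-subject-out cross-validation: all home tasks of
one participant held out per fold, a validation slot of one bimanual home
task per remaining participant, two training conditions (home only / home
plus laboratory supplement). Metrics are MCC, F1, precision, recall and
accuracy, reported as macro averages (mean ± SD across held-out
participants) and micro averages (pooled counts), stratified by the more-
and less-affected hand. Annotation reliability uses Cohen's &kappa; and
PABAK = 2p&#8325;&#8338; − 1 with the usual interpretation bands
(0.61–0.8 substantial, 0.81–1 almost perfect).

The scientific rationale, parameter choices, generator design and
limitations are documented in `vignettes/methods.Rmd`.

## Worked example

```r
library(egohand)

spec <- cohort_spec(n_participants = 4, tasks_per_participant = 3,
                    frames_per_task = 60, seed = 42)
ds <- generate_cohort(spec)
ds$realized
#> $interaction_fraction
#> [1] 0.7
#>
#> $manipulation_fraction
#> [1] 0.202381

fe  <- featurize_dataset(ds)
res <- run_experiment(ds, features = fe, targets = "interaction",
                      conditions = "home_only", seed = 42)
subset(res, stratum == "overall",
       select = c(average_type, M, F, P, R, A))
#>   average_type      M      F P      R      A
#> 5        macro 0.9904 0.9947 1 0.9896 0.9951
#> 6        micro 0.9903 0.9948 1 0.9896 0.9951
```

The realized fractions confirm the generator hit its class priors (0.7
interaction within interaction tasks, 0.2 manipulation among bimanual
interaction frames). The experiment rows say that on this small
high-contrast synthetic cohort, interaction detection on held-out
participants is near ceiling — frame-level MCC ≈ 0.99 — whether
participants are averaged equally (macro) or frames are pooled (micro);
real home video sits far below this synthetic ceiling.

Agreement statistics work on any two aligned binary annotation tracks:

```r
rate_agreement(c(1,1,0,0,1,0,1,1,0,1), c(1,1,0,1,1,0,1,0,0,1))
#>    N p_o kappa PABAK kappa_band pabak_band
#> 1 10 0.8 0.583   0.6   moderate   moderate
```

## Analysis workflow

`analysis/` holds numbered drivers that run the study end to end at desk
scale and leave their tables under `results/`:

1. `01_generate_cohort.R` — synthetic home + homelab cohorts; writes the
   on-disk dataset and a cohort summary.
2. `02_extract_features.R` — instance descriptors for every task, persisted
   as CSV.
3. `03_evaluate_interaction.R` — LOSOCV interaction detection in both
   training conditions plus a shuffled-label chance control.
4. `04_evaluate_roles.R` — hand-role classification with and without the
   weighted loss.
5. `05_agreement.R` — &kappa;/PABAK on a simulated double annotation.

Run them from the repository root: `Rscript analysis/01_generate_cohort.R`,
etc.

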