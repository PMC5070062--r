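# jagaze

Joint attention (JA) — coordinating visual attention with a partner toward
an object — is an early-developing social skill whose disruption is among
the earliest markers of autism spectrum disorder (ASD). Screen-based
eye tracking makes both of its dimensions measurable in toddlers:
*responding* to JA (following a model's gaze cue toward an object) and
*initiating* JA (alternating gaze between an object and the model's face).

`jagaze` is an R package for analysing such studies end to end, built for
researchers comparing an ASD group with typically developing (TD)
controls across three video tasks (responding JA; initiating JA with a
predictable moving object; initiating JA with an unexpected crossing
object). It takes 120 Hz binocular gaze logs and produces the full
analysis:

* **Events** — dispersion-based (I-DT) fixation detection with a 60 ms
  duration threshold and 1.0° dispersion ceiling, AOI labelling
  (face / target object / non-target object), and AOI-to-AOI transition
  extraction with off-AOI fixations transparent.
* **Trials** — segmentation into looking-down / interaction / JA phases
  and the two standard exclusion criteria (no face look during the
  interaction; whole JA phase off-screen).
* **Measures** — per participant and task: first-look counts, normalized
  accuracy `(n_t − n_nt)/(n_t + n_nt)`, per-trial transition rates,
  normalized transition scores `(a − b)/(a + b)` on the task-appropriate
  transition pair, and fixation-duration percentages (FD%), overall and
  conditional on a congruent first look.
* **Statistics** — ANCOVA `dv ~ group + covariate` (nonverbal
  developmental score as covariate) with a Shapiro–Wilk gate to a rank
  (Conover–Iman) ANCOVA, partial η², Levene's test, Benjamini–Hochberg
  FDR at q = 0.05 per task family, distribution-gated correlations, and a
  repeated-measures ANOVA on usable-trial counts.
* **Simulation** — a semi-Markov gaze generator (log-normal dwells,
  embedded Markov chain over AOIs, Gaussian sample jitter, blinks,
  off-screen gaps, trial attrition) with presets calibrated in closed
  form to published group-level transition rates, so the entire pipeline
  is testable with no recordings.

## Worked example

Simulate a small two-group study from the calibrated presets, run the
pipeline, and compare the groups:

```r
library(jagaze)
library(dplyr)

cfg <- load_task_config()                    # packaged 3-task layout
res <- run_study(list(simulate = list(n_asd = 17, n_td = 15), seed = 42))

res$usable$by_group
#> # A tibble: 2 × 4
#>   group mean_usable sd_usable     n
#>   <chr>       <dbl>     <dbl> <int>
#> 1 ASD          10.7     0.920    17
#> 2 TD           11.3     0.961    15

res$comparisons |>
  filter(task == "IJA2") |>
  select(variable, mean_ASD, mean_TD, F, p, eta2_partial, ranked, fdr_significant)
#>                   variable mean_ASD mean_TD     F        p eta2_partial ranked fdr_significant
#> 1            t_target_face     3.55    1.63 55.94 3.04e-08        0.659   TRUE            TRUE
#> 2            t_face_target     3.76    1.42 45.24 2.22e-07        0.609   TRUE            TRUE
#> 3              fd_pct_face    51.29   46.57  6.92 1.35e-02        0.193  FALSE            TRUE
#> 4            fd_pct_target    48.71   53.43  6.92 1.35e-02        0.193  FALSE            TRUE
#> 5 fd_pct_face_first_target    51.29   46.57  6.92 1.35e-02        0.193  FALSE            TRUE
```

Read: the simulated ASD group alternates between the unexpected object
and the face more than twice as often per trial as the TD group (3.6 vs
1.6 target→face transitions per trial) and spends a somewhat larger share
of its JA-phase fixation time on the face — the calibrated group
contrast, recovered from raw 120 Hz samples by the full event pipeline
and flagged significant after FDR correction (the skewed transition
counts go through the rank ANCOVA, the near-normal FD% through the
parametric one). In IJA-2 the conditional face FD% equals the
unconditional one because the single-object task makes every first
object look congruent. Mean usable trials (10.7 of 12 ASD, 11.3 TD)
reflect the preset attrition rates (0.1 / 0.075 per trial).

`plot_fd_summary(res$measures)` draws the FD% group summary;
`autoplot(res$comparisons)` shows effect sizes against the conventional
η² bands. `run_study(..., out_dir = "report/")` writes the CSV report
bundle (documented in `inst/extdata/data_dictionary.md`) plus a JSON
manifest. A thin command-line wrapper is included:

```sh
Rscript inst/cli/jagaze.R simulate --group ASD --n 17 --seed 42 --out sim/
Rscript inst/cli/jagaze.R analyze --config study.json --out report/
```

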