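# squathmm

Computerized diagnosis of movement-control changes in the barbell back
squat. Given 2D marker trajectories (barbell, hip, knee, ankle; centimetres,
30 frames/s) tracked from sagittal-plane video, `squathmm` detects whether
added load (e.g. 50 % or 75 % of body weight) changed a lifter's movement
pattern relative to their own unloaded repetitions. It is aimed at
biomechanics and strength-and-conditioning researchers who already have
marker tracking output and want a reproducible, per-subject change
detector.

## Method

Two layers answer two questions per subject, marker and load pair:

1. **Did the displacement change?** A one-way fixed-effects ANOVA (with
   Tukey HSD post hoc) compares the repetitions' maximum ascent-phase
   displacements
   `d = sqrt((x_f - x_i)^2 + (y_f - y_i)^2)`
   across the two loads, at α = 0.05. Only significant cases proceed.
2. **Is the pattern separable, and how complex a model does it take?**
   Ascent-phase coordinates are vector-quantized by K-means into M = 20
   symbols (one codebook shared by both conditions), and a discrete hidden
   Markov model λ = {A, B, π} with a linear (left-right) topology — each
   state transitions only to itself or its successor — is trained per load
   by multi-sequence Baum–Welch. Executions are attributed to the condition
   whose model gives the larger forward-algorithm log-likelihood P(O|λ).
   The pipeline reports the minimum number of hidden states N at which
   every repetition of both conditions is attributed to its own condition
   (searched ascending, default 2–50).

Supporting modules: a long-format CSV interchange for trajectory datasets,
displacement kinematics and cohort summaries, interrater agreement
(percent agreement and Cohen's kappa with a null-hypothesis p-value) for
comparing model verdicts with human evaluators, and a synthetic squat
generator with known ground truth for testing everything without raw
video. The methods vignette
(`vignettes/squathmm-methods.Rmd`) documents the model, its assumptions,
and the protocol choices.

## Worked example

```r
library(squathmm)

p <- generator_params(n_subjects = 3, seed = 5,
                      load_effect = list("0" = c(0, 0), "50" = c(2, 1),
                                         "75" = c(4, 2)))
g <- generate_cohort(p)           # 27 executions, known ground truth
res <- run_pipeline(g$dataset, markers = "hip",
                    load_pairs = list(c(0, 75)), N_range = 2:10, seed = 1)
summary(res)
```

```
<pipeline_result> 3 cases (3 gated by ANOVA at alpha = 0.05)
  subject marker pair   anova_p gated min_states identification_rate
1     S01    hip 0-75 0.0031150  TRUE          2                   1
2     S02    hip 0-75 0.0015285  TRUE          2                   1
3     S03    hip 0-75 0.0003053  TRUE          2                   1
```

Reading: for every synthetic subject, the 4 cm vertical-amplitude load
effect (over 0.5 cm tracking noise) was flagged by the displacement ANOVA
(`anova_p` < 0.05), and a two-state left-right HMM per condition was
already enough to attribute all six repetitions to their own load
(`identification_rate` = 1 at `min_states` = 2). Unloaded and loaded
movement patterns are cleanly separable for these subjects.

The same run from a shell:

```sh
squat-hmm simulate --config sim.yaml --out cohort.csv --truth truth.csv
squat-hmm detect cohort.csv --markers hip --pairs 0:75 --n-range 2:10 \
          --seed 1 --out report.json
```

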