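Package: squathmm
Title: Hidden Markov Model Detection of Load-Induced Changes in Back-Squat Movement Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for diagnosing movement-control changes in the barbell back
    squat from 2D marker trajectories. Discrete hidden Markov models with a
    linear (left-right) topology are trained on a lifter's own unloaded
    repetitions and used to classify loaded repetitions by forward-algorithm
    likelihood, searching for the minimum number of hidden states at which
    baseline and loaded executions are perfectly separated. Includes the
    supporting kinematics (Euclidean and vertical displacement, ascent-phase
    extraction, maximum-displacement summaries), per-subject one-way ANOVA
    gating with Tukey post hoc tests, interrater agreement statistics
    (percent agreement, Cohen's kappa), K-means vector quantization of
    trajectories, a long-format CSV trajectory interchange, and a synthetic
    squat-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
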