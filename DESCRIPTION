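Package: herpipe
Title: Heartbeat-Evoked Response Analysis with Cluster Permutation and Surrogate Controls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for heartbeat-evoked responses (HERs) in
    multichannel neurophysiological recordings (MEG/EEG) with simultaneous
    ECG. Provides a synthetic session generator with planted ground truth,
    ECG R- and T-peak detection by sliding template correlation, cardiac and
    blink artifact-component selection rules (pairwise phase consistency
    with the ECG, EOG correlation), pupil preprocessing, heartbeat
    eligibility rules and T-peak-locked epoch averaging, a spatio-temporal
    cluster-based permutation test on arbitrary sensor graphs, a
    surrogate-heartbeat control that reassigns heartbeat timings across
    trials, iterative rating stratification for confound equating,
    trial-level general linear models, and BIC/JZS Bayes factors with
    Jeffreys-style evidence labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, graphics, tools, signal, jsonlite
Suggests: testthat (>= 3.0.0), igraph, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'filters.R'
    'layout.R'
    'synthgen.R'
    'session-io.R'
    'cardiac.R'
    'clean.R'
    'epochs.R'
    'clusterstat.R'
    'resample.R'
    'inferstats.R'
    'pipeline.R'
    'herpipe-package.R'
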