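Package: fitime
Title: Fixed-Interval Timing Analysis of Behavior and Striatal Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing 12-s fixed-interval operant timing
    experiments with pharmacological inactivation and optogenetic
    stimulation conditions: curvature of time-response histograms
    computed from cumulative response records, single-trial start-time
    detection by change-point search, waveform-based classification of
    striatal units into medium spiny neurons and fast-spiking
    interneurons, per-neuron time-ramping regression of firing rate,
    peri-event time histogram matrices sorted by principal components,
    and trial-level linear mixed-effects models of response times and
    firing rates. Includes a fully seeded synthetic-session generator
    that emulates the behavioural and spike-train structure the
    analyses assume, so the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    lmerTest,
    car,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'fitime-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'behavior.R'
    'ephys.R'
    'simConfig.R'
    'simulate.R'
    'io.R'
    'mixedstats.R'
    'pipeline.R'
    'utils.R'
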