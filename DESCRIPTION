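Package: RevLearnEEG
Title: Instructed Probabilistic Reversal Learning: Task Simulation, Bayesian
    HMM Agents, Model Fitting and ERP Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates instructed probabilistic reversal-learning experiments
    (block schedules, probabilistic feedback, rule reversals), implements
    Bayesian hidden-Markov observers with entropy-aversion switching in
    instruction-blind and instruction-sensitive variants together with a
    model-free Rescorla-Wagner learner, fits the entropy-aversion parameter
    per subject by grid search with a lapse likelihood and compares models by
    BIC, computes the behavioural measures of such studies (phase-wise
    accuracy, trials-to-repetition, switch probability after surprising
    negative feedback, paired tests and effect sizes), and quantifies
    event-related potentials (FRN base-to-peak with window widening, SPN
    window means with laterality, P3, P1, N1) on epoched EEG, including a
    synthetic ERP generator with closed-form component templates for oracle
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
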