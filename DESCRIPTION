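Package: ratseize
Title: Rodent EEG Seizure Quantification and Outcome Statistics for
    Organophosphate Status Epilepticus Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing cortical electroencephalography (EEG) from
    rodent models of organophosphate-induced status epilepticus. Provides
    gamma-band (20-70 Hz) power quantification in fixed epochs, rule-based
    detection of epileptiform spikes, status epilepticus onset, and
    spontaneous recurrent seizures (five-criterion detector with post-ictal
    suppression), movement-artifact removal, a seeded synthetic-EEG
    generator with ground-truth labels for detector validation, behavioral
    scoring rubrics (modified Racine scale, modified Irwin test, novel
    object recognition discrimination index), and the study-level outcome
    statistics (exact Fisher tests, Mann-Whitney tests, 2^-ddCt relative
    quantification with geometric-mean housekeeping control, incidence and
    frequency reductions). Includes EDF and CSV readers/writers and a
    reproducible end-to-end pipeline with machine-readable JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
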