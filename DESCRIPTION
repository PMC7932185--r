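Package: megdecode
Title: Decoding Word Semantics from MEG During Speech Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses magnetoencephalography (MEG) recordings
    from a colored-object picture-naming experiment in which words are
    produced in isolation, in two-word lists, or in adjective-noun phrases.
    Provides a synthetic-data generator with the full counterbalanced
    stimulus and block design, standard epoch preprocessing (zero-phase
    Butterworth band-pass, baseline correction, error-trial rejection,
    random group averaging), ridge regression from sliding sensor-time
    windows onto word embeddings with per-dimension leave-one-out selection
    of the regularization parameter, 2-vs-2 evaluation of the decoders,
    within- and across-condition temporal generalization matrices, and
    significance assessment via label-shuffling permutation nulls with
    kernel-density p-values, Benjamini-Yekutieli FDR correction, and
    cluster-based permutation ANOVA over time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
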