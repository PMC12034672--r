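Package: dbfn
Title: Dynamic Brain Functional Networks from EEG via Mutual Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs static and dynamic brain functional networks from
    multichannel EEG. Trials are decomposed into theta, alpha, beta and gamma
    rhythms with complex Morlet wavelets; amplitude and phase differences
    between band pairs are windowed with non-overlapping sliding windows;
    histogram mutual information between channels yields per-window
    connectivity matrices that are binarized at a positional (rank-based)
    threshold; global efficiency, local efficiency and clustering coefficients
    of each binary network form the feature vectors. Includes mRMR feature
    selection, an SVM protocol with repeated stratified cross-validation and
    grid search, three evaluation designs (subject-dependent,
    leave-one-subject-out, and subject-and-trial-independent), region and
    band-pair ablations, and a synthetic-data generator with planted
    cross-channel coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    yaml
Config/testthat/edition: 3
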