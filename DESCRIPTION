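Package: pupilratio
Title: Ratio-Based Pupillometry Biomarker Simulation and Nonparametric Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a ratio-based pupillary
    biomarker of brainstem injury. The DADA index, the ratio of iris-minus-pupil
    surface to pupil surface (IRr^2 - Pr^2)/Pr^2, tracks parasympathetic failure
    of the Edinger-Westphal nucleus after subarachnoid haemorrhage. The package
    provides a seeded synthetic-cohort generator emulating a three-group rabbit
    experiment (control, sham, study) with a latent-severity model; from-scratch
    exact small-sample nonparametric tests (Mann-Whitney U by complete
    enumeration, tie-corrected Kruskal-Wallis, Spearman rank correlation with
    exact permutation p-values); isotonic calibration of the index against
    histological degeneration; threshold classification of subjects as deceased
    or viable under a pupil-diameter criterion versus the DADA-index criterion;
    and an end-to-end reporting pipeline with JSON, CSV and markdown output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
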