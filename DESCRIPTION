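Package: aismir
Title: Arousal-Based Screening of Stressed Mice and Brain-Area miRNA/mRNA
    Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for phenotyping stress-exposed mice into susceptible and
    resilient subgroups from post-trauma acoustic startle reactivity
    (z-normalized arousal scores thresholded at 1), and for the downstream
    molecular analysis of brain-area RT-qPCR data: relative quantification by
    the 2^-ddCt method with GAPDH/U6 reference normalization, group statistics
    (D'Agostino-Pearson normality, one-way ANOVA with Tukey-Kramer post hoc,
    Pearson correlation matrices), exhaustive best-subset linear regression to
    detect synergic miRNA effects on target transcripts and behavioral scores,
    transcription-factor and lncRNA regulator set-overlap matrices, and
    Fisher-exact pathway over-representation with Benjamini-Hochberg FDR
    control. A synthetic cohort generator with planted group effects and
    analyte covariance makes every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
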