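Package: clipcontext
Title: Measuring Drinking-Context Brightness, Loudness and Attendance from
    Short Video Clips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the physical and social context of drinking
    events captured by 10-second video clips in ecological momentary
    assessment designs. Provides a synthetic-study generator (multilevel
    event structure, rendered frame stacks and audio, simulated participant
    and annotator ratings), algorithmic extraction of perceived brightness,
    A-weighted sound level and person counts from clips, multi-annotator
    ordinal fusion with ICC(2,k) agreement, cluster-adjusted descriptive
    comparisons with Cohen's d, random-intercept logistic regression with
    McKelvey-Zavoina pseudo R-squared and a multilevel Hosmer-Lemeshow
    test, and class-balanced cross-validated random-forest inference of
    alcohol use from contextual measures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    matrixStats,
    EBImage,
    png,
    ranger,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
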