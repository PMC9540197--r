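Package: speechcoh
Title: Speech-Brain Coherence and Alpha Power Under Noise-Vocoded Speech
    Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how spectral degradation of
    continuous speech (noise vocoding) modulates low-frequency speech-brain
    coherence ("speech tracking") and alpha-band power. Provides an
    n-channel noise vocoder with analysis bands equidistant along the
    basilar membrane (Greenwood map), cochlear-filterbank extraction of the
    acoustic speech envelope, DPSS multitaper estimation of trial-averaged
    envelope-brain coherence and spectral power, cluster-corrected
    permutation repeated-measures ANOVA with FDR-corrected post hocs,
    random-intercept mixed-model comparisons across vocoding levels (linear
    versus quadratic), and intelligibility models predicting behavioral
    performance from tracking and alpha activation. A synthetic-data
    generator emulates the condition structure of degraded-speech listening
    experiments so that every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
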