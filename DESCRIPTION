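Package: skewscope
Title: Automated Skew-Deviation Quantification from Alternating-Cover
    Video-Oculography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating vertical ocular misalignment (skew
    deviation) from monocular video-oculography recorded under an
    alternating-cover stimulus. Provides a synthetic recording simulator
    with main-sequence saccade kinematics and a simulated prism cover
    test examiner, an estimation engine (adaptive-threshold saccade
    detection, event-windowed velocity integration, robust aggregation),
    method-agreement statistics (intraclass correlation, Bland-Altman
    limits of agreement, percent error, paired Wilcoxon), and a
    command-line interface for a full simulate-estimate-compare study
    replica.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
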