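Package: constancy
Title: Color-Constancy Indices for Discretized-Palette Matching Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for real-object color-constancy experiments in
    which observers match painted stimuli to a discretized commercial paint
    palette under a 2 (illuminant) x 2 (background) design. Implements CIE
    1976 u'v' colorimetry from spectral power distributions, observer- and
    trial-level discard rules with an audit trail, modified-Brunswick
    constancy ratios with their constancy predictions, an atheoretic error
    index baselined by split-half resampling, central-tendency and
    variability statistics (including direct least-squares ellipse fitting),
    palette-density summaries, and the inferential layer (paired t-tests,
    three-way fixed-effects ANOVA, Pearson correlations). A synthetic
    experiment generator with known adaptation, background-modulation and
    noise parameters makes every stage testable and supports
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
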