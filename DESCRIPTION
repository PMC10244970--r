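Package: duradapt
Title: Duration Channels, Motion Adaptation, and 2AFC Duration Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A population model of perceived duration built from duration-tuned
    pooling mechanisms with divisive normalization, a biphasic temporal
    front-end filter, and gain-control adaptation, together with the
    psychophysical machinery needed to analyse two-alternative forced-choice
    duration judgements: cumulative-Gaussian psychometric fitting (PSE and
    JND), adaptation-effect summaries, paired comparisons and correlation
    analyses, and a synthetic-observer generator that emulates a
    twenty-participant motion-adaptation duration experiment with sub-second
    (600 ms) and supra-second (1200 ms) standards.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
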