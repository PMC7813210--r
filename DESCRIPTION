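Package: opiniondyn
Title: Reading Dynamics and Lexicon-Based Opinion Scoring for Social Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the spread of attention and opinion on
    microblogging platforms. Implements a susceptible-reading-susceptible/immune
    (SRS/I) compartmental model of topic-reading dynamics with a public-opinion
    reproduction ratio, stage-wise least-squares estimation of the ratio from
    daily reading counts, dictionary-weighted price-tendency scoring,
    lexicon-based sentiment polarity with three-rater adjudication,
    vaccine-type attention profiling over engagement dimensions, and a
    synthetic corpus generator carrying ground truth for every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
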