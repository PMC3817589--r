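Package: rovcoral
Title: Quantification and Statistics for ROV Video Transects of Cold-Water Corals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying benthic video transects collected by a
    remotely operated vehicle (ROV) along depth gradients, built around the
    survey design used to map the cold-water coral Desmophyllum dianthus in
    Chilean fjords. The package scales video frames from echo-sounder ranges
    and camera angles of view, places frames in a fjord coordinate system,
    writes ESRI worldfiles, excludes overlapping frames, aggregates coral and
    substrate quantities into 10-m depth bins together with CTD profiles, and
    tests for an abundance break at depth with rank-sum and permutation tests
    plus per-predictor regressions. A seeded synthetic-survey generator with
    known ground truth makes the whole pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
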