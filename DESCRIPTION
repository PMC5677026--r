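Package: halflie
Title: Half-Lie Search Games for Photon-Efficient Target Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models confocal and multiphoton target localization as a
    statistical Renyi-Ulam search game with asymmetric ("half-lie") errors:
    a fluorescent emitter inside the illuminated region may fail to yield a
    photon with probability alpha0, while a detection is always truthful.
    Provides the closed-form mutual information of a single top-hat query
    and its information-optimal boundary, the q-sectioning-with-verification
    family of search heuristics as an exact per-query simulator and a
    distribution-identical fast sampler, closed-form expected query costs,
    Monte Carlo summaries of query-count distributions, and exact censuses
    of which sectioning order q minimizes the expected cost across precision
    and loss-rate grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
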