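Package: tlmabac
Title: Linguistic Interval-Valued q-Rung Orthopair Fuzzy MABAC for Group Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-attribute group decision making with 2-tuple
    linguistic interval-valued q-rung orthopair fuzzy numbers. Implements the
    2-tuple linguistic representation model, the fuzzy-number algebra (operational
    laws, score and accuracy functions, normalized Hamming distance), weighted
    averaging and weighted geometric aggregation operators, and an extended
    MABAC (multi-attributive border approximation area comparison) ranking
    pipeline with rung-parameter sensitivity sweeps. Ships an embedded
    breast-cancer treatment-selection case study, a constraint-aware random
    instance generator, JSON/CSV interchange, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
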