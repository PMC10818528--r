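Package: ssfra
Title: Species Sensitivity Factor Read-Across for Acute Aquatic Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts acute aquatic toxicity (LC50) of a data-poor target
    chemical from a structurally and mechanistically similar source chemical
    using species sensitivity ratios (SSR) and their geometric mean, the
    species sensitivity factor (SSF). Covers category selection of
    acetylcholinesterase-inhibiting organophosphates and carbamates by
    log Kow, mode of action and functional group; solubility filtering and
    geometric-mean aggregation of ECOTOX-style LC50 records; ordered
    source-target pairing with per-taxon species matching and a sensitivity
    exclusion rule; donor-combination enumeration under data-rich (Case I)
    and data-poor (Case II) scenarios; over/underestimation classification;
    and an agreement-evaluation suite (bias, relative bias, precision, mean
    absolute error, Bland-Altman limits, Pearson correlation) on
    log-transformed predictions. Includes a synthetic-data generator with a
    known multiplicative sensitivity structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nortest,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
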