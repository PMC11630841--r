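Package: foldrescue
Title: Family-Template Rescue of Low-Confidence Protein Structure Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects protein families whose AlphaFold-style models show a
    bimodal per-domain plDDT distribution, builds within-family template
    banks from the confident members, re-predicts the low-confidence
    members through a pluggable prediction backend in template+MSA and
    template+single-sequence modes, selects best-pick models, classifies
    rescues (plDDT crossing the confidence threshold of 70), and reports
    paired nonparametric statistics. Ships a synthetic family generator
    and a stochastic mock backend so the whole pipeline is testable at
    desk scale without GPUs or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
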