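Package: metaref
Title: Absolute Expression Profiling Against a Large Common Reference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-probeset meta-profiles (step-fit high/low threshold,
    dynamic range, signed expression percentiles) from a large pool of
    normalized microarray data used as a common reference, maps new samples
    and replicate-averaged populations onto that reference as absolute
    expression calls, searches genes by high/low patterns across populations,
    and simulates how large the reference pool must be before per-probeset
    dynamic-range estimates stabilize. A synthetic-data module generates
    reference pools with known ground truth so the whole pipeline is testable
    without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
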