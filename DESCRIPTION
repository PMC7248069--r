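Package: meiocnv
Title: Meiotic Segregation Simulation and Low-Coverage Single-Cell
    Aneuploidy Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates chromosome segregation through female meiosis in
    crossover-deficient oocytes (univalent mis-segregation, premature
    sister-chromatid separation, meiosis II nondisjunction) at chromatid
    resolution, converts the resulting karyotypes of zygotes and polar
    bodies into low-coverage per-chromosome mapped-read counts, and
    implements a read-proportion copy-number procedure: empirical
    reference building from karyotypically normal samples, per-chromosome
    ratio and doubling transform, whole-chromosome gain/loss calling,
    aneuploidy complexity classification, and matched zygote-polar-body
    reciprocity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
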