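Package: microseqr
Title: Germline Mosaicism Workup from Deep Targeted Counts and
    Microdissected-Fragment Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Single-patient workup of suspected germline (gonadal)
    mosaicism. Quantifies low-fraction mosaic variants from deep targeted
    read counts under an explicit sequencing-error model with
    depth-dependent detection limits; infers the parental chromosome
    origin of an apparent de novo mutation from haploid
    microdissected-fragment observations via informative-SNP linkage;
    checks paternity with STR markers; and computes recurrence risk and
    the diagnostic decision path for genetic counseling. A seeded
    synthetic-cohort module generates every input (trios, fragments,
    pileups, mixtures, STR panels) with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
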