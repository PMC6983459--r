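Package: rvburden
Title: Case-Control Rare-Variant Collapsing Burden Analysis with
    Coverage Harmonization, Cosegregation and ACMG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level rare-variant association analysis for case-control
    exome studies. Implements site-based coverage harmonization between
    cohorts, population-database novelty filtering, classification of
    variants into likely gene-disrupting (LGD) and damaging-missense
    (D-mis, CADD-thresholded) classes, subject-level (CAST-style)
    collapsing with one-sided Fisher exact and chi-square burden tests
    stratified by deleteriousness, autosomal-dominant pedigree
    cosegregation filtering, and combination of ACMG evidence codes into
    a pathogenicity class. Includes a synthetic cohort generator (VCF,
    coverage, frequency-resource and pedigree fixtures) so the full
    pipeline is testable without access to protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
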