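Package: csdload
Title: Complementary Sex Determination Load and Mating Structure in Haplodiploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the genetic load imposed by complementary sex
    determination (CSD) in haplodiploid insects at the population level.
    Provides closed-form predictions of diploid male production under
    single-locus and two-locus CSD with partial sibmating, an exact
    mating-table enumeration and individual-based simulators that validate
    those predictions, Weir-Cockerham F-statistics, hierarchical AMOVA,
    exact Hardy-Weinberg and EM-based linkage-disequilibrium tests with
    the associated locus-filtering procedure, SNP panel selection from
    candidate tables, diploid-male-proportion estimation from ploidy
    counts, Genepop/CSV input and output, and seeded synthetic-data
    generators so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
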