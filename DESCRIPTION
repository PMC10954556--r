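Package: holocross
Title: Crossover Detection and Recombination Analysis from Single-Gamete Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects meiotic crossovers in individual gametes genotyped at
    sparse haplotype-specific SNP markers, as produced by droplet single-cell
    sequencing of pollen nuclei from a heterozygous individual. Provides
    marker selection from variant calls against a phased reference, cell-level
    quality control including genotype-switch-rate doublet screening, a
    two-stage smoothing genotyper that emits crossover intervals between
    qualified genotype blocks, windowed recombination landscapes, Marey maps
    and genetic map lengths, crossover-interference statistics (dispersion
    tests and coefficient-of-coincidence curves), permutation-based tests of
    crossover association with genomic features, and merging rules for
    repeat-based centromeric-unit annotations. A synthetic gamete generator
    with a stationary gamma-renewal crossover model makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
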