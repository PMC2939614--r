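Package: fwdgwas
Title: Forward-Time Simulation of Realistic Samples for Genome-Wide
    Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Expands an initial diploid population built from phased
    haplotypes forward in time under mutation, map-based recombination,
    natural selection, migration and optional lambda-scaling of all
    forces; controls disease-allele frequencies with pre-simulated
    forward or backward trajectories enforced by a controlled mating
    scheme; and draws analysis-ready case-control, trio and admixed
    samples under logistic or ancestry-linear penetrance models.
    Includes linkage-disequilibrium, FST and haplotype-diversity
    statistics, readers and writers for phased VCF, Oxford haps/sample,
    genetic-map text and PLINK PED/MAP, and a synthetic haplotype-panel
    generator with block-wise LD for self-contained testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
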