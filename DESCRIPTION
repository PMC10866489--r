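Package: fossilccm
Title: Character Completeness and the Lagerstatten Effect in Fossil Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the phylogenetic information content of fossil records
    using the Character Completeness Metric 2 (CCM2): the percentage of a
    morphological character matrix scorable for a fossil species given the
    skeletal elements preserved across all its referred specimens. Provides
    character-to-anatomical-region mapping with NEXUS matrix ingestion,
    limbless-taxon "true completeness" denominators, SCM2-to-CCM2 conversion,
    occurrence-table vetting and partitioning by landmass, depositional
    environment and geologic unit, nonparametric pairwise comparison batteries
    (Mann-Whitney U, Kolmogorov-Smirnov) with Bonferroni correction,
    leave-unit-out quantification of the lagerstatten effect on completeness
    distributions and on taxon representation in phylogenetic matrices, and a
    synthetic fossil-record generator with closed-form expected completeness
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
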