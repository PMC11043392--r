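Package: patriseg
Title: Forward-Time Simulation of Patrilineal Segmentary Systems and
    Uniparental Genetic Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based forward-time simulator of human populations structured
    into villages and patrilineal descent groups, designed to study how
    segmentary kinship dynamics shape Y-chromosome and mitochondrial DNA
    diversity. Models sex-biased migration under patrilocal, matrilocal or
    multilocal residence, descent-group exogamy, group-level variance in
    reproductive success with transmission at fission, lineal and random
    fission of over-large groups, violent inter-group competition, polygyny,
    and post-fission group migration. Tracks uniparental genealogies through
    the pedigree, initialises standing diversity with a coalescent model of
    the pre-structure phase, overlays mutations on the resulting gene trees,
    and converts nucleotide diversity (pi) into male and female effective
    population sizes with BCa bootstrap confidence intervals across
    replicates. Sampled genealogies and haplotypes can be exported as FASTA,
    Newick, NEXUS and VCF for external coalescent inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    boot,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
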