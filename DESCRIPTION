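Package: strpanel
Title: Forensic Statistics for Sequence-Based STR and SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic and forensic analysis of massively parallel
    sequencing (MPS) STR/SNP panels starting from called genotypes: a parser
    and nomenclature engine for bracketed sequence-based STR alleles (ISFG
    length designations, repeat-region vs flanking-region variation),
    chromosome-aware allele and Y-haplotype frequency tables, the standard
    forensic parameter suite (heterozygosity, gene diversity, PIC, match
    probability, powers of discrimination and exclusion, paternity indices,
    X-chromosomal mean exclusion chances, Y haplotype diversity and
    discrimination capacity, combined panel statistics), exact
    Hardy-Weinberg and EM-based linkage-disequilibrium tests with Bonferroni
    bookkeeping, sequence-based versus length-based allele accounting,
    depth-of-coverage quality control, and a seeded synthetic-population
    generator shaped like a 306-marker, 100-individual panel study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
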