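Package: dikaryoMap
Title: Dominant-Trait Co-Segregation Mapping in Monokaryon/Dikaryon Fungal Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to map a dominant Mendelian trait in basidiomycete breeding
    pedigrees that mix haploid monokaryons and heterokaryotic dikaryons.
    Provides Mendelian segregation chi-square tests on phenotype counts,
    record-level SNP filtering of VCF genotypes (biallelic, depth, genotype
    quality, completeness), a dominance-model genotype-phenotype
    co-segregation filter over discovery pedigrees and multi-cultivar
    validation panels, strand-aware coding-effect classification of SNPs
    against gene models, and a seeded pedigree simulator (founder haplotypes,
    F1 dikaryon, meiotic F2 spores, selfed F2 dikaryons, cultivar panel) that
    emits VCF, FASTA, GFF3 and sample sheets so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
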