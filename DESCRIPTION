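Package: imprintscan
Title: Parent-of-Origin Imprinting Detection from Reciprocal-Cross Allele-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate genomically imprinted loci from reciprocal-cross
    F1 designs with pooled offspring RNA-seq. Starting from parental
    whole-genome genotype calls (VCF) and offspring-pool allele counts (read
    alignments or pre-computed tables), the package discovers strain-diagnostic
    SNPs under configurable depth standards, orients strain alleles to parental
    origin per cross, and applies a candidate cascade: a per-locus coverage
    floor, a chi-square test against the 1:1 biallelic null with Bonferroni
    correction, a parent-of-origin expression-fraction threshold required in
    both reciprocal crosses, and a strain-allele inversion check that separates
    imprinting from strain-biased cis effects. ZW sex-chromosome logic flags
    female Z hemizygosity and untestable W loci. Candidate SNPs can be
    annotated for genic location and coding effect against gene models, and
    screened against novel long non-coding RNA transcripts. A synthetic-data
    generator emulates the full study design (two inbred strains, two
    reciprocal crosses, same-sex offspring pools, ZW karyotype) with planted
    imprinting, strain-ASE, sex-specific and heterozygous-parent artifact
    scenarios, so the whole cascade is testable offline against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
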