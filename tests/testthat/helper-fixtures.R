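# shared fixture builders; everything is generated in code at test time

default_design <- cross_design("Cor", "WL")

# write a tiny coordinate-sorted SAM and convert to indexed BAM
make_bam <- function(reads, contigs = c(chr1 = 100), dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sam <- file.path(dir, "reads.sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  writeLines(c(header, reads), sam)
  Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE)
}

sam_read <- function(qname, chrom, pos, seq, qual = strrep("I", nchar(seq)),
                     cigar = paste0(nchar(seq), "M"), flag = 0, mapq = 60) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, chrom, pos, mapq, cigar, seq, qual)
}

# hand-build a strain-allele count table row set for one locus across the
# four libraries; counts given in (maternal, paternal) per library
counts_for_locus <- function(chrom, pos, mp, design = default_design,
                             a = "A", b = "G", other = c(0, 0, 0, 0)) {
  libs <- design$libraries
  do.call(rbind, lapply(seq_len(4), function(j) {
    m <- mp[[j]][1]; p <- mp[[j]][2]
    dam_is_a <- libs$dam_strain[j] == design$strains["a"]
    data.frame(chrom = chrom, pos = pos,
               strainA_allele = a, strainB_allele = b,
               library = libs$library[j], cross = libs$cross[j],
               sex = libs$sex[j],
               count_strainA = if (dam_is_a) m else p,
               count_strainB = if (dam_is_a) p else m,
               count_other = other[j], stringsAsFactors = FALSE)
  }))
}

# minimal single-sample VCF writer for genotype fixtures
write_test_vcf <- function(path, sample, chrom, pos, ref, alt, gt, dp) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", unique(chrom)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                     sample))
  writeLines(c(header,
               sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP\t%s:%d",
                       chrom, pos, ref, alt, gt, dp)), path)
  path
}

# four-parent VCF fixture from per-parent genotype/depth vectors
make_parent_fixture <- function(chrom, pos, ref, alt, gt, dp,
                                dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parents <- data.frame(
    parent = c("I_dam", "I_sire", "II_dam", "II_sire"),
    strain = c("Cor", "WL", "WL", "Cor"),
    cross = c("I", "I", "II", "II"),
    role = c("dam", "sire", "dam", "sire"),
    stringsAsFactors = FALSE)
  parents$path <- vapply(seq_len(4), function(k)
    write_test_vcf(file.path(dir, paste0(parents$parent[k], ".vcf")),
                   parents$parent[k], chrom, pos, ref, alt,
                   gt[[k]], dp[[k]]), character(1))
  parents
}

# toy one-gene genome spec used across annotation tests
toy_gene_spec <- function(cds_seq, strand = "+", chrom_len = 2000,
                          cds_start = 101) {
  cds_end <- cds_start + nchar(cds_seq) - 1
  list(chromosomes = c(chr1 = chrom_len),
       genes = list(list(gene_id = "g1", transcript_id = "t1",
                         chrom = "chr1", strand = strand,
                         exons = list(c(cds_start, cds_end)),
                         cds = list(c(cds_start, cds_end)),
                         cds_seq = cds_seq)))
}
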