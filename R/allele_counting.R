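#' Count strain alleles at diagnostic SNPs from RNA-seq alignments
#'
#' Tallies, for every diagnostic SNP, the reads supporting the strain-A
#' allele, the strain-B allele, or any other base. Secondary, supplementary
#' and duplicate-flagged alignments are excluded, as are reads below the
#' mapping-quality threshold and bases below the base-quality threshold.
#' A deletion spanning the SNP counts as "other". When both mates of a pair
#' overlap the SNP the base with the higher base quality is counted once.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param snps A `diagnostic_snps` data.frame from [find_diagnostic_snps()].
#' @param library_id Library identifier; must appear in `design$libraries`.
#' @param design A [cross_design()].
#' @param min_mapq,min_baseq Quality thresholds (defaults 20/20).
#' @return An `allele_count_table` data.frame (one row per SNP) with the same
#'   schema as [sample_allele_counts()]. SNPs with no passing reads are
#'   retained with zero counts so downstream coverage filtering sees them.
#' @export
count_alleles_from_alignments <- function(bam, snps, library_id,
                                          design = cross_design(),
                                          min_mapq = 20, min_baseq = 20) {
  stopifnot(file.exists(bam), nrow(snps) >= 1)
  lib <- design$libraries[design$libraries$library == library_id, ]
  if (nrow(lib) != 1) stop("unknown library id: ", library_id)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM file is not indexed: ", bam)

  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing_contig <- setdiff(unique(snps$chrom), names(hdr))
  if (length(missing_contig))
    stop("contig(s) absent from BAM header: ",
         paste(missing_contig, collapse = ", "))

  target <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(which = GenomicRanges::reduce(target),
                                   flag = flags,
                                   mapqFilter = min_mapq,
                                   what = c("qname", "seq", "qual"))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)

  count_a <- integer(nrow(snps))
  count_b <- integer(nrow(snps))
  count_other <- integer(nrow(snps))

  if (length(gal)) {
    # project read sequence and qualities into reference space: deletions
    # become "-", insertions are removed, so position arithmetic is direct
    seq_ref <- GenomicAlignments::sequenceLayer(
      S4Vectors::mcols(gal)$seq, GenomicAlignments::cigar(gal))
    qual_ref <- GenomicAlignments::sequenceLayer(
      as(S4Vectors::mcols(gal)$qual, "BStringSet"),
      GenomicAlignments::cigar(gal))
    hits <- GenomicRanges::findOverlaps(target,
                                        GenomicRanges::granges(gal),
                                        ignore.strand = TRUE)
    if (length(hits)) {
      si <- S4Vectors::queryHits(hits)
      ri <- S4Vectors::subjectHits(hits)
      starts <- IRanges::start(GenomicRanges::granges(gal))
      off <- snps$pos[si] - starts[ri] + 1L
      base <- as.character(Biostrings::subseq(seq_ref[ri], off, off))
      qch <- as.character(Biostrings::subseq(qual_ref[ri], off, off))
      bq <- rep(-1L, length(qch))
      nz <- qch != "-"
      if (any(nz))
        bq[nz] <- utf8ToInt(paste(qch[nz], collapse = "")) - 33L
      qname <- S4Vectors::mcols(gal)$qname[ri]

      # overlapping mates: keep the higher-quality base per (snp, read name)
      key <- paste(si, qname)
      ord <- order(key, -bq)
      keep_first <- !duplicated(key[ord])
      sel <- ord[keep_first]
      si <- si[sel]; base <- base[sel]; bq <- bq[sel]

      is_del <- base == "-"
      pass <- is_del | bq >= min_baseq
      si <- si[pass]; base <- base[pass]; is_del <- is_del[pass]

      a <- snps$strain_a_allele[si]
      b <- snps$strain_b_allele[si]
      cat_a <- !is_del & base == a
      cat_b <- !is_del & base == b
      cat_o <- !cat_a & !cat_b
      count_a <- tabulate(si[cat_a], nbins = nrow(snps))
      count_b <- tabulate(si[cat_b], nbins = nrow(snps))
      count_other <- tabulate(si[cat_o], nbins = nrow(snps))
    }
  }

  out <- data.frame(
    chrom = snps$chrom, pos = snps$pos,
    strainA_allele = snps$strain_a_allele,
    strainB_allele = snps$strain_b_allele,
    library = library_id, cross = lib$cross, sex = lib$sex,
    count_strainA = count_a, count_strainB = count_b,
    count_other = count_other, stringsAsFactors = FALSE
  )
  class(out) <- c("allele_count_table", "data.frame")
  out
}

#' Load a pooled allele-count table from TSV
#'
#' Reads the tab-separated schema written by [write_count_table()] /
#' emitted by the simulator, and validates it against the design: known
#' library ids, non-negative counts, no duplicated (locus, library) rows.
#'
#' @param path TSV file with header `chrom pos strainA_allele strainB_allele
#'   library cross sex count_strainA count_strainB count_other`.
#' @param design A [cross_design()].
#' @return An `allele_count_table` data.frame.
#' @export
load_count_table <- function(path, design = cross_design()) {
  need <- c("chrom", "pos", "strainA_allele", "strainB_allele", "library",
            "cross", "sex", "count_strainA", "count_strainB", "count_other")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  if (!all(need %in% names(tab)))
    stop("count table is missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab <- tab[need]
  cnt <- c("count_strainA", "count_strainB", "count_other")
  if (any(vapply(tab[cnt], function(x) any(x < 0 | x != floor(x)), logical(1))))
    stop("counts must be non-negative integers")
  unknown <- setdiff(unique(tab$library), design$libraries$library)
  if (length(unknown))
    stop("unknown library id(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(tab[c("chrom", "pos", "library")]))
    stop("duplicated (locus, library) row(s) in count table")
  class(tab) <- c("allele_count_table", "data.frame")
  tab
}

#' Orient strain-allele counts to parental origin
#'
#' In each cross the maternal count is the count of the dam-strain allele:
#' in cross I (strain A dam) maternal = strain-A count; in the reciprocal
#' cross II the mapping is swapped. Strain-allele counts are retained
#' alongside so the between-cross inversion check can run in strain space.
#'
#' @param counts An `allele_count_table`.
#' @param design A [cross_design()].
#' @return A data.frame of class `oriented_counts`: locus, library metadata,
#'   `maternal_count`, `paternal_count`, `other_count`, plus the original
#'   strain-space counts and alleles.
#' @export
orient_to_parent <- function(counts, design = cross_design()) {
  stopifnot(all(c("library", "count_strainA", "count_strainB") %in%
                  names(counts)))
  idx <- match(counts$library, design$libraries$library)
  if (anyNA(idx))
    stop("library with unknown cross: ",
         paste(unique(counts$library[is.na(idx)]), collapse = ", "))
  dam_is_a <- design$libraries$dam_strain[idx] == design$strains["a"]
  out <- data.frame(
    chrom = counts$chrom, pos = counts$pos,
    strainA_allele = counts$strainA_allele,
    strainB_allele = counts$strainB_allele,
    library = counts$library,
    cross = design$libraries$cross[idx],
    sex = design$libraries$sex[idx],
    maternal_count = ifelse(dam_is_a, counts$count_strainA,
                            counts$count_strainB),
    paternal_count = ifelse(dam_is_a, counts$count_strainB,
                            counts$count_strainA),
    other_count = counts$count_other,
    count_strainA = counts$count_strainA,
    count_strainB = counts$count_strainB,
    stringsAsFactors = FALSE
  )
  class(out) <- c("oriented_counts", "data.frame")
  out
}

#' Merge the female and male pools of each cross
#'
#' Element-wise sums of the two sex libraries per cross, mirroring a merged
#' reanalysis of the pooled data. Z-chromosome loci are flagged
#' (`z_mixed_dosage`): merging combines hemizygous female pools (single,
#' paternal Z) with biallelic male pools, so the 1:1 null is distorted there.
#'
#' @param oriented An `oriented_counts` data.frame covering both sexes.
#' @param design A [cross_design()].
#' @return An `oriented_counts` data.frame with `library = "<cross>_merged"`,
#'   `sex = "merged"` and a logical `z_mixed_dosage` column.
#' @export
merge_sexes <- function(oriented, design = cross_design()) {
  stopifnot(inherits(oriented, "data.frame"),
            all(c("cross", "sex", "maternal_count") %in% names(oriented)))
  pieces <- lapply(unique(oriented$cross), function(cr) {
    f <- oriented[oriented$cross == cr & oriented$sex == "female", ]
    m <- oriented[oriented$cross == cr & oriented$sex == "male", ]
    if (!nrow(f) || !nrow(m))
      stop("missing sex library for cross ", cr)
    key_f <- paste(f$chrom, f$pos)
    key_m <- paste(m$chrom, m$pos)
    if (!setequal(key_f, key_m))
      stop("female and male pools cover different loci in cross ", cr)
    m <- m[match(key_f, key_m), , drop = FALSE]
    data.frame(
      chrom = f$chrom, pos = f$pos,
      strainA_allele = f$strainA_allele, strainB_allele = f$strainB_allele,
      library = paste0(cr, "_merged"), cross = cr, sex = "merged",
      maternal_count = f$maternal_count + m$maternal_count,
      paternal_count = f$paternal_count + m$paternal_count,
      other_count = f$other_count + m$other_count,
      count_strainA = f$count_strainA + m$count_strainA,
      count_strainB = f$count_strainB + m$count_strainB,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  out$z_mixed_dosage <- chrom_class(out$chrom, design) == "Z"
  rownames(out) <- NULL
  class(out) <- c("oriented_counts", "data.frame")
  out
}
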