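#' Find novel transcripts relative to a reference annotation
#'
#' A transcript from the assembled set is novel iff none of its exons
#' overlaps any exon of any reference transcript, on either strand
#' (intergenic-novelty convention; 1-based inclusive intervals). Transcripts
#' sharing even one exonic base with the reference are `known-overlap`.
#'
#' @param assembled_gtf,reference_gtf Paths to GTF files with exon features.
#' @return An object of class `novel_transcripts`: list with `table` (one row
#'   per assembled transcript: `transcript_id`, `chrom`, `strand`, `n_exons`,
#'   `spliced_length`, `provenance`) and `exons` (a `GRangesList` of the
#'   assembled transcripts' exons, for sequence extraction and SNP mapping).
#' @export
find_novel_transcripts <- function(assembled_gtf, reference_gtf) {
  import_exons <- function(path) {
    # an annotation with no records (empty file) is a valid, vacuous reference
    has_body <- any(!grepl("^#|^\\s*$", readLines(path, warn = FALSE)))
    if (!has_body) return(GenomicRanges::GRanges())
    gr <- rtracklayer::import(path, format = "gtf")
    gr[gr$type == "exon"]
  }
  asm <- import_exons(assembled_gtf)
  ref <- import_exons(reference_gtf)

  exons <- S4Vectors::split(asm, asm$transcript_id)
  olap <- if (length(ref)) {
    GenomicRanges::findOverlaps(asm, ref, ignore.strand = TRUE)
  } else NULL
  overlapping_tx <- if (!is.null(olap) && length(olap)) {
    unique(asm$transcript_id[S4Vectors::queryHits(olap)])
  } else character()

  ids <- names(exons)
  tab <- data.frame(
    transcript_id = ids,
    chrom = vapply(ids, function(i)
      as.character(GenomicRanges::seqnames(exons[[i]])[1]), character(1)),
    strand = vapply(ids, function(i)
      as.character(BiocGenerics::strand(exons[[i]])[1]), character(1)),
    n_exons = vapply(ids, function(i) length(exons[[i]]), integer(1)),
    spliced_length = vapply(ids, function(i)
      sum(BiocGenerics::width(exons[[i]])), integer(1)),
    provenance = ifelse(ids %in% overlapping_tx, "known-overlap", "novel"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(table = tab, exons = exons), class = "novel_transcripts")
}

#' @export
print.novel_transcripts <- function(x, ...) {
  cat(sprintf("novel_transcripts: %d assembled, %d novel\n",
              nrow(x$table), sum(x$table$provenance == "novel")))
  invisible(x)
}

#' Extract spliced transcript sequences
#'
#' @param transcripts A `novel_transcripts` object.
#' @param genome A `DNAStringSet` (or FASTA path) covering the transcripts'
#'   contigs.
#' @return A named character vector of spliced, strand-corrected sequences.
#' @export
transcript_sequences <- function(transcripts, genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
  }
  vapply(names(transcripts$exons), function(id) {
    ex <- BiocGenerics::sort(transcripts$exons[[id]])
    chrom <- as.character(GenomicRanges::seqnames(ex)[1])
    pieces <- as.character(Biostrings::extractAt(
      genome[[chrom]],
      IRanges::IRanges(BiocGenerics::start(ex), BiocGenerics::end(ex))))
    s <- paste(pieces, collapse = "")
    if (as.character(BiocGenerics::strand(ex)[1]) == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
}

# longest ORF (in nt, ATG..stop inclusive, or ATG..end of last complete
# codon when no stop follows) over the three frames of one strand
.longest_orf_one_strand <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    k <- (n - frame) %/% 3
    if (k < 1) next
    codons <- substring(seq, frame + 1 + 3 * (0:(k - 1)),
                        frame + 3 + 3 * (0:(k - 1)))
    open_at <- NA_integer_
    for (j in seq_len(k)) {
      if (is.na(open_at) && codons[j] == "ATG") open_at <- j
      if (!is.na(open_at) && codons[j] %in% stops) {
        best <- max(best, (j - open_at + 1L) * 3L)
        open_at <- NA_integer_
      }
    }
    if (!is.na(open_at)) best <- max(best, (k - open_at + 1L) * 3L)
  }
  best
}

#' Coding-potential score of a transcript sequence
#'
#' A transparent, deterministic open-reading-frame heuristic standing in for
#' SVM-based coding-potential classifiers: the longest ORF is searched in all
#' six frames (ORF = ATG through the next in-frame stop, or through the last
#' complete codon when the frame runs off the end), and the score is the mean
#' of its length as a fraction of the transcript and its amino-acid length
#' normalised by 100 (capped at 1). Higher scores are more coding-like; a
#' sequence without ATG scores 0.
#'
#' @param seq Character vector of nucleotide sequences (A/C/G/T/N, case
#'   insensitive).
#' @return Numeric vector of scores in `[0, 1]`.
#' @examples
#' coding_potential_score("CCCTTTCCC")          # no ATG -> 0
#' coding_potential_score(strrep("ATGGCT", 50)) # one 300-nt ORF -> 1
#' @export
coding_potential_score <- function(seq) {
  vapply(seq, function(s) {
    s <- toupper(s)
    if (nchar(s) < 1) stop("empty sequence")
    if (grepl("[^ACGTN]", s)) stop("non-nucleotide characters in sequence")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    orf <- max(.longest_orf_one_strand(s), .longest_orf_one_strand(rc))
    if (orf == 0) return(0)
    aa <- orf / 3  # codon count of the ORF
    mean(c(orf / nchar(s), min(1, aa / 100)))
  }, numeric(1), USE.NAMES = !is.null(names(seq)))
}

#' Filter novel transcripts to lncRNA candidates
#'
#' Retains transcripts that are novel, at least `lnc_min_length` bases of
#' spliced length, at least `lnc_min_exons` exons (the multi-exon default
#' reads the published exclusion of single-exon fragments; set
#' `lnc_min_exons = 1` for the literal reading), below the coding-potential
#' threshold, and without a protein database hit when that column is
#' supplied.
#'
#' @param novel A `novel_transcripts` object.
#' @param config A [filter_config()].
#' @param scores Named numeric vector of coding-potential scores per
#'   transcript id (e.g. from [coding_potential_score()]); transcripts
#'   without a score are kept only if `scores` is `NULL` entirely.
#' @param protein_hit Optional named logical vector: `TRUE` drops the
#'   transcript (external protein-database evidence of coding).
#' @return The retained subset of `novel$table`, with a `score` column when
#'   scores were supplied.
#' @export
filter_lncrna_candidates <- function(novel, config = filter_config(),
                                     scores = NULL, protein_hit = NULL) {
  tab <- novel$table
  keep <- tab$provenance == "novel" &
    tab$spliced_length >= config$lnc_min_length &
    tab$n_exons >= config$lnc_min_exons
  if (!is.null(scores)) {
    sc <- scores[tab$transcript_id]
    tab$score <- unname(sc)
    keep <- keep & !is.na(sc) & sc < config$lnc_score_threshold
  }
  if (!is.null(protein_hit)) {
    ph <- protein_hit[tab$transcript_id]
    keep <- keep & !(ph %in% TRUE)
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary statistics of retained lncRNA candidates
#'
#' @param retained Output of [filter_lncrna_candidates()].
#' @return List with `n`, `mean_length`, `mean_exons`.
#' @export
lncrna_summary <- function(retained) {
  list(n = nrow(retained),
       mean_length = if (nrow(retained)) mean(retained$spliced_length) else NA,
       mean_exons = if (nrow(retained)) mean(retained$n_exons) else NA)
}

#' Map candidate SNPs onto transcripts
#'
#' A SNP maps to a transcript iff its position falls inside one of the
#' transcript's exons (exonic convention: intronic positions do not map).
#'
#' @param snps A data.frame with `chrom` and `pos`.
#' @param transcripts A `novel_transcripts` object (or any `GRangesList` of
#'   exons named by transcript).
#' @param ids Optional subset of transcript ids to map against (e.g. the
#'   retained lncRNA candidates).
#' @return A data.frame `chrom`, `pos`, `transcript_id`; zero rows when
#'   nothing maps.
#' @export
map_snps_to_transcripts <- function(snps, transcripts, ids = NULL) {
  exons <- if (inherits(transcripts, "novel_transcripts"))
    transcripts$exons else transcripts
  if (!is.null(ids)) exons <- exons[names(exons) %in% ids]
  if (!length(exons) || !nrow(snps))
    return(data.frame(chrom = character(), pos = integer(),
                      transcript_id = character(), stringsAsFactors = FALSE))
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  flat <- unlist(exons, use.names = FALSE)
  tx_of <- rep(names(exons), S4Vectors::elementNROWS(exons))
  hits <- GenomicRanges::findOverlaps(snp_gr, flat, ignore.strand = TRUE)
  out <- data.frame(
    chrom = snps$chrom[S4Vectors::queryHits(hits)],
    pos = snps$pos[S4Vectors::queryHits(hits)],
    transcript_id = tx_of[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  unique(out)
}
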