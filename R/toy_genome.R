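#' Generate a toy genome FASTA and GTF annotations
#'
#' Builds an internally consistent genome + gene-model fixture set for the
#' effect-annotation and lncRNA stages: a FASTA with random background
#' sequence, a reference GTF of declared gene models, and an "assembled"
#' GTF containing the reference transcripts plus any declared novel
#' transcripts (as a transcript-assembly stage would emit).
#'
#' @param genome_spec A list with elements:
#'   \describe{
#'     \item{chromosomes}{named integer vector of chromosome lengths; should
#'       include `Z` and `W` entries when sex-chromosome logic is exercised.}
#'     \item{genes}{list of gene models, each a list with `gene_id`,
#'       `transcript_id`, `chrom`, `strand` (`"+"`/`"-"`), `exons` (list of
#'       `c(start, end)` 1-based inclusive), optional `cds` (list of
#'       `c(start, end)`, subset of the exons) and optional `cds_seq`
#'       (coding-sense DNA written into the genome across the CDS; reverse
#'       complemented onto minus-strand genes).}
#'     \item{novel_transcripts}{optional list like `genes` but without CDS;
#'       written only to the assembled GTF.}
#'   }
#' @param outdir Output directory (created if needed).
#' @param seed Seed for the random background sequence.
#' @return List of paths: `fasta`, `genes_gtf`, `assembled_gtf`.
#' @examples
#' spec <- list(
#'   chromosomes = c(chr1 = 1000),
#'   genes = list(list(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
#'                     strand = "+", exons = list(c(101, 400)),
#'                     cds = list(c(101, 400)))))
#' paths <- generate_toy_genome(spec, outdir = tempfile("toy"))
#' @export
generate_toy_genome <- function(genome_spec, outdir = tempfile("toy"),
                                seed = 1L) {
  chroms <- genome_spec$chromosomes
  if (is.null(chroms) || is.null(names(chroms)) || any(!nzchar(names(chroms))))
    stop("genome_spec$chromosomes must be a named vector of lengths")
  genes <- genome_spec$genes %||% list()
  novel <- genome_spec$novel_transcripts %||% list()
  set.seed(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  seqs <- lapply(chroms, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))

  validate_model <- function(g, need_cds_multiple3 = TRUE) {
    stopifnot(!is.null(g$chrom), g$chrom %in% names(chroms),
              g$strand %in% c("+", "-"), length(g$exons) >= 1)
    ex <- do.call(rbind, lapply(g$exons, function(e) e[1:2]))
    if (any(ex[, 1] > ex[, 2])) stop("exon start > end in ", g$transcript_id)
    if (any(ex < 1) || any(ex[, 2] > chroms[[g$chrom]]))
      stop("exon outside chromosome in ", g$transcript_id)
    o <- order(ex[, 1])
    ex <- ex[o, , drop = FALSE]
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2]))
      stop("overlapping exons in ", g$transcript_id)
    if (!is.null(g$cds)) {
      cds <- do.call(rbind, lapply(g$cds, function(e) e[1:2]))
      cds <- cds[order(cds[, 1]), , drop = FALSE]
      inside <- vapply(seq_len(nrow(cds)), function(i)
        any(cds[i, 1] >= ex[, 1] & cds[i, 2] <= ex[, 2]), logical(1))
      if (!all(inside)) stop("CDS not contained in exons in ", g$transcript_id)
      len <- sum(cds[, 2] - cds[, 1] + 1)
      if (need_cds_multiple3 && len %% 3 != 0)
        stop("CDS length not divisible by 3 in ", g$transcript_id)
      g$cds_mat <- cds
    }
    g$exon_mat <- ex
    g
  }
  genes <- lapply(genes, validate_model)
  novel <- lapply(novel, validate_model, need_cds_multiple3 = FALSE)

  # plant declared coding sequences into the background genome
  for (g in genes) {
    if (is.null(g$cds_seq) || is.null(g$cds_mat)) next
    cds_len <- sum(g$cds_mat[, 2] - g$cds_mat[, 1] + 1)
    if (nchar(g$cds_seq) != cds_len)
      stop("cds_seq length mismatch in ", g$transcript_id)
    genomic <- if (g$strand == "+") g$cds_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$cds_seq)))
    offset <- 0
    for (i in seq_len(nrow(g$cds_mat))) {
      w <- g$cds_mat[i, 2] - g$cds_mat[i, 1] + 1
      piece <- substr(genomic, offset + 1, offset + w)
      substr(seqs[[g$chrom]], g$cds_mat[i, 1], g$cds_mat[i, 2]) <- piece
      offset <- offset + w
    }
  }

  fasta <- file.path(outdir, "genome.fa")
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- names(chroms)
  Biostrings::writeXStringSet(dna, fasta)

  gtf_lines <- function(g, source) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     g$gene_id %||% g$transcript_id, g$transcript_id)
    ex <- g$exon_mat
    lines <- sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                     g$chrom, source, min(ex[, 1]), max(ex[, 2]), g$strand, attrs)
    lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, source, ex[, 1], ex[, 2], g$strand, attrs))
    if (!is.null(g$cds_mat)) {
      cds <- g$cds_mat
      ord <- if (g$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
      widths <- cds[ord, 2] - cds[ord, 1] + 1
      frame <- cumsum(c(0, widths[-length(widths)])) %% 3
      lines <- c(lines, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
                                g$chrom, source, cds[ord, 1], cds[ord, 2],
                                g$strand, frame, attrs))
    }
    lines
  }

  genes_gtf <- file.path(outdir, "genes.gtf")
  writeLines(as.character(unlist(lapply(genes, gtf_lines, source = "toy"))),
             genes_gtf)
  assembled_gtf <- file.path(outdir, "assembled.gtf")
  writeLines(as.character(unlist(lapply(c(genes, novel), gtf_lines,
                                        source = "assembly"))),
             assembled_gtf)
  list(fasta = fasta, genes_gtf = genes_gtf, assembled_gtf = assembled_gtf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
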