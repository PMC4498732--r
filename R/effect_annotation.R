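#' Load transcript gene models from GTF + genome FASTA
#'
#' Imports a GTF annotation and the matching genome, validates each
#' transcript model (exons sorted and non-overlapping, CDS contained in
#' exons), and flags transcripts whose total CDS length is not divisible by 3
#' as incomplete (loaded with a warning).
#'
#' @param gtf Path to a GTF file with `exon` (and optionally `CDS`) features
#'   carrying `gene_id` and `transcript_id` attributes.
#' @param fasta Path to the genome FASTA; every GTF contig must be present.
#' @return An object of class `gene_models`: list with `transcripts` (named
#'   list of models: `transcript_id`, `gene_id`, `chrom`, `strand`, `exons`
#'   and `cds` as 2-column start/end matrices, `incomplete_cds` flag) and
#'   `genome` (a `DNAStringSet`).
#' @export
load_gene_models <- function(gtf, fasta) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*", "", names(genome))
  missing_contig <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                            names(genome))
  if (length(missing_contig))
    stop("GTF references contig(s) absent from FASTA: ",
         paste(missing_contig, collapse = ", "))

  feat <- as.data.frame(gr)
  feat$seqnames <- as.character(feat$seqnames)
  feat$strand <- as.character(feat$strand)
  exon_rows <- feat[feat$type == "exon", , drop = FALSE]
  cds_rows <- feat[feat$type == "CDS", , drop = FALSE]
  if (!nrow(exon_rows)) {
    return(structure(list(transcripts = list(), genome = genome),
                     class = "gene_models"))
  }
  models <- list()
  for (tx in unique(exon_rows$transcript_id)) {
    ex <- exon_rows[exon_rows$transcript_id == tx, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in transcript ", tx)
    cd <- cds_rows[cds_rows$transcript_id == tx, , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    cds_mat <- NULL
    incomplete <- FALSE
    if (nrow(cd)) {
      inside <- vapply(seq_len(nrow(cd)), function(i)
        any(cd$start[i] >= ex$start & cd$end[i] <= ex$end), logical(1))
      if (!all(inside)) stop("CDS not contained in exons of transcript ", tx)
      cds_mat <- cbind(start = cd$start, end = cd$end)
      if (sum(cd$end - cd$start + 1) %% 3 != 0) {
        warning("CDS length of transcript ", tx, " not divisible by 3; ",
                "model flagged incomplete")
        incomplete <- TRUE
      }
    }
    models[[tx]] <- list(
      transcript_id = tx,
      gene_id = ex$gene_id[1] %||% tx,
      chrom = ex$seqnames[1], strand = ex$strand[1],
      exons = cbind(start = ex$start, end = ex$end),
      cds = cds_mat, incomplete_cds = incomplete
    )
  }
  structure(list(transcripts = models, genome = genome),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d transcript(s), %d contig(s)\n",
              length(x$transcripts), length(x$genome)))
  invisible(x)
}

# severity ranking for the worst-case summary (most severe first)
.effect_rank <- c("stop_gained", "stop_lost", "start_lost", "non_synonymous",
                  "splice_region", "synonymous", "UTR",
                  "non_coding_transcript", "intronic", "intergenic")

# genomic positions of a CDS in coding (5'->3') order
.cds_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$cds)), function(i)
    model$cds[i, "start"]:model$cds[i, "end"]))
  if (model$strand == "-") rev(pos) else pos
}

.base_at <- function(genome, chrom, pos) {
  as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
}

.complement <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}

#' Annotate SNPs with genic location and coding effect
#'
#' Classifies each SNP against every overlapping transcript model:
#' inside a CDS the containing codon is reconstructed (reverse-complemented
#' for minus-strand genes), the alternate allele substituted and the amino
#' acids compared under the standard genetic code, giving `synonymous`,
#' `non_synonymous`, `stop_gained`, `stop_lost` or `start_lost`. Exonic
#' non-CDS positions are `UTR` (or `non_coding_transcript` when the
#' transcript has no CDS), positions inside the transcript but outside exons
#' are `intronic`, and SNPs overlapping nothing are `intergenic`. Positions
#' within 2 bases of an internal exon/intron boundary are additionally marked
#' `splice_region`. The per-SNP summary takes the most severe category across
#' transcripts.
#'
#' The reference allele at a locus is whichever of the two strain alleles
#' matches the genome base; if neither matches, the SNP is reported with
#' category `NA` and a note (not an error).
#'
#' @param snps A data.frame with `chrom`, `pos`, `strain_a_allele`,
#'   `strain_b_allele` (e.g. a `diagnostic_snps` or candidate table).
#' @param models A `gene_models` object from [load_gene_models()].
#' @return A list: `per_transcript` (one row per SNP x overlapping
#'   transcript, plus one `intergenic` row for SNPs overlapping nothing) and
#'   `summary` (one row per SNP with the worst-case `category`).
#' @export
annotate_snps <- function(snps, models) {
  stopifnot(inherits(models, "gene_models"),
            all(c("chrom", "pos", "strain_a_allele", "strain_b_allele") %in%
                  names(snps)))
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    chrom <- snps$chrom[i]; pos <- snps$pos[i]
    a <- snps$strain_a_allele[i]; b <- snps$strain_b_allele[i]
    ref_base <- if (chrom %in% names(models$genome) &&
                    pos <= length(models$genome[[chrom]]))
      .base_at(models$genome, chrom, pos) else NA_character_
    if (is.na(ref_base) || !(ref_base %in% c(a, b))) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, pos = pos, transcript_id = NA, gene_id = NA,
        category = NA_character_, codon_change = NA_character_,
        splice_region = FALSE,
        note = "allele mismatch vs reference base",
        stringsAsFactors = FALSE)
      next
    }
    alt <- if (ref_base == a) b else a

    hit_any <- FALSE
    for (model in models$transcripts) {
      if (model$chrom != chrom) next
      span <- range(model$exons)
      if (pos < span[1] || pos > span[2]) next
      hit_any <- TRUE

      in_exon <- any(pos >= model$exons[, "start"] & pos <= model$exons[, "end"])
      in_cds <- !is.null(model$cds) &&
        any(pos >= model$cds[, "start"] & pos <= model$cds[, "end"])

      # splice region: within 2 bases of an internal exon boundary
      splice <- FALSE
      if (nrow(model$exons) > 1) {
        internal <- c(model$exons[-nrow(model$exons), "end"],
                      model$exons[-1, "start"])
        splice <- any(abs(pos - internal) <= 2)
      }

      category <- NA_character_
      codon_change <- NA_character_
      if (in_cds) {
        cds_pos <- .cds_positions(model)
        k <- match(pos, cds_pos)
        codon_idx <- (k - 1) %/% 3
        offset <- (k - 1) %% 3
        codon_genomic <- cds_pos[codon_idx * 3 + 1:3]
        bases <- vapply(codon_genomic, function(p)
          .base_at(models$genome, chrom, p), character(1))
        if (model$strand == "-") bases <- .complement(bases)
        ref_codon <- paste(bases, collapse = "")
        alt_sense <- if (model$strand == "-") .complement(alt) else alt
        alt_bases <- bases
        alt_bases[offset + 1] <- alt_sense
        alt_codon <- paste(alt_bases, collapse = "")
        aa_ref <- Biostrings::GENETIC_CODE[[ref_codon]]
        aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
        codon_change <- paste0(ref_codon, ">", alt_codon)
        category <- if (aa_ref == aa_alt) "synonymous"
          else if (aa_alt == "*") "stop_gained"
          else if (aa_ref == "*") "stop_lost"
          else if (codon_idx == 0 && ref_codon == "ATG") "start_lost"
          else "non_synonymous"
      } else if (in_exon) {
        category <- if (is.null(model$cds)) "non_coding_transcript" else "UTR"
      } else {
        category <- "intronic"
      }
      if (splice && match(category, .effect_rank) >
            match("splice_region", .effect_rank))
        category <- "splice_region"
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, pos = pos,
        transcript_id = model$transcript_id, gene_id = model$gene_id,
        category = category, codon_change = codon_change,
        splice_region = splice, note = NA_character_,
        stringsAsFactors = FALSE)
    }
    if (!hit_any) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, pos = pos, transcript_id = NA, gene_id = NA,
        category = "intergenic", codon_change = NA_character_,
        splice_region = FALSE, note = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  per_transcript <- do.call(rbind, rows)
  rownames(per_transcript) <- NULL

  key <- paste(per_transcript$chrom, per_transcript$pos)
  summary <- do.call(rbind, lapply(unique(key), function(k) {
    sub <- per_transcript[key == k & !is.na(per_transcript$category), ,
                          drop = FALSE]
    if (!nrow(sub)) {
      sub <- per_transcript[key == k, , drop = FALSE][1, , drop = FALSE]
      return(sub[c("chrom", "pos", "category", "gene_id", "codon_change")])
    }
    worst <- sub[which.min(match(sub$category, .effect_rank)), , drop = FALSE]
    worst[c("chrom", "pos", "category", "gene_id", "codon_change")]
  }))
  rownames(summary) <- NULL
  list(per_transcript = per_transcript, summary = summary)
}
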