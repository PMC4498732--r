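#' Load the four parental genotype call sets
#'
#' Reads one single-sample VCF per parent and assembles the per-locus
#' genotype/depth matrix used by [find_diagnostic_snps()]. Indel and
#' multi-allelic records are skipped (with a message reporting how many):
#' indel-adjacent loci are a documented source of unreliable allele counts.
#' A locus present in only some files is retained with a no-call for the
#' missing parents.
#'
#' @param parent_files A data.frame with columns `path`, `parent`, `strain`,
#'   `cross`, `role` (as returned by [generate_parent_vcfs()]); exactly four
#'   rows, two parents per strain.
#' @param design A [cross_design()]; strains must match `parent_files$strain`.
#' @return An object of class `parent_genotypes`: list with `loci` (data.frame
#'   `chrom`, `pos`, `ref`, `alt`) and per-parent genotype columns
#'   `gt_<parent>` (like `"A/A"`, `NA` for no-call) and depth columns
#'   `dp_<parent>`, plus the `parents` metadata.
#' @export
load_parent_genotypes <- function(parent_files, design = cross_design()) {
  stopifnot(is.data.frame(parent_files),
            all(c("path", "parent", "strain", "cross", "role") %in%
                  names(parent_files)))
  if (nrow(parent_files) != 4)
    stop("exactly four parents are required (two per strain)")
  if (!setequal(unique(parent_files$strain), unname(design$strains)))
    stop("parent strains do not match the design")

  per_parent <- vector("list", 4)
  n_skipped <- 0L
  for (k in seq_len(4)) {
    v <- vcfR::read.vcfR(parent_files$path[k], verbose = FALSE)
    if (ncol(v@gt) != 2)  # FORMAT + exactly one sample
      stop("multi-sample VCF not allowed: ", parent_files$path[k])
    fix <- as.data.frame(v@fix[, c("CHROM", "POS", "REF", "ALT"),
                               drop = FALSE], stringsAsFactors = FALSE)
    fix$POS <- as.integer(fix$POS)
    # skip indels and multi-allelic records
    keep <- nchar(fix$REF) == 1 & !grepl(",", fix$ALT) & nchar(fix$ALT) == 1
    n_skipped <- n_skipped + sum(!keep)
    gt_raw <- vcfR::extract.gt(v, element = "GT")[keep]
    dp <- as.integer(vcfR::extract.gt(v, element = "DP")[keep])
    fix <- fix[keep, , drop = FALSE]
    key <- paste(fix$CHROM, fix$POS)
    if (anyDuplicated(key))
      stop("duplicate locus within ", parent_files$path[k])
    # decode numeric GT to base pairs
    alleles <- cbind(fix$REF, fix$ALT)
    parts <- strsplit(ifelse(is.na(gt_raw), "./.", gt_raw), "[/|]")
    i1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L))) + 1L
    i2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))) + 1L
    ok <- !is.na(i1) & !is.na(i2) & i1 <= 2 & i2 <= 2
    gt <- rep(NA_character_, length(gt_raw))
    gt[ok] <- paste(alleles[cbind(which(ok), i1[ok])],
                    alleles[cbind(which(ok), i2[ok])], sep = "/")
    per_parent[[k]] <- data.frame(key = key, chrom = fix$CHROM, pos = fix$POS,
                                  ref = fix$REF, alt = fix$ALT,
                                  gt = gt, dp = dp, stringsAsFactors = FALSE)
  }
  if (n_skipped > 0)
    message(n_skipped, " indel/multi-allelic record(s) skipped")

  all_keys <- unique(unlist(lapply(per_parent, `[[`, "key")))
  base <- do.call(rbind, per_parent)
  base <- base[!duplicated(base$key), c("key", "chrom", "pos", "ref", "alt")]
  base <- base[match(all_keys, base$key), , drop = FALSE]
  if (length(design$chrom_class)) {
    unknown <- setdiff(unique(base$chrom), names(design$chrom_class))
    if (length(unknown))
      warning("contig(s) absent from the karyotype map, treated as autosomal: ",
              paste(unknown, collapse = ", "))
  }
  for (k in seq_len(4)) {
    p <- per_parent[[k]]
    idx <- match(base$key, p$key)
    base[[paste0("gt_", parent_files$parent[k])]] <- p$gt[idx]
    base[[paste0("dp_", parent_files$parent[k])]] <- p$dp[idx]
  }
  base <- base[order(base$chrom, base$pos), , drop = FALSE]
  rownames(base) <- NULL
  structure(list(loci = base, parents = parent_files, design = design),
            class = "parent_genotypes")
}

#' @export
print.parent_genotypes <- function(x, ...) {
  cat(sprintf("parent_genotypes: %d loci x %d parents\n",
              nrow(x$loci), nrow(x$parents)))
  invisible(x)
}

#' Discover strain-diagnostic SNPs
#'
#' A locus is diagnostic when all four parents are called, every parent is
#' homozygous, the two parents of each strain carry the identical allele, the
#' two strain alleles differ, and every parent's depth is strictly greater
#' than the standard's threshold (loose: > 2x, general: > 10x). Loci failing
#' any condition are dropped; strain heterozygosity that is visible in the
#' genotype calls therefore removes a locus entirely.
#'
#' @param parents A `parent_genotypes` object.
#' @param standard `"loose"` or `"general"`.
#' @param config A [filter_config()].
#' @return A data.frame of class `diagnostic_snps`: `chrom`, `pos`,
#'   `strain_a_allele`, `strain_b_allele`, `min_parent_depth`, `standard`.
#'   Strain A is the dam strain of cross I.
#' @export
find_diagnostic_snps <- function(parents, standard = c("general", "loose"),
                                 config = filter_config()) {
  stopifnot(inherits(parents, "parent_genotypes"))
  standard <- match.arg(standard)
  min_depth <- switch(standard, loose = config$loose_depth,
                      general = config$general_depth)
  pf <- parents$parents
  loci <- parents$loci
  design <- parents$design
  a_parents <- pf$parent[pf$strain == design$strains["a"]]
  b_parents <- pf$parent[pf$strain == design$strains["b"]]

  gt_cols <- paste0("gt_", pf$parent)
  dp_cols <- paste0("dp_", pf$parent)
  gts <- as.matrix(loci[gt_cols])
  dps <- as.matrix(loci[dp_cols])

  all_called <- rowSums(!is.na(gts)) == 4
  split_gt <- function(col) {
    m <- matrix(NA_character_, nrow(loci), 2)
    ok <- !is.na(col)
    sp <- strsplit(col[ok], "/", fixed = TRUE)
    m[ok, 1] <- vapply(sp, `[`, "", 1L)
    m[ok, 2] <- vapply(sp, `[`, "", 2L)
    m
  }
  hom_allele <- matrix(NA_character_, nrow(loci), 4)
  is_hom <- matrix(FALSE, nrow(loci), 4)
  for (k in seq_len(4)) {
    m <- split_gt(gts[, k])
    is_hom[, k] <- !is.na(m[, 1]) & m[, 1] == m[, 2]
    hom_allele[, k] <- ifelse(is_hom[, k], m[, 1], NA_character_)
  }
  colnames(hom_allele) <- pf$parent
  all_hom <- rowSums(is_hom) == 4
  same_a <- hom_allele[, a_parents[1]] == hom_allele[, a_parents[2]]
  same_b <- hom_allele[, b_parents[1]] == hom_allele[, b_parents[2]]
  diff_ab <- hom_allele[, a_parents[1]] != hom_allele[, b_parents[1]]
  depth_ok <- rowSums(!is.na(dps) & dps > min_depth) == 4

  keep <- all_called & all_hom &
    !is.na(same_a) & same_a & !is.na(same_b) & same_b &
    !is.na(diff_ab) & diff_ab & depth_ok
  idx <- which(keep)
  out <- data.frame(
    chrom = loci$chrom[idx], pos = loci$pos[idx],
    strain_a_allele = unname(hom_allele[idx, a_parents[1]]),
    strain_b_allele = unname(hom_allele[idx, b_parents[1]]),
    min_parent_depth = if (length(idx))
      apply(dps[idx, , drop = FALSE], 1, min) else integer(0),
    standard = rep(standard, length(idx)), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("diagnostic_snps", "data.frame")
  out
}

#' Remove diagnostic SNPs that are too densely spaced
#'
#' Enforces fewer than `density_max_snps` SNPs in any `density_window`-base
#' span (defaults: fewer than 2 per 10 bases). Both members of a violating
#' pair are removed: with the defaults, any SNP with another diagnostic SNP
#' within 9 bases on the same chromosome is dropped, so no retained 10-base
#' window ever holds two SNPs.
#'
#' @param snps A `diagnostic_snps` data.frame (any data.frame with `chrom`,
#'   `pos` works).
#' @param config A [filter_config()].
#' @return The filtered data.frame, original order preserved.
#' @export
apply_density_filter <- function(snps, config = filter_config()) {
  stopifnot(all(c("chrom", "pos") %in% names(snps)))
  if (nrow(snps) < config$density_max_snps) return(snps)
  w <- config$density_window
  kmax <- config$density_max_snps
  drop <- logical(nrow(snps))
  ord <- order(snps$chrom, snps$pos)
  pos <- snps$pos[ord]
  chrom <- snps$chrom[ord]
  n <- length(pos)
  # a SNP violates if any window of kmax consecutive same-chromosome SNPs
  # containing it spans < density_window bases
  if (n >= kmax) {
    for (i in seq_len(n - kmax + 1)) {
      j <- i + kmax - 1
      if (chrom[i] == chrom[j] && pos[j] - pos[i] <= w - 1) {
        drop[ord[i:j]] <- TRUE
      }
    }
  }
  out <- snps[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
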