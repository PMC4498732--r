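#' Reciprocal-cross experimental design
#'
#' Describes a two-strain reciprocal F1 design with same-sex pooled offspring
#' RNA-seq libraries. Cross I uses `strain_a` as the dam and `strain_b` as the
#' sire; cross II is the strict reciprocal. Four libraries (2 crosses x 2
#' sexes) are assumed unless sexes are merged downstream.
#'
#' @param strain_a,strain_b Strain labels; `strain_a` is the dam of cross I.
#' @param chrom_class Named character vector mapping chromosome names to one
#'   of `"autosome"`, `"Z"`, `"W"`, `"unplaced"`. Chromosomes absent from the
#'   map default to `"autosome"` except names `"Z"`/`"W"` which map to
#'   themselves and names starting with `"un"` or `"JH"` which map to
#'   `"unplaced"` (unplaced scaffolds are still tested, like autosomes).
#'
#' @details The design assumes a ZW karyotype (females ZW, males ZZ), so a
#'   female offspring's single Z chromosome is always paternal. This drives
#'   the hemizygosity flags applied by [flag_sex_chromosomes()].
#'
#' @return An object of class `cross_design`: list with `strains`, a
#'   `libraries` data.frame (`library`, `cross`, `sex`, `dam_strain`,
#'   `sire_strain`) and the `chrom_class` map.
#' @examples
#' design <- cross_design("Cor", "WL")
#' design$libraries
#' @export
cross_design <- function(strain_a = "Cor", strain_b = "WL",
                         chrom_class = character()) {
  stopifnot(is.character(strain_a), is.character(strain_b),
            nzchar(strain_a), nzchar(strain_b), strain_a != strain_b)
  libraries <- data.frame(
    library    = c("I_female", "I_male", "II_female", "II_male"),
    cross      = c("I", "I", "II", "II"),
    sex        = c("female", "male", "female", "male"),
    dam_strain  = c(strain_a, strain_a, strain_b, strain_b),
    sire_strain = c(strain_b, strain_b, strain_a, strain_a),
    stringsAsFactors = FALSE
  )
  structure(
    list(strains = c(a = strain_a, b = strain_b),
         libraries = libraries,
         chrom_class = chrom_class),
    class = "cross_design"
  )
}

#' @export
print.cross_design <- function(x, ...) {
  cat("Reciprocal cross design\n")
  cat(sprintf("  cross I : dam %s x sire %s\n", x$strains["a"], x$strains["b"]))
  cat(sprintf("  cross II: dam %s x sire %s\n", x$strains["b"], x$strains["a"]))
  cat(sprintf("  libraries: %s\n", paste(x$libraries$library, collapse = ", ")))
  invisible(x)
}

#' Classify chromosomes under a design's karyotype map
#'
#' @param chrom Character vector of chromosome names.
#' @param design A [cross_design()].
#' @return Character vector in `{"autosome","Z","W","unplaced"}`.
#' @export
chrom_class <- function(chrom, design) {
  stopifnot(inherits(design, "cross_design"))
  out <- rep("autosome", length(chrom))
  out[chrom == "Z"] <- "Z"
  out[chrom == "W"] <- "W"
  out[grepl("^(un|JH)", chrom)] <- "unplaced"
  if (length(design$chrom_class)) {
    hit <- chrom %in% names(design$chrom_class)
    out[hit] <- unname(design$chrom_class[chrom[hit]])
  }
  bad <- setdiff(unique(out), c("autosome", "Z", "W", "unplaced"))
  if (length(bad)) stop("unknown chromosome class: ", paste(bad, collapse = ", "))
  out
}

#' Filtering thresholds for the imprinting-candidate cascade
#'
#' Bundles every numeric threshold used across the pipeline. Defaults follow
#' the published analysis this package reimplements: parental depth strictly
#' greater than 2x (loose) or 10x (general); at least 10 RNA reads on the two
#' parental alleles per cross; chi-square against 1:1 with Bonferroni-adjusted
#' p below 0.05; parent-of-origin fraction strictly above 0.75 in both
#' reciprocal crosses; fewer than two diagnostic SNPs per 10-base window;
#' lncRNA candidates at least 200 bases and at least 2 exons.
#'
#' @param loose_depth,general_depth Parental sequencing depth must be strictly
#'   greater than this for a diagnostic SNP under the loose/general standard.
#' @param min_rna_reads Minimum maternal+paternal RNA reads per cross.
#' @param alpha Familywise significance level for the Bonferroni-adjusted
#'   chi-square test.
#' @param candidate_fraction A candidate needs the same parental side strictly
#'   above this fraction in both crosses.
#' @param density_window,density_max_snps Window size (bases) and the maximum
#'   number of diagnostic SNPs allowed in any window; with the defaults, two
#'   SNPs within 10 bases disqualify each other.
#' @param lnc_min_length,lnc_min_exons Minimum spliced length (bases) and exon
#'   count for a long-non-coding-RNA candidate. The multi-exon default can be
#'   relaxed to 1.
#' @param lnc_score_threshold Transcripts with coding-potential score at or
#'   above this are dropped from the lncRNA screen.
#' @return A list of class `filter_config`.
#' @examples
#' cfg <- filter_config()
#' cfg$candidate_fraction
#' @export
filter_config <- function(loose_depth = 2, general_depth = 10,
                          min_rna_reads = 10, alpha = 0.05,
                          candidate_fraction = 0.75,
                          density_window = 10, density_max_snps = 2,
                          lnc_min_length = 200, lnc_min_exons = 2,
                          lnc_score_threshold = 0.5) {
  stopifnot(loose_depth >= 0, general_depth >= 0,
            min_rna_reads > 0, alpha > 0, alpha < 1,
            candidate_fraction > 0, candidate_fraction < 1,
            density_window >= 1, density_max_snps >= 1,
            lnc_min_length > 0, lnc_min_exons >= 1,
            lnc_score_threshold > 0)
  structure(
    list(loose_depth = loose_depth, general_depth = general_depth,
         min_rna_reads = min_rna_reads, alpha = alpha,
         candidate_fraction = candidate_fraction,
         density_window = density_window, density_max_snps = density_max_snps,
         lnc_min_length = lnc_min_length, lnc_min_exons = lnc_min_exons,
         lnc_score_threshold = lnc_score_threshold),
    class = "filter_config"
  )
}
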