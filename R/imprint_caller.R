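#' Chi-square test for allelic deviation from the 1:1 null
#'
#' Goodness-of-fit chi-square of the maternal/paternal read counts against
#' equal expression of both alleles: statistic
#' \eqn{\sum (o - e)^2 / e} with \eqn{e = (m + p) / 2}, one degree of
#' freedom, no continuity correction; p is the upper-tail probability.
#' "Other"-allele reads are not part of the test: only reads aligned to the
#' two parental alleles enter the denominator.
#'
#' @param maternal,paternal Non-negative integer vectors of read counts.
#' @return A data.frame with columns `statistic` and `p`.
#' @examples
#' test_allelic_deviation(15, 5)   # statistic 5, p ~ 0.025
#' @export
test_allelic_deviation <- function(maternal, paternal) {
  stopifnot(length(maternal) == length(paternal),
            all(maternal >= 0), all(paternal >= 0))
  total <- maternal + paternal
  if (any(total == 0))
    stop("total parental read count is zero for ", sum(total == 0), " locus/loci")
  e <- total / 2
  statistic <- (maternal - e)^2 / e + (paternal - e)^2 / e
  data.frame(statistic = statistic,
             p = stats::pchisq(statistic, df = 1, lower.tail = FALSE))
}

#' Bonferroni adjustment with a significance mask
#'
#' Multiplies each raw p-value by the family size (the number of loci tested,
#' i.e. passing coverage, in the same stratum-and-cross family) and caps at 1.
#'
#' @param raw_p Numeric vector of raw p-values (the whole family).
#' @param alpha Familywise significance level.
#' @return A data.frame with `p_adjusted` and logical `significant`
#'   (`p_adjusted < alpha`).
#' @export
bonferroni_adjust <- function(raw_p, alpha = 0.05) {
  stopifnot(length(raw_p) >= 1, alpha > 0, alpha < 1)
  adj <- stats::p.adjust(raw_p, method = "bonferroni")
  data.frame(p_adjusted = adj, significant = adj < alpha)
}

#' Call imprinting candidates from oriented allele counts for one stratum
#'
#' Applies the full candidate cascade per locus, requiring in BOTH reciprocal
#' crosses: at least `min_rna_reads` reads on the two parental alleles;
#' Bonferroni-significant chi-square deviation from 1:1 (family = loci passing
#' coverage within this stratum and cross); the SAME parental side (maternal
#' in both crosses, or paternal in both) expressed at a fraction strictly
#' above `candidate_fraction`; and inversion of the strain-allele ratio
#' between the crosses (the majority strain allele must flip), which separates
#' parent-of-origin effects from strain-biased allele-specific expression.
#' Every failed condition is recorded as a flag; a locus is a candidate iff
#' it carries no flags.
#'
#' @param oriented An `oriented_counts` data.frame for a single stratum
#'   (female, male or merged), covering both crosses.
#' @param config A [filter_config()].
#' @param stratum Label stored in the output (`"female"`, `"male"`,
#'   `"merged"`).
#' @return A data.frame of class `candidate_calls`: locus, `stratum`,
#'   per-cross maternal fractions (`frac_I`, `frac_II`), chi-square statistics
#'   and raw/adjusted p-values, `expressed_parent`
#'   (`maternal`/`paternal`/`none`), comma-separated `flags`, and `verdict`
#'   (`candidate`/`excluded`).
#' @export
call_candidates <- function(oriented, config = filter_config(),
                            stratum = unique(oriented$sex)) {
  stopifnot(inherits(oriented, "data.frame"), length(stratum) == 1)
  crosses <- sort(unique(oriented$cross))
  if (!setequal(crosses, c("I", "II")))
    stop("both crosses are required; found: ", paste(crosses, collapse = ", "))
  x1 <- oriented[oriented$cross == "I", ]
  x2 <- oriented[oriented$cross == "II", ]
  key1 <- paste(x1$chrom, x1$pos)
  key2 <- paste(x2$chrom, x2$pos)
  if (!setequal(key1, key2))
    stop("the two crosses cover different loci in stratum ", stratum)
  x2 <- x2[match(key1, key2), , drop = FALSE]
  n <- nrow(x1)

  tot1 <- x1$maternal_count + x1$paternal_count
  tot2 <- x2$maternal_count + x2$paternal_count
  cov1 <- tot1 >= config$min_rna_reads
  cov2 <- tot2 >= config$min_rna_reads

  stat1 <- p1 <- padj1 <- rep(NA_real_, n)
  stat2 <- p2 <- padj2 <- rep(NA_real_, n)
  sig1 <- sig2 <- rep(NA, n)
  if (any(cov1)) {
    t1 <- test_allelic_deviation(x1$maternal_count[cov1],
                                 x1$paternal_count[cov1])
    b1 <- bonferroni_adjust(t1$p, config$alpha)
    stat1[cov1] <- t1$statistic; p1[cov1] <- t1$p
    padj1[cov1] <- b1$p_adjusted; sig1[cov1] <- b1$significant
  }
  if (any(cov2)) {
    t2 <- test_allelic_deviation(x2$maternal_count[cov2],
                                 x2$paternal_count[cov2])
    b2 <- bonferroni_adjust(t2$p, config$alpha)
    stat2[cov2] <- t2$statistic; p2[cov2] <- t2$p
    padj2[cov2] <- b2$p_adjusted; sig2[cov2] <- b2$significant
  }

  frac1 <- ifelse(tot1 > 0, x1$maternal_count / tot1, NA_real_)
  frac2 <- ifelse(tot2 > 0, x2$maternal_count / tot2, NA_real_)
  cf <- config$candidate_fraction
  maternal_side <- !is.na(frac1) & !is.na(frac2) & frac1 > cf & frac2 > cf
  paternal_side <- !is.na(frac1) & !is.na(frac2) &
    (1 - frac1) > cf & (1 - frac2) > cf

  # inversion in strain space: the majority strain allele must differ
  maj1 <- sign(x1$count_strainA - x1$count_strainB)
  maj2 <- sign(x2$count_strainA - x2$count_strainB)
  inverted <- maj1 != 0 & maj2 != 0 & maj1 != maj2

  flags <- vector("list", n)
  add_flag <- function(which, flag) {
    for (i in which(which)) flags[[i]] <<- c(flags[[i]], flag)
  }
  add_flag(!cov1 | !cov2, "low_coverage")
  add_flag(cov1 & cov2 & !(sig1 & sig2), "not_significant")
  add_flag(cov1 & cov2 & !(maternal_side | paternal_side), "below_fraction")
  add_flag(cov1 & cov2 & !inverted, "not_inverted")
  flag_str <- vapply(flags, function(f)
    paste(unique(f), collapse = ","), character(1))

  candidate <- flag_str == ""
  expressed <- rep("none", n)
  expressed[candidate & maternal_side] <- "maternal"
  expressed[candidate & paternal_side] <- "paternal"

  out <- data.frame(
    chrom = x1$chrom, pos = x1$pos,
    strainA_allele = x1$strainA_allele, strainB_allele = x1$strainB_allele,
    stratum = stratum,
    frac_I = frac1, frac_II = frac2,
    chi2_I = stat1, chi2_II = stat2,
    p_I = p1, p_II = p2,
    padj_I = padj1, padj_II = padj2,
    expressed_parent = expressed,
    flags = flag_str,
    verdict = ifelse(candidate, "candidate", "excluded"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("candidate_calls", "data.frame")
  out
}

# append a flag and force the verdict to excluded
.add_call_flag <- function(calls, idx, flag) {
  has <- nzchar(calls$flags[idx])
  calls$flags[idx] <- ifelse(has, paste(calls$flags[idx], flag, sep = ","),
                             flag)
  calls$verdict[idx] <- "excluded"
  calls$expressed_parent[idx] <- "none"
  calls
}

#' Flag sex-chromosome loci that cannot evidence imprinting
#'
#' Under ZW sex determination a female's single Z chromosome is always
#' paternal, so paternal-only expression of female-stratum Z loci is dosage,
#' not imprinting: they receive `z_hemizygous_expected` and are excluded.
#' Merged-stratum Z loci receive the same flag because merging mixes
#' hemizygous female with biallelic male dosage. Male-stratum Z loci are
#' testable (ZZ). W loci are untestable in every stratum (`w_untestable`):
#' there is no paternal W.
#'
#' @param calls A `candidate_calls` data.frame.
#' @param design A [cross_design()] providing the karyotype map.
#' @return The calls with sex-chromosome flags applied and verdicts updated.
#' @export
flag_sex_chromosomes <- function(calls, design = cross_design()) {
  cls <- chrom_class(calls$chrom, design)
  z_flag <- cls == "Z" & calls$stratum %in% c("female", "merged")
  if (any(z_flag)) calls <- .add_call_flag(calls, z_flag, "z_hemizygous_expected")
  w_flag <- cls == "W"
  if (any(w_flag)) calls <- .add_call_flag(calls, w_flag, "w_untestable")
  calls
}

#' Summarize candidate calls across strata
#'
#' @param calls A `candidate_calls` data.frame covering one or more strata
#'   (rbind of per-stratum results).
#' @param design A [cross_design()].
#' @return A list of class `imprint_summary`: `candidates_by_stratum`,
#'   `candidates_by_chrom_class` (stratum x autosome/Z/W/unplaced),
#'   `candidates_by_parent`, `flag_counts`, and `sex_specific_candidates`
#'   (loci that are candidates in exactly one sex stratum).
#' @export
summarize_calls <- function(calls, design = cross_design()) {
  stopifnot(inherits(calls, "data.frame"))
  cls <- chrom_class(calls$chrom, design)
  cand <- calls$verdict == "candidate"
  strata <- unique(calls$stratum)
  by_stratum <- vapply(strata, function(s)
    sum(cand & calls$stratum == s), integer(1))
  by_class <- table(stratum = calls$stratum[cand], class = cls[cand])
  by_parent <- table(stratum = calls$stratum[cand],
                     parent = calls$expressed_parent[cand])
  all_flags <- unlist(strsplit(calls$flags[nzchar(calls$flags)], ","))
  flag_counts <- if (length(all_flags)) table(all_flags) else table(character())

  key <- paste(calls$chrom, calls$pos)
  fem <- key[cand & calls$stratum == "female"]
  mal <- key[cand & calls$stratum == "male"]
  sex_specific <- sort(union(setdiff(fem, mal), setdiff(mal, fem)))

  structure(
    list(candidates_by_stratum = by_stratum,
         candidates_by_chrom_class = by_class,
         candidates_by_parent = by_parent,
         flag_counts = flag_counts,
         sex_specific_candidates = sex_specific),
    class = "imprint_summary"
  )
}

#' @export
print.imprint_summary <- function(x, ...) {
  cat("Imprinting-candidate summary\n")
  cat("  candidates by stratum:\n")
  for (s in names(x$candidates_by_stratum))
    cat(sprintf("    %-8s %d\n", s, x$candidates_by_stratum[[s]]))
  n_ss <- length(x$sex_specific_candidates)
  if (n_ss) {
    shown <- utils::head(x$sex_specific_candidates, 5)
    cat(sprintf("  sex-specific candidates: %d (%s%s)\n", n_ss,
                paste(shown, collapse = ", "),
                if (n_ss > 5) ", ..." else ""))
  }
  invisible(x)
}
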