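#' Configuration for the reciprocal-cross study simulator
#'
#' Defines the planted scenarios and sampling model used by [generate_truth()],
#' [generate_parent_vcfs()] and [sample_allele_counts()]. The simulator
#' emulates a two-inbred-strain reciprocal cross with four same-sex pooled
#' offspring RNA-seq libraries (2 crosses x 2 sexes) on a ZW karyotype.
#'
#' Scenarios:
#' \describe{
#'   \item{null_biallelic}{both alleles expressed equally (maternal fraction 0.5).}
#'   \item{imprinted_maternal}{the maternal allele is expressed at
#'     `true_parent_fraction` in every library.}
#'   \item{imprinted_paternal}{the paternal allele is expressed at
#'     `true_parent_fraction` (maternal fraction `1 - f`).}
#'   \item{sex_specific_imprinted}{imprinted (random parent) in one randomly
#'     chosen sex, biallelic in the other.}
#'   \item{strain_ase}{a fixed strain allele is favoured at
#'     `true_parent_fraction` in both crosses, so the maternal fraction is `f`
#'     in the cross where that strain is the dam and `1 - f` in the reciprocal
#'     cross; a cis effect, not imprinting.}
#'   \item{het_parent_artifact}{the site secretly segregates within the
#'     "inbred" strains: one randomly chosen parent in each cross is truly
#'     heterozygous, but is recorded as homozygous in its VCF with probability
#'     `het_miscall_rate`. Offspring pools then sit at dam-strain allele
#'     fractions 0.25 or 0.75 depending on whether the dam or the sire
#'     carries the hidden allele, reproducing the dominant false-positive mode
#'     of genotype-driven imprinting scans.}
#'   \item{z_hemizygous}{a biallelically expressed locus on the Z chromosome.
#'     Female offspring (ZW) carry a single, paternal Z, so the maternal
#'     fraction is 0 in female pools and 0.5 in male (ZZ) pools.}
#' }
#'
#' @param n_loci_per_scenario Number of loci planted per scenario (>= 1).
#' @param scenarios Character vector of scenario labels (see Details).
#' @param true_parent_fraction Expression fraction of the favoured allele for
#'   non-null scenarios, in `[0.5, 1]`.
#' @param depth_mean Mean per-locus, per-library sequencing depth.
#' @param depth_dispersion Negative-binomial dispersion of depth: variance is
#'   `mu + depth_dispersion * mu^2`; 0 gives Poisson depth.
#' @param overdispersion_rho Intra-class correlation of the beta-binomial
#'   allele sampler, in `[0, 1)`; 0 gives pure binomial sampling.
#' @param het_miscall_rate Probability that a truly heterozygous parent at a
#'   `het_parent_artifact` locus is recorded as homozygous in its VCF.
#' @param error_rate Per-read probability of a third ("other") allele,
#'   emulating sequencing error.
#' @param n_w_loci Additionally planted W-chromosome loci (maternal-only in
#'   females, absent in males); untestable for imprinting and flagged as such
#'   downstream. Labelled scenario `"w_locus"` in the truth table.
#' @param seed Integer seed; identical configs give bit-identical outputs.
#' @return A list of class `scenario_config`.
#' @seealso [generate_truth()], [sample_allele_counts()]
#' @export
scenario_config <- function(n_loci_per_scenario = 100,
                            scenarios = c("null_biallelic",
                                          "imprinted_maternal",
                                          "imprinted_paternal",
                                          "sex_specific_imprinted",
                                          "strain_ase",
                                          "het_parent_artifact",
                                          "z_hemizygous"),
                            true_parent_fraction = 0.95,
                            depth_mean = 30,
                            depth_dispersion = 0.1,
                            overdispersion_rho = 0.01,
                            het_miscall_rate = 0.5,
                            error_rate = 0.005,
                            n_w_loci = 0,
                            seed = 1L) {
  known <- c("null_biallelic", "imprinted_maternal", "imprinted_paternal",
             "sex_specific_imprinted", "strain_ase", "het_parent_artifact",
             "z_hemizygous")
  bad <- setdiff(scenarios, known)
  if (length(bad)) stop("unknown scenario label: ", paste(bad, collapse = ", "))
  stopifnot(n_loci_per_scenario >= 1,
            true_parent_fraction >= 0.5, true_parent_fraction <= 1,
            depth_mean > 0, depth_dispersion >= 0,
            overdispersion_rho >= 0, overdispersion_rho < 1,
            het_miscall_rate >= 0, het_miscall_rate <= 1,
            error_rate >= 0, error_rate < 1,
            n_w_loci >= 0)
  structure(
    list(n_loci_per_scenario = as.integer(n_loci_per_scenario),
         scenarios = scenarios,
         true_parent_fraction = true_parent_fraction,
         depth_mean = depth_mean,
         depth_dispersion = depth_dispersion,
         overdispersion_rho = overdispersion_rho,
         het_miscall_rate = het_miscall_rate,
         error_rate = error_rate,
         n_w_loci = as.integer(n_w_loci),
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# Library ids in fixed order; the per-library truth columns follow this order.
.lib_ids <- c("I_female", "I_male", "II_female", "II_male")

#' Generate ground-truth loci for a simulated reciprocal-cross study
#'
#' Lays out diagnostic-SNP loci across autosomes, unplaced scaffolds and the
#' Z/W chromosomes, assigns strain alleles, and computes the expected maternal
#' (dam-strain) allele fraction in each of the four pooled libraries according
#' to the planted scenario.
#'
#' Loci are spaced at least 20 bases apart so the density filter is neutral
#' on simulated data unless violations are planted explicitly.
#'
#' @param config A [scenario_config()].
#' @param design A [cross_design()].
#' @return A data.frame of class `truth_table`: one row per locus with columns
#'   `chrom`, `pos`, `strain_a_allele`, `strain_b_allele`, `scenario`,
#'   `f_I_female`, `f_I_male`, `f_II_female`, `f_II_male` (expected maternal
#'   fraction per library; `NA` where the locus is absent from a library, as
#'   for W loci in males), and for `het_parent_artifact` loci
#'   `het_parent_I`/`het_parent_II` (`"dam"` or `"sire"`, else `NA`).
#' @examples
#' truth <- generate_truth(scenario_config(n_loci_per_scenario = 5, seed = 7))
#' table(truth$scenario)
#' @export
generate_truth <- function(config, design = cross_design()) {
  stopifnot(inherits(config, "scenario_config"), inherits(design, "cross_design"))
  set.seed(config$seed)
  n <- config$n_loci_per_scenario
  f <- config$true_parent_fraction
  scen <- rep(config$scenarios, each = n)
  if (config$n_w_loci > 0) scen <- c(scen, rep("w_locus", config$n_w_loci))
  m <- length(scen)

  autosomes <- c("1", "2", "3", "un1")
  chrom <- character(m)
  chrom[scen == "z_hemizygous"] <- "Z"
  chrom[scen == "w_locus"] <- "W"
  auto_idx <- !(scen %in% c("z_hemizygous", "w_locus"))
  chrom[auto_idx] <- sample(autosomes, sum(auto_idx), replace = TRUE)

  # positions: per chromosome, cumulative gaps of 20..220 bases
  pos <- integer(m)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- cumsum(sample(20:220, length(i), replace = TRUE))
  }

  bases <- c("A", "C", "G", "T")
  a_allele <- sample(bases, m, replace = TRUE)
  b_allele <- vapply(a_allele,
                     function(a) sample(setdiff(bases, a), 1L),
                     character(1))

  fr <- matrix(0.5, nrow = m, ncol = 4,
               dimnames = list(NULL, .lib_ids))
  het_I <- rep(NA_character_, m)
  het_II <- rep(NA_character_, m)

  for (i in seq_len(m)) {
    s <- scen[i]
    if (s == "null_biallelic") {
      # stays at 0.5
    } else if (s == "imprinted_maternal") {
      fr[i, ] <- f
    } else if (s == "imprinted_paternal") {
      fr[i, ] <- 1 - f
    } else if (s == "sex_specific_imprinted") {
      sex <- sample(c("female", "male"), 1L)
      parent <- sample(c("maternal", "paternal"), 1L)
      val <- if (parent == "maternal") f else 1 - f
      fr[i, paste(c("I", "II"), sex, sep = "_")] <- val
    } else if (s == "strain_ase") {
      favored <- sample(unname(design$strains), 1L)
      # maternal fraction is f where the favored strain is the dam
      fa <- ifelse(design$libraries$dam_strain == favored, f, 1 - f)
      fr[i, design$libraries$library] <- fa
    } else if (s == "het_parent_artifact") {
      het_I[i] <- sample(c("dam", "sire"), 1L)
      het_II[i] <- sample(c("dam", "sire"), 1L)
      # a het dam halves the dam-strain content of maternal haplotypes (0.25);
      # a het sire pushes dam-strain content of paternal haplotypes up (0.75)
      fr[i, c("I_female", "I_male")] <- if (het_I[i] == "dam") 0.25 else 0.75
      fr[i, c("II_female", "II_male")] <- if (het_II[i] == "dam") 0.25 else 0.75
    } else if (s == "z_hemizygous") {
      fr[i, c("I_female", "II_female")] <- 0   # single Z, paternal
      fr[i, c("I_male", "II_male")] <- 0.5     # ZZ
    } else if (s == "w_locus") {
      fr[i, c("I_female", "II_female")] <- 1   # single W, maternal
      fr[i, c("I_male", "II_male")] <- NA      # males carry no W
    }
  }

  out <- data.frame(chrom = chrom, pos = pos,
                    strain_a_allele = a_allele, strain_b_allele = b_allele,
                    scenario = scen,
                    f_I_female = fr[, "I_female"], f_I_male = fr[, "I_male"],
                    f_II_female = fr[, "II_female"], f_II_male = fr[, "II_male"],
                    het_parent_I = het_I, het_parent_II = het_II,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("truth_table", "data.frame")
  out
}

# beta-binomial sampler with mean prob f and intra-class correlation rho;
# rho = 0 degenerates to binomial, f in {0,1} to a point mass
.rbetabinom <- function(n, size, f, rho) {
  out <- integer(length(size))
  degenerate <- f <= 0 | f >= 1 | rho == 0
  if (any(degenerate)) {
    i <- which(degenerate)
    out[i] <- stats::rbinom(length(i), size[i], f)
  }
  if (any(!degenerate)) {
    i <- which(!degenerate)
    ab <- 1 / rho - 1
    p <- stats::rbeta(length(i), f * ab, (1 - f) * ab)
    out[i] <- stats::rbinom(length(i), size[i], p)
  }
  out
}

#' Sample pooled allele counts for the four offspring libraries
#'
#' Draws per-locus, per-library depths from a negative-binomial model
#' (variance `mu + depth_dispersion * mu^2`), assigns a small fraction of
#' reads to a third allele at `error_rate`, and splits the remaining parental
#' reads between the dam-strain and sire-strain alleles by binomial (or
#' beta-binomial, `overdispersion_rho > 0`) sampling around the locus's true
#' maternal fraction. Counts are reported in strain-allele space together
#' with the library metadata needed to orient them to parental origin.
#'
#' @param truth A `truth_table` from [generate_truth()].
#' @param config The [scenario_config()] used to generate it.
#' @param design A [cross_design()].
#' @return A data.frame (class `allele_count_table`) with columns `chrom`,
#'   `pos`, `strainA_allele`, `strainB_allele`, `library`, `cross`, `sex`,
#'   `count_strainA`, `count_strainB`, `count_other`. Loci absent from a
#'   library (W in males) get zero depth.
#' @export
sample_allele_counts <- function(truth, config, design = cross_design()) {
  stopifnot(inherits(truth, "data.frame"), inherits(config, "scenario_config"))
  set.seed(config$seed + 1L)
  m <- nrow(truth)
  libs <- design$libraries
  pieces <- vector("list", nrow(libs))
  mu <- config$depth_mean
  size <- if (config$depth_dispersion > 0) 1 / config$depth_dispersion else Inf
  for (j in seq_len(nrow(libs))) {
    lib <- libs$library[j]
    fmat <- truth[[paste0("f_", lib)]]
    depth <- if (is.finite(size)) {
      stats::rnbinom(m, size = size, mu = mu)
    } else {
      stats::rpois(m, mu)
    }
    depth[is.na(fmat)] <- 0L
    other <- stats::rbinom(m, depth, config$error_rate)
    parental <- depth - other
    fmat0 <- ifelse(is.na(fmat), 0, fmat)
    maternal <- .rbetabinom(m, parental, fmat0, config$overdispersion_rho)
    maternal[is.na(fmat)] <- 0L
    paternal <- parental - maternal
    # orient maternal/paternal into strain-allele space via the dam strain
    dam_is_a <- libs$dam_strain[j] == design$strains["a"]
    count_a <- if (dam_is_a) maternal else paternal
    count_b <- if (dam_is_a) paternal else maternal
    pieces[[j]] <- data.frame(
      chrom = truth$chrom, pos = truth$pos,
      strainA_allele = truth$strain_a_allele,
      strainB_allele = truth$strain_b_allele,
      library = lib, cross = libs$cross[j], sex = libs$sex[j],
      count_strainA = count_a, count_strainB = count_b, count_other = other,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("allele_count_table", "data.frame")
  out
}

# minimal deterministic VCF 4.2 writer (one sample, GT:DP)
.write_vcf <- function(path, sample_name, chrom, pos, ref, alt, gt, dp,
                       contigs) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=imprintscan-simulator",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name)
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP\t%s:%d",
                  chrom, pos, ref, alt, gt, dp)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the four parental genotype VCFs for a simulated study
#'
#' Each parent is homozygous for its strain allele at every locus, except at
#' `het_parent_artifact` loci where the designated parent of each cross is
#' truly heterozygous but is recorded as homozygous (for its strain allele)
#' with probability `het_miscall_rate` — emulating the genotyping misses that
#' produce false imprinting candidates. Per-parent depths follow the
#' config's negative-binomial depth model. REF is the strain-A allele and ALT
#' the strain-B allele at every locus.
#'
#' @param truth A `truth_table` from [generate_truth()].
#' @param config The matching [scenario_config()] (`het_miscall_rate`, depth
#'   model and `seed` are taken from it).
#' @param design A [cross_design()].
#' @param outdir Directory to write into (created if needed).
#' @return A data.frame mapping each written VCF `path` to its `parent` id,
#'   `strain`, `cross` and `role` (dam/sire) — the design metadata expected by
#'   [load_parent_genotypes()].
#' @export
generate_parent_vcfs <- function(truth, config, design = cross_design(),
                                 outdir = tempfile("parents")) {
  stopifnot(inherits(truth, "data.frame"), nrow(truth) > 0,
            inherits(config, "scenario_config"))
  set.seed(config$seed + 2L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  parents <- data.frame(
    parent = c("I_dam", "I_sire", "II_dam", "II_sire"),
    strain = c(design$strains["a"], design$strains["b"],
               design$strains["b"], design$strains["a"]),
    cross = c("I", "I", "II", "II"),
    role = c("dam", "sire", "dam", "sire"),
    stringsAsFactors = FALSE
  )
  contigs <- unique(truth$chrom)
  m <- nrow(truth)
  mu <- config$depth_mean
  size <- if (config$depth_dispersion > 0) 1 / config$depth_dispersion else Inf
  paths <- character(nrow(parents))
  for (k in seq_len(nrow(parents))) {
    p <- parents[k, ]
    hom_gt <- if (p$strain == design$strains["a"]) "0/0" else "1/1"
    gt <- rep(hom_gt, m)
    het_col <- if (p$cross == "I") truth$het_parent_I else truth$het_parent_II
    is_het <- !is.na(het_col) & het_col == p$role
    miscalled <- is_het & stats::runif(m) < config$het_miscall_rate
    gt[is_het & !miscalled] <- "0/1"
    dp <- if (is.finite(size)) stats::rnbinom(m, size = size, mu = mu)
          else stats::rpois(m, mu)
    # parents carry W only if female (dam); sires have no W reads
    if (p$role == "sire") dp[truth$chrom == "W"] <- 0L
    paths[k] <- file.path(outdir, paste0(p$parent, ".vcf"))
    .write_vcf(paths[k], p$parent, truth$chrom, truth$pos,
               truth$strain_a_allele, truth$strain_b_allele, gt, dp, contigs)
  }
  parents$path <- paths
  parents
}

#' Write a pooled allele-count table as TSV
#'
#' @param counts An `allele_count_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
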