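test_that("scenario truth fractions follow the genetic model", {
  cfg <- scenario_config(n_loci_per_scenario = 20, true_parent_fraction = 0.95,
                         seed = 101)
  truth <- generate_truth(cfg, default_design)
  fcols <- c("f_I_female", "f_I_male", "f_II_female", "f_II_male")

  mat <- truth[truth$scenario == "imprinted_maternal", fcols]
  expect_true(all(mat == 0.95))
  pat <- truth[truth$scenario == "imprinted_paternal", fcols]
  expect_true(all(abs(pat - 0.05) < 1e-12))

  # strain bias does not invert with parental origin: maternal fraction is f
  # in one cross and 1-f in the other
  ase <- truth[truth$scenario == "strain_ase", ]
  near <- function(x, v) abs(x - v) < 1e-12
  expect_true(all((near(ase$f_I_female, 0.95) & near(ase$f_II_female, 0.05)) |
                  (near(ase$f_I_female, 0.05) & near(ase$f_II_female, 0.95))))
  expect_equal(ase$f_I_female, ase$f_I_male)

  # female Z is paternal: maternal fraction 0 in female pools, 0.5 in males
  z <- truth[truth$scenario == "z_hemizygous", ]
  expect_true(all(z$chrom == "Z"))
  expect_true(all(z$f_I_female == 0 & z$f_II_female == 0))
  expect_true(all(z$f_I_male == 0.5 & z$f_II_male == 0.5))

  # sex-specific loci deviate in exactly one sex, identically in both crosses
  ss <- truth[truth$scenario == "sex_specific_imprinted", ]
  female_dev <- ss$f_I_female != 0.5
  male_dev <- ss$f_I_male != 0.5
  expect_true(all(xor(female_dev, male_dev)))
  expect_equal(ss$f_I_female, ss$f_II_female)

  # het-parent artifact: expected dam-strain fraction 0.25 (het dam) or 0.75
  # (het sire), per cross
  ha <- truth[truth$scenario == "het_parent_artifact", ]
  expect_true(all(ifelse(ha$het_parent_I == "dam", 0.25, 0.75) ==
                    ha$f_I_female))
  expect_true(all(ifelse(ha$het_parent_II == "dam", 0.25, 0.75) ==
                    ha$f_II_male))

  expect_true(all(truth$strain_a_allele != truth$strain_b_allele))
  expect_error(scenario_config(scenarios = "imprinted_everywhere"),
               "unknown scenario")
})

test_that("identical config gives bit-identical outputs, different seed differs", {
  cfg <- scenario_config(n_loci_per_scenario = 15, seed = 7)
  t1 <- generate_truth(cfg, default_design)
  t2 <- generate_truth(cfg, default_design)
  expect_identical(t1, t2)
  c1 <- sample_allele_counts(t1, cfg, default_design)
  c2 <- sample_allele_counts(t2, cfg, default_design)
  expect_identical(c1, c2)

  d1 <- tempfile(); d2 <- tempfile()
  p1 <- generate_parent_vcfs(t1, cfg, default_design, d1)
  p2 <- generate_parent_vcfs(t1, cfg, default_design, d2)
  for (k in 1:4)
    expect_identical(readLines(p1$path[k]), readLines(p2$path[k]))

  t3 <- generate_truth(scenario_config(n_loci_per_scenario = 15, seed = 8),
                       default_design)
  expect_false(identical(t1$pos, t3$pos))
})

test_that("counts conserve depth and track the true fraction", {
  cfg <- scenario_config(n_loci_per_scenario = 400,
                         scenarios = "null_biallelic",
                         overdispersion_rho = 0, error_rate = 0.01,
                         depth_mean = 50, seed = 33)
  truth <- generate_truth(cfg, default_design)
  counts <- sample_allele_counts(truth, cfg, default_design)
  expect_true(all(counts$count_strainA >= 0 & counts$count_strainB >= 0 &
                    counts$count_other >= 0))
  # mean fraction within 3 binomial standard errors of 0.5
  tot <- counts$count_strainA + counts$count_strainB
  frac <- sum(counts$count_strainA) / sum(tot)
  se <- sqrt(0.25 / sum(tot))
  expect_lt(abs(frac - 0.5), 3 * se)

  # f = 1 gives zero paternal reads everywhere
  cfg1 <- scenario_config(n_loci_per_scenario = 30,
                          scenarios = "imprinted_maternal",
                          true_parent_fraction = 1, error_rate = 0, seed = 5)
  tr1 <- generate_truth(cfg1, default_design)
  ct1 <- orient_to_parent(sample_allele_counts(tr1, cfg1, default_design),
                          default_design)
  expect_true(all(ct1$paternal_count == 0))
})

test_that("beta-binomial overdispersion inflates variance per the closed form", {
  n_loci <- 2000
  depth <- 40
  base <- scenario_config(n_loci_per_scenario = n_loci,
                          scenarios = "null_biallelic", depth_mean = depth,
                          depth_dispersion = 0, error_rate = 0, seed = 61)
  over <- scenario_config(n_loci_per_scenario = n_loci,
                          scenarios = "null_biallelic", depth_mean = depth,
                          depth_dispersion = 0, error_rate = 0,
                          overdispersion_rho = 0.3, seed = 61)
  tr <- generate_truth(base, default_design)
  c0 <- sample_allele_counts(tr, base, default_design)
  c3 <- sample_allele_counts(tr, over, default_design)
  v0 <- var(c0$count_strainA[c0$library == "I_female"])
  v3 <- var(c3$count_strainA[c3$library == "I_female"])
  expect_gt(v3, v0)
  # beta-binomial variance n f (1-f) (1 + (n-1) rho), with Poisson n ~ depth
  sizes <- c3$count_strainA + c3$count_strainB
  expected_v3 <- mean(sizes) * 0.25 * (1 + (mean(sizes) - 1) * 0.3)
  expect_lt(abs(v3 - expected_v3) / expected_v3, 0.25)
})

test_that("parent VCFs encode the heterozygous-parent artifact and miscalls", {
  base <- scenario_config(n_loci_per_scenario = 40,
                          scenarios = c("null_biallelic",
                                        "het_parent_artifact"),
                          het_miscall_rate = 0, seed = 19)
  truth <- generate_truth(base, default_design)
  pf <- generate_parent_vcfs(truth, base, default_design)
  pg <- load_parent_genotypes(pf, default_design)
  het_keys <- paste(truth$chrom, truth$pos)[truth$scenario ==
                                              "het_parent_artifact"]
  gts <- pg$loci[paste(pg$loci$chrom, pg$loci$pos) %in% het_keys,
                 paste0("gt_", pf$parent)]
  # with no miscalls, exactly one visibly het parent per cross at every locus
  n_het <- rowSums(gts == "A/C" | gts == "A/G" | gts == "A/T" |
                     gts == "C/G" | gts == "C/T" | gts == "G/T" |
                     gts == "C/A" | gts == "G/A" | gts == "T/A" |
                     gts == "G/C" | gts == "T/C" | gts == "T/G")
  expect_true(all(n_het == 2))

  # miscall rate 1: every parent recorded homozygous everywhere
  full <- scenario_config(n_loci_per_scenario = 40,
                          scenarios = c("null_biallelic",
                                        "het_parent_artifact"),
                          het_miscall_rate = 1, seed = 19)
  pf2 <- generate_parent_vcfs(truth, full, default_design)
  pg2 <- load_parent_genotypes(pf2, default_design)
  gts2 <- as.matrix(pg2$loci[paste0("gt_", pf2$parent)])
  first <- substr(gts2, 1, 1)
  last <- substr(gts2, 3, 3)
  expect_true(all(first == last))
})

test_that("toy genome writes consistent FASTA/GTF and plants CDS sequences", {
  cds <- paste0("ATG", strrep("GCT", 98), "TAA")
  paths <- generate_toy_genome(toy_gene_spec(cds), outdir = tempfile(),
                               seed = 3)
  genome <- Biostrings::readDNAStringSet(paths$fasta)
  expect_equal(length(genome[["chr1"]]), 2000)
  gtf <- read.table(paths$genes_gtf, sep = "\t", stringsAsFactors = FALSE)
  cds_row <- gtf[gtf$V3 == "CDS", ]
  expect_equal(c(cds_row$V4, cds_row$V5), c(101, 400))
  planted <- as.character(Biostrings::subseq(genome[["chr1"]], 101, 400))
  expect_equal(planted, cds)

  # minus strand: genomic CDS reverse-complements to the declared sequence
  pm <- generate_toy_genome(toy_gene_spec(cds, strand = "-"),
                            outdir = tempfile(), seed = 3)
  gm <- Biostrings::readDNAStringSet(pm$fasta)
  genomic <- Biostrings::subseq(gm[["chr1"]], 101, 400)
  expect_equal(as.character(Biostrings::reverseComplement(genomic)), cds)

  # empty gene list: valid FASTA, empty GTF body
  pe <- generate_toy_genome(list(chromosomes = c(chr1 = 500), genes = list()),
                            outdir = tempfile(), seed = 3)
  expect_equal(length(readLines(pe$genes_gtf)), 0)
  expect_error(generate_toy_genome(
    toy_gene_spec(paste0("ATG", strrep("GCT", 98), "TAAC"))),
    "divisible by 3")
})
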