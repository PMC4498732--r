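# parents ordered I_dam (Cor), I_sire (WL), II_dam (WL), II_sire (Cor)

test_that("diagnostic-SNP rules: homozygous, strain-fixed, depth standards", {
  pf <- make_parent_fixture(
    chrom = rep("1", 4), pos = c(100L, 200L, 300L, 400L),
    ref = rep("A", 4), alt = rep("G", 4),
    gt = list(c("0/0", "0/0", "0/0", "0/0"),   # I_dam:  AAAA
              c("1/1", "1/1", "0/1", "1/1"),   # I_sire: het at pos 300
              c("1/1", "1/1", "1/1", "1/1"),
              c("0/0", "0/0", "0/0", "0/0")),
    dp = list(c(12L, 12L, 12L, 12L), c(15L, 5L, 15L, 15L),
              c(20L, 20L, 20L, 20L), c(11L, 11L, 11L, 4L)))
  # pos 100: depths all > 10 -> both standards
  # pos 200: one parent depth 5 -> loose only
  # pos 300: het parent -> never
  # pos 400: depth 4 -> loose only (4 > 2)
  pg <- load_parent_genotypes(pf, default_design)
  loose <- find_diagnostic_snps(pg, "loose")
  general <- find_diagnostic_snps(pg, "general")
  expect_setequal(loose$pos, c(100L, 200L, 400L))
  expect_equal(general$pos, 100L)
  expect_equal(general$strain_a_allele, "A")
  expect_equal(general$strain_b_allele, "G")

  # same allele in both strains is not diagnostic
  pf2 <- make_parent_fixture("1", 100L, "A", "G",
                             gt = list("0/0", "0/0", "0/0", "0/0"),
                             dp = list(30L, 30L, 30L, 30L))
  pg2 <- load_parent_genotypes(pf2, default_design)
  expect_equal(nrow(find_diagnostic_snps(pg2, "loose")), 0)
})

test_that("depth thresholds are strict and boundary depths are excluded", {
  for (std in c("loose", "general")) {
    cutoff <- if (std == "loose") 2L else 10L
    pf <- make_parent_fixture("1", c(10L, 20L), c("A", "A"), c("G", "G"),
      gt = list(c("0/0", "0/0"), c("1/1", "1/1"),
                c("1/1", "1/1"), c("0/0", "0/0")),
      dp = list(c(cutoff, cutoff + 1L), rep(cutoff + 1L, 2),
                rep(cutoff + 1L, 2), rep(cutoff + 1L, 2)))
    pg <- load_parent_genotypes(pf, default_design)
    snps <- find_diagnostic_snps(pg, std)
    expect_equal(snps$pos, 20L, info = std)  # depth == cutoff fails "higher than"
  }
})

test_that("no-call and missing loci exclude a locus; multi-sample VCF errors", {
  dir <- tempfile(); dir.create(dir)
  pf <- make_parent_fixture("1", c(50L, 60L), c("A", "A"), c("G", "G"),
    gt = list(c("0/0", "0/0"), c("1/1", "./."),
              c("1/1", "1/1"), c("0/0", "0/0")),
    dp = list(c(30L, 30L), c(30L, 30L), c(30L, 30L), c(30L, 30L)))
  pg <- load_parent_genotypes(pf, default_design)
  expect_equal(find_diagnostic_snps(pg, "loose")$pos, 50L)

  # locus present in 3 of 4 files is retained as data with a no-call
  pf3 <- pf
  write_test_vcf(pf3$path[2], "I_sire", "1", 50L, "A", "G", "1/1", 30L)
  pg3 <- load_parent_genotypes(pf3, default_design)
  expect_equal(nrow(pg3$loci), 2)
  expect_true(is.na(pg3$loci$gt_I_sire[pg3$loci$pos == 60]))
  expect_equal(find_diagnostic_snps(pg3, "loose")$pos, 50L)

  # a two-sample VCF is rejected
  bad <- file.path(dir, "two.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "1\t50\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1"), bad)
  pf_bad <- pf
  pf_bad$path[1] <- bad
  expect_error(load_parent_genotypes(pf_bad, default_design), "multi-sample")
})

test_that("indel and multi-allelic records are skipped with a message", {
  dir <- tempfile(); dir.create(dir)
  parents <- data.frame(
    parent = c("I_dam", "I_sire", "II_dam", "II_sire"),
    strain = c("Cor", "WL", "WL", "Cor"),
    cross = c("I", "I", "II", "II"),
    role = c("dam", "sire", "dam", "sire"), stringsAsFactors = FALSE)
  gts <- c("0/0", "1/1", "1/1", "0/0")
  parents$path <- vapply(seq_len(4), function(k) {
    p <- file.path(dir, paste0(parents$parent[k], ".vcf"))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
                 "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"D\">",
                 paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                        "\tFORMAT\t", parents$parent[k]),
                 sprintf("1\t10\t.\tA\tG\t.\tPASS\t.\tGT:DP\t%s:30", gts[k]),
                 sprintf("1\t20\t.\tAT\tA\t.\tPASS\t.\tGT:DP\t%s:30", gts[k]),
                 sprintf("1\t30\t.\tA\tG,T\t.\tPASS\t.\tGT:DP\t%s:30", gts[k])),
               p)
    p
  }, character(1))
  expect_message(pg <- load_parent_genotypes(parents, default_design),
                 "skipped")
  expect_equal(pg$loci$pos, 10L)
})

test_that("density filter removes both members of close pairs only", {
  snps <- data.frame(
    chrom = c("1", "1", "1", "1", "2"),
    pos = c(100L, 105L, 200L, 215L, 105L),
    stringsAsFactors = FALSE)
  out <- apply_density_filter(snps, filter_config())
  # 100/105 within 10 bases: both removed; 200/215 kept; chr2 singleton kept
  expect_setequal(paste(out$chrom, out$pos), c("1 200", "1 215", "2 105"))
  # boundary: span of exactly 10 bases (100, 109) violates; (100, 110) is fine
  expect_equal(nrow(apply_density_filter(
    data.frame(chrom = "1", pos = c(100L, 109L)), filter_config())), 0)
  expect_equal(nrow(apply_density_filter(
    data.frame(chrom = "1", pos = c(100L, 110L)), filter_config())), 2)
  # chains: 100,105,112 -> all three drop (105 pairs with both)
  expect_equal(nrow(apply_density_filter(
    data.frame(chrom = "1", pos = c(100L, 105L, 112L)), filter_config())), 0)
})

test_that("discovery matches a brute-force oracle and is strain-symmetric", {
  set.seed(202)
  for (rep in 1:3) {
    n <- 60
    pos <- sort(sample(1000:99999, n)) * 20L  # spaced, density-neutral
    ref <- sample(c("A", "C"), n, TRUE)
    alt <- ifelse(ref == "A", "G", "T")
    gt_pool <- c("0/0", "1/1", "0/1", "./.")
    gt <- replicate(4, sample(gt_pool, n, TRUE, prob = c(.4, .4, .1, .1)),
                    simplify = FALSE)
    dp <- replicate(4, sample(0:40, n, TRUE), simplify = FALSE)
    pf <- make_parent_fixture("1", pos, ref, alt, gt, dp)
    pg <- load_parent_genotypes(pf, default_design)
    loose <- find_diagnostic_snps(pg, "loose")
    general <- find_diagnostic_snps(pg, "general")

    # independent brute-force scan over the raw fixture vectors
    oracle <- function(min_dp) {
      hom <- vapply(1:4, function(k) gt[[k]] %in% c("0/0", "1/1"), logical(n))
      alleles <- vapply(1:4, function(k)
        ifelse(gt[[k]] == "0/0", ref, ifelse(gt[[k]] == "1/1", alt, NA)),
        character(n))
      deep <- vapply(1:4, function(k) dp[[k]] > min_dp, logical(n))
      # parent order: I_dam=Cor, I_sire=WL, II_dam=WL, II_sire=Cor
      ok <- rowSums(hom) == 4 & rowSums(deep) == 4 &
        alleles[, 1] == alleles[, 4] & alleles[, 2] == alleles[, 3] &
        alleles[, 1] != alleles[, 2]
      pos[which(ok)]
    }
    expect_setequal(loose$pos, oracle(2))
    expect_setequal(general$pos, oracle(10))
    # monotonicity: general subset of loose
    expect_true(all(general$pos %in% loose$pos))

    # symmetry: calling the other strain "A" swaps the allele columns only
    design_sw <- cross_design("WL", "Cor")
    pg_sw <- load_parent_genotypes(pf, design_sw)
    loose_sw <- find_diagnostic_snps(pg_sw, "loose")
    expect_setequal(loose_sw$pos, loose$pos)
    m <- match(loose$pos, loose_sw$pos)
    expect_equal(loose_sw$strain_a_allele[m], loose$strain_b_allele)
    expect_equal(loose_sw$strain_b_allele[m], loose$strain_a_allele)
  }
})

test_that("visible heterozygosity removes every artifact locus from discovery", {
  cfg <- scenario_config(n_loci_per_scenario = 60,
                         scenarios = c("null_biallelic",
                                       "het_parent_artifact"),
                         het_miscall_rate = 0, depth_mean = 40, seed = 71)
  truth <- generate_truth(cfg, default_design)
  pf <- generate_parent_vcfs(truth, cfg, default_design)
  pg <- load_parent_genotypes(pf, default_design)
  snps <- find_diagnostic_snps(pg, "loose")
  het_keys <- paste(truth$chrom, truth$pos)[truth$scenario ==
                                              "het_parent_artifact"]
  expect_equal(sum(paste(snps$chrom, snps$pos) %in% het_keys), 0)
})
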