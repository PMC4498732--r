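---
title: "Detecting parent-of-origin imprinting from reciprocal-cross pooled RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parent-of-origin imprinting from reciprocal-cross pooled RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscan)
```

## The design and the statistical problem

Genomic imprinting silences one parental copy of a gene, so an imprinted
locus shows expression from (predominantly) the maternal or the paternal
allele regardless of which strain contributed it. A reciprocal F1 cross
between two inbred strains separates this parent-of-origin signal from
ordinary *cis*-regulatory strain bias: in cross I strain A is the dam and
strain B the sire, in cross II the roles are swapped. At a *diagnostic SNP*
— homozygous within each strain, different between strains — every offspring
RNA-seq read can be assigned to a parent. A strain-biased (cis) effect
favours the same *strain* allele in both crosses; imprinting favours the
same *parental* side, which means the majority strain allele must *invert*
between the crosses.

`imprintscan` implements this logic for pooled offspring libraries (two
crosses × two sexes) on a ZW karyotype (female birds are ZW, males ZZ), from
parental genotype VCFs and per-SNP allele counts through to candidate calls,
variant-effect annotation and a long-non-coding-RNA screen.

## The candidate cascade

For each locus, stratum (female, male, or sexes merged) and cross, let $m$
and $p$ be the reads supporting the maternal and paternal allele. A locus is
a candidate only if, in **both** crosses:

1. **Coverage**: $m + p \ge 10$ reads on the two parental alleles
   ("other"-allele reads never enter the test).
2. **Significance**: the chi-square goodness-of-fit statistic against the
   1:1 biallelic null,
   $X^2 = \sum_{o \in \{m,p\}} (o - e)^2/e$ with $e = (m+p)/2$, one degree
   of freedom and no continuity correction, is significant after Bonferroni
   correction at $\alpha = 0.05$. The Bonferroni family is the set of loci
   passing coverage within the same stratum-and-cross; a global family is a
   plausible alternative, but the per-family choice matches how each cross's
   test battery is assembled and is the stricter reading when coverage
   differs between crosses.
3. **Fraction**: the *same* parental side (maternal in both crosses, or
   paternal in both) carries strictly more than 75% of the parental reads.
   The threshold is strict: exactly 75% fails.
4. **Inversion**: the majority *strain* allele flips between the crosses.
   This is what rejects strain-biased allele-specific expression, which can
   satisfy conditions 1–3 on one parental side per cross but always favours
   the same strain allele.

Every failed condition is recorded as a flag (`low_coverage`,
`not_significant`, `below_fraction`, `not_inverted`); a locus is a candidate
iff it carries no flags, so exclusions are always auditable. Requiring the
chi-square in both crosses (rather than in one) was a genuinely open design
point; we require both because a reproducible deviation is the minimum
evidence for an effect that is supposed to be epigenetically systematic.

### Sex chromosomes

A female's single Z chromosome is always paternal, so female-stratum Z loci
necessarily show paternal-only expression — dosage, not imprinting. They are
flagged `z_hemizygous_expected` and excluded. The same flag is applied in
the *merged* stratum: merging adds a hemizygous female pool (expected
maternal fraction 0) to a biallelic male pool (0.5), so the merged 1:1 null
is structurally wrong on Z and every merged Z locus would otherwise drift
toward an apparent paternal fraction of ~0.75. Male-stratum Z loci (ZZ) are
fully testable. W loci are untestable in all strata (`w_untestable`): there
is no paternal W to compare against.

### Diagnostic SNPs and the density filter

Diagnostic SNPs are discovered from four single-sample parental VCFs. A
locus qualifies when all four parents are called homozygous, the two parents
of a strain agree, the strains differ, and each parent's depth is *strictly
greater* than the standard's threshold — 2× under the loose standard, 10×
under the general standard ("higher than" is read literally). Indel and
multi-allelic records are skipped with a reported count — indel-adjacent
positions are a documented source of miscounted alleles — and a no-call in
any parent excludes the locus rather than defaulting, because unobserved
parental heterozygosity is the dominant false-positive mode (below).

A density filter enforces fewer than two retained SNPs per 10 bases. The
wording does not say which member of a violating pair to keep, so both are
removed: the symmetric, conservative choice. The filter is applied to the
diagnostic-SNP set before RNA analysis; applying it among the RNA-stage
filters instead yields the same candidate set, since it depends only on
positions.

## The synthetic study generator

Real reciprocal-cross data at study scale are not shippable, so the
generator is a first-class, tested module that emulates the design's
essential structure: two inbred strains with fixed differences, four pooled
libraries (2 crosses × 2 sexes), a ZW karyotype, and planted scenarios with
known truth:

* `null_biallelic` — maternal fraction 0.5 everywhere;
* `imprinted_maternal` / `imprinted_paternal` — the favoured parent's
  allele at fraction $f$ (default 0.95, the strong expression bias typical
  of canonical imprinted genes) in all four libraries;
* `sex_specific_imprinted` — imprinted in one random sex, biallelic in the
  other;
* `strain_ase` — a fixed strain allele favoured at $f$ in both crosses, the
  cis-effect confounder the inversion check must reject;
* `z_hemizygous` — biallelic Z loci (maternal fraction 0 in female pools,
  0.5 in male pools);
* `het_parent_artifact` — the locus secretly segregates within the
  "inbred" strains: one randomly chosen parent *in each cross* is truly
  heterozygous but is written to its VCF as homozygous with probability
  `het_miscall_rate`. A single hidden heterozygote cannot mimic imprinting —
  the unaffected cross stays at an expected fraction of 0.5 and the
  both-crosses rule blocks it — but one per cross shifts the dam-strain
  fraction to 0.25 (hidden-het dam) or 0.75 (hidden-het sire) in each cross
  independently. The dam/dam and sire/sire configurations then sit exactly
  at the 75% boundary on a consistent parental side with a correctly
  inverting strain ratio, and sampling noise pushes a predictable minority
  of such loci past every filter. This is the false-positive mechanism that
  wet-lab verification of candidate imprinted SNPs keeps uncovering, and
  the generator reproduces it quantitatively (`evaluate_against_truth()`
  attributes the resulting false candidates to their scenario).

Depths are negative-binomial (variance $\mu + d\mu^2$; $d = 0$ gives
Poisson), defaulting to a mean of 30 reads — a realistic per-SNP exonic
depth for a multi-gigabase pooled brain library. Allele counts are binomial
around the true fraction, or beta-binomial with intra-class correlation
$\rho$ (variance $nf(1-f)(1 + (n-1)\rho)$). Pool-level overdispersion is
not measurable from a single study's printed results; the default
$\rho = 0.01$ is a deliberately mild choice representing minor
individual-to-individual expression variation within a pool, and the
acceptance checks run both with and without it. A fixed per-read error rate
(default 0.005) produces third-allele counts so the counting contract
(maternal + paternal + other = depth) is exercised. Pools are sampled at the
library level, not per individual — the analysis itself only ever sees
pools.

What the generator does **not** emulate: read-level artefacts (mapping
bias toward the reference allele, indel realignment errors), correlated
errors along haplotypes, expression-level heterogeneity between genes, and
per-individual pool composition. Passing tests therefore demonstrate the
statistical correctness of the cascade on its stated sampling model, not
robustness to alignment pathology; the alignment-facing entry point
(`count_alleles_from_alignments()`) is tested separately against a read-level
pileup oracle.

## Allele counting from alignments

When counts are taken from BAM rather than precomputed tables, reads are
filtered with conventional defaults the source analysis leaves unstated:
mapping quality ≥ 20, base quality ≥ 20, duplicates and secondary or
supplementary alignments excluded. A deletion spanning the SNP counts as
"other". Overlapping mates are counted once, keeping the higher-quality
base. Counting happens on a single reference; the original dual
"strain-genome" alignment could admit reads near other variants slightly
differently, a known reference-bias caveat that single-reference counting
inherits and that we flag rather than resolve.

## Effect annotation and the lncRNA screen

Candidate SNPs are classified against transcript models: inside a CDS the
containing codon is reconstructed (reverse-complemented on minus-strand
genes), the alternate allele substituted and the amino acids compared under
the standard nuclear genetic code — `synonymous`, `non_synonymous`,
`stop_gained`, `stop_lost`, `start_lost`; exonic non-CDS positions are
`UTR`, CDS-less transcripts `non_coding_transcript`, positions within 2
bases of an internal exon boundary additionally `splice_region` (the 2-base
window is our definition; annotation tools vary here). Across overlapping
transcripts the most severe category is the summary, with all
per-transcript calls retained.

The lncRNA screen takes an assembled-transcript GTF and a reference GTF: a
transcript is novel iff none of its exons overlaps a reference exon on
either strand. Candidates must be ≥ 200 bases of spliced length and — by
default — multi-exonic: the published exclusion of transcripts that "lacked
at least one exon" can only discriminate anything if read as requiring more
than one exon, since every transcript has one; both readings are available
via `lnc_min_exons`. Coding potential is scored by a transparent six-frame
ORF heuristic (mean of ORF length as a fraction of the transcript, and ORF
codon count normalised by 100) rather than an external SVM classifier:
deterministic, dependency-free and testable, with externally computed
scores and a protein-database-hit column accepted as overrides. Candidate
SNPs map to transcripts by exonic overlap only.

## Numerical and degenerate-input choices

* Chi-square p-values come from the exact $\chi^2_1$ survival function; a
  locus with zero parental reads is an error in the test function and is
  screened out by the coverage filter upstream.
* Bonferroni adjustment is `min(1, p·m)`, significance is `adjusted < α`
  (strict).
* Majority-strain ties (possible only at 50:50) fail the inversion check;
  such loci can never pass the fraction rule anyway.
* Coordinates are 1-based inclusive throughout (VCF/GTF convention).
* Determinism: every generator function derives its RNG stream from the
  config seed, so identical configs give byte-identical outputs, including
  written VCFs.

## Verification scale

The test suite and the acceptance script verify, among other properties:
exact agreement of the chi-square implementation with an independent
normal-tail oracle over all count pairs up to 200 reads; familywise error
of the *full cascade* within its Monte-Carlo band over 200 null replicates
of 1,000 loci; recovery of planted imprinting (500 loci, fraction 0.95,
depth ≈ 80) at the analytically computed binomial detection rate with 100%
correct parent labels; exact rejection of noiseless strain-ASE fixtures at
several depths; complete and correctly one-sided ZW flagging; subset
monotonicity of the two depth standards on 1,000 random genotype fixtures;
reproduction and correct attribution of the hidden-heterozygote
false-positive mode across seeds; positionwise agreement of the effect
annotator with a full-CDS translation oracle on both strands; and 20
study-scale null runs (50,000 diagnostic SNPs, $\rho = 0.01$) ending with
zero candidates. These problem sizes were chosen to give stable Monte-Carlo
estimates while keeping a full verification run in the minutes range on a
single CPU.

## Known limitations

* The generator's artefact menu is the one documented for this design;
  other real-data failure modes (mapping bias, RNA editing, pool
  composition skew) are out of its scope.
* The beta-binomial $\rho$ default is a modelling choice, not an estimate.
* Unplaced scaffolds are treated as autosomes unless the karyotype map says
  otherwise.
* The coding-potential heuristic is intentionally simple; for production
  annotation feed externally computed scores.
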