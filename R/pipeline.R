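#' Run the full simulated reciprocal-cross imprinting study
#'
#' Orchestrates simulate -> diagnose -> count -> call -> summarize -> evaluate
#' on a synthetic study: generates ground truth and parental VCFs, loads the
#' genotypes back through the standard ingestion path, discovers diagnostic
#' SNPs under the chosen depth standard, applies the density filter, samples
#' pooled offspring allele counts (round-tripped through the TSV schema),
#' orients them to parental origin, calls candidates in the female, male and
#' merged strata with sex-chromosome flags, and evaluates the calls against
#' the planted truth.
#'
#' @param config A [scenario_config()] defining the simulated study.
#' @param design A [cross_design()].
#' @param filters A [filter_config()].
#' @param standard Parental depth standard, `"loose"` or `"general"`.
#' @param outdir Output directory; `NULL` runs in a temporary directory.
#'   Stage outputs (`truth.tsv`, parent VCFs, `counts.tsv`, `calls.tsv`,
#'   `report.json`) are written with provenance headers (package version,
#'   seed, config hash).
#' @param keep_files If `FALSE` (default when `outdir` is `NULL`), the
#'   temporary directory is removed on exit.
#' @return A list of class `imprint_study`: `truth`, `diagnostic`
#'   (post-density-filter diagnostic SNPs), `calls` (all strata, flagged),
#'   `summary` ([summarize_calls()]), `evaluation`
#'   ([evaluate_against_truth()]), `stage_counts` (loci in/out of each
#'   cascade stage), and `paths` of the written files.
#' @export
run_pipeline <- function(config, design = cross_design(),
                         filters = filter_config(),
                         standard = c("loose", "general"),
                         outdir = NULL, keep_files = !is.null(outdir)) {
  stopifnot(inherits(config, "scenario_config"))
  standard <- match.arg(standard)
  if (is.null(outdir)) outdir <- tempfile("imprintscan")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!keep_files) on.exit(unlink(outdir, recursive = TRUE), add = TRUE)

  provenance <- c(
    sprintf("# imprintscan %s",
            as.character(utils::packageVersion("imprintscan"))),
    sprintf("# seed=%d", config$seed),
    sprintf("# config_hash=%s", .config_hash(config))
  )
  write_tsv <- function(df, path) {
    writeLines(provenance, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }

  # simulate
  truth <- generate_truth(config, design)
  truth_path <- write_tsv(truth, file.path(outdir, "truth.tsv"))
  parent_files <- generate_parent_vcfs(truth, config, design,
                                       outdir = file.path(outdir, "parents"))

  # diagnose
  parents <- load_parent_genotypes(parent_files, design)
  diag <- find_diagnostic_snps(parents, standard, filters)
  diag_filtered <- apply_density_filter(diag, filters)
  density_excluded <- diag[!paste(diag$chrom, diag$pos) %in%
                             paste(diag_filtered$chrom, diag_filtered$pos), ,
                           drop = FALSE]

  # count
  counts <- sample_allele_counts(truth, config, design)
  counts_path <- file.path(outdir, "counts.tsv")
  write_count_table(counts, counts_path)
  counts <- load_count_table(counts_path, design)
  keep <- paste(counts$chrom, counts$pos) %in%
    paste(diag_filtered$chrom, diag_filtered$pos)
  counts <- counts[keep, , drop = FALSE]
  oriented <- orient_to_parent(counts, design)

  # call, per stratum
  calls <- list()
  for (sx in c("female", "male")) {
    sub <- oriented[oriented$sex == sx, , drop = FALSE]
    calls[[sx]] <- call_candidates(sub, filters, stratum = sx)
  }
  merged <- merge_sexes(oriented, design)
  calls$merged <- call_candidates(merged, filters, stratum = "merged")
  calls <- do.call(rbind, calls)
  calls <- flag_sex_chromosomes(calls, design)
  rownames(calls) <- NULL

  # record loci removed by the density filter as excluded calls
  if (nrow(density_excluded)) {
    dens <- do.call(rbind, lapply(c("female", "male", "merged"), function(sx)
      data.frame(chrom = density_excluded$chrom, pos = density_excluded$pos,
                 strainA_allele = density_excluded$strain_a_allele,
                 strainB_allele = density_excluded$strain_b_allele,
                 stratum = sx, frac_I = NA_real_, frac_II = NA_real_,
                 chi2_I = NA_real_, chi2_II = NA_real_,
                 p_I = NA_real_, p_II = NA_real_,
                 padj_I = NA_real_, padj_II = NA_real_,
                 expressed_parent = "none", flags = "density_excluded",
                 verdict = "excluded", stringsAsFactors = FALSE)))
    calls <- rbind(calls, dens)
  }
  class(calls) <- c("candidate_calls", "data.frame")
  calls_path <- write_tsv(calls, file.path(outdir, "calls.tsv"))

  summary <- summarize_calls(calls, design)
  evaluation <- evaluate_against_truth(calls, truth)

  stage_counts <- list(
    loci_simulated = nrow(truth),
    diagnostic_snps = nrow(diag),
    after_density_filter = nrow(diag_filtered),
    loci_tested = length(unique(paste(counts$chrom, counts$pos))),
    candidates = sum(calls$verdict == "candidate")
  )

  report <- list(
    seed = config$seed,
    config_hash = .config_hash(config),
    standard = standard,
    stage_counts = stage_counts,
    candidates_by_stratum = as.list(summary$candidates_by_stratum),
    sex_specific_candidates = summary$sex_specific_candidates,
    sensitivity = evaluation$sensitivity,
    false_candidates = evaluation$false_candidates
  )
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  structure(
    list(truth = truth, diagnostic = diag_filtered, calls = calls,
         summary = summary, evaluation = evaluation,
         stage_counts = stage_counts,
         paths = list(truth = truth_path, counts = counts_path,
                      calls = calls_path, report = report_path,
                      parents = parent_files$path)),
    class = "imprint_study"
  )
}

.config_hash <- function(config) {
  # stable content hash without extra dependencies
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  as.character(sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e9)
}

#' @export
print.imprint_study <- function(x, ...) {
  cat("imprint_study\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("  %-22s %d\n", nm, x$stage_counts[[nm]]))
  invisible(x)
}

#' Evaluate candidate calls against the planted truth
#'
#' Joins per-locus verdicts (candidate in at least one stratum) with the
#' truth table's scenarios and reports per-scenario sensitivity, the number
#' and origin of false candidates, the accuracy of the expressed-parent
#' label on detected planted loci, and a scenario x verdict confusion table
#' whose rows sum to the planted locus counts.
#'
#' Imprinted scenarios (`imprinted_maternal`, `imprinted_paternal`,
#' `sex_specific_imprinted`) are "planted" positives; any candidate from
#' another scenario is a false candidate.
#'
#' @param calls A `candidate_calls` data.frame (any strata).
#' @param truth The matching `truth_table`.
#' @return A list of class `truth_evaluation`: `sensitivity` (named list per
#'   planted scenario, `NA` when none planted), `false_candidates` (count),
#'   `false_candidates_by_scenario`, `parent_label_accuracy`, and
#'   `confusion` (scenario x candidate/excluded table).
#' @export
evaluate_against_truth <- function(calls, truth) {
  stopifnot(all(c("chrom", "pos", "verdict") %in% names(calls)),
            all(c("chrom", "pos", "scenario") %in% names(truth)))
  key_calls <- paste(calls$chrom, calls$pos)
  key_truth <- paste(truth$chrom, truth$pos)
  if (!all(key_calls %in% key_truth))
    stop("calls contain loci absent from the truth table")

  cand_keys <- unique(key_calls[calls$verdict == "candidate"])
  is_cand <- key_truth %in% cand_keys
  planted_scen <- c("imprinted_maternal", "imprinted_paternal",
                    "sex_specific_imprinted")

  sens <- list()
  for (s in intersect(planted_scen, unique(truth$scenario))) {
    in_s <- truth$scenario == s
    sens[[s]] <- sum(is_cand & in_s) / sum(in_s)
  }

  false_mask <- is_cand & !(truth$scenario %in% planted_scen)
  false_by <- table(truth$scenario[false_mask])

  # expressed-parent correctness on detected planted loci
  correct <- total <- 0L
  cand_calls <- calls[calls$verdict == "candidate", , drop = FALSE]
  ck <- paste(cand_calls$chrom, cand_calls$pos)
  for (s in c("imprinted_maternal", "imprinted_paternal")) {
    want <- if (s == "imprinted_maternal") "maternal" else "paternal"
    keys_s <- key_truth[truth$scenario == s]
    hit <- cand_calls$expressed_parent[ck %in% keys_s]
    total <- total + length(hit)
    correct <- correct + sum(hit == want)
  }
  # sex-specific loci: the detected sex stratum must label the planted parent
  ss_keys <- key_truth[truth$scenario == "sex_specific_imprinted"]
  if (length(ss_keys)) {
    idx <- match(ck, ss_keys)
    hit <- which(!is.na(idx))
    for (i in hit) {
      t_row <- truth[key_truth == ck[i], ][1, ]
      fcols <- c(t_row$f_I_female, t_row$f_I_male,
                 t_row$f_II_female, t_row$f_II_male)
      f_aff <- fcols[!is.na(fcols) & fcols != 0.5][1]
      want <- if (!is.na(f_aff) && f_aff > 0.5) "maternal" else "paternal"
      total <- total + 1L
      correct <- correct + (cand_calls$expressed_parent[i] == want)
    }
  }

  confusion <- table(scenario = truth$scenario,
                     verdict = factor(ifelse(is_cand, "candidate", "excluded"),
                                      levels = c("candidate", "excluded")))
  structure(
    list(sensitivity = if (length(sens)) sens else NA,
         false_candidates = sum(false_mask),
         false_candidates_by_scenario = false_by,
         parent_label_accuracy = if (total) correct / total else NA,
         confusion = confusion),
    class = "truth_evaluation"
  )
}

#' @export
print.truth_evaluation <- function(x, ...) {
  cat("Evaluation against planted truth\n")
  if (is.list(x$sensitivity))
    for (s in names(x$sensitivity))
      cat(sprintf("  sensitivity %-24s %.3f\n", s, x$sensitivity[[s]]))
  cat(sprintf("  false candidates: %d\n", x$false_candidates))
  if (!is.na(x$parent_label_accuracy))
    cat(sprintf("  expressed-parent accuracy: %.3f\n",
                x$parent_label_accuracy))
  invisible(x)
}
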