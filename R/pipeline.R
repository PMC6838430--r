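# Readers/writers and the end-to-end pipeline:
# simulate -> (genotype) -> mosaicism -> score -> associate.
# Tables are TSV/CSV with '.' for missing values and '#' provenance
# headers; statistical summaries are JSON.

.provenance_header <- function(seed, inputs = character(0)) {
  h <- c(paste0("# httex1 ", as.character(utils::packageVersion("httex1"))),
         paste0("# seed: ", seed))
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    h <- c(h, paste0("# input ", basename(inputs), " md5: ", sums))
  }
  h
}

#' Write a table with a provenance header
#'
#' TSV (or CSV) with `#` comment lines carrying the tool version, seed and
#' input checksums; missing values are written as `.`.
#'
#' @param x Data frame.
#' @param path Output path (`.csv` switches to comma separation).
#' @param seed Seed recorded in the header.
#' @param inputs Paths of input files whose md5 sums are recorded.
#' @export
write_table_prov <- function(x, path, seed = NA, inputs = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(seed, inputs), con)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(x, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a pipeline table
#'
#' Reads TSV/CSV written by [write_table_prov()] (skips `#` headers,
#' `.` means missing).
#'
#' @param path File path.
#' @export
read_table_prov <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    na.strings = ".", stringsAsFactors = FALSE)
}

.check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing ", what, " column(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

.fit_json <- function(fit) {
  if (inherits(fit, "se_fit") || inherits(fit, "outcome_fit")) {
    out <- list(model = fit$model_name, n = fit$n,
                r_squared = fit$r_squared,
                coefficients = cbind(term = rownames(fit$coefficients),
                                     fit$coefficients))
    if (!is.null(fit$lsmeans)) out$lsmeans <- fit$lsmeans
    out
  } else {
    list(model = fit$model_name, n = fit$n, n_events = fit$n_events,
         log_likelihood = fit$loglik,
         hazard_ratios = cbind(term = rownames(fit$hr_table),
                               fit$hr_table))
  }
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order — simulate, mosaicism (expansion
#' ratios from the simulated read-count distributions), score (SEQT / SEQ1 /
#' SEQ1Q2, bootstrap model comparison, permutation model comparison,
#' somatic expansion scores), clinical association (AAO Cox models with
#' permutation p-values and adjusted survival, baseline TMS / progression /
#' TMS- and TFC-rate models with least-square means, FDR per family), and
#' SNP association (per-cohort regressions, Hardy-Weinberg checks,
#' meta-analysis) — writing every table and summary under `out_dir`. All
#' randomness derives from `seed`; rerunning with the same configuration
#' gives byte-identical outputs. Stage timings are logged to standard
#' error.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_participants,seed,n_perm,n_boot Pipeline-scale parameters.
#' @param config A [synth_config()] overriding `n_participants`/`seed`, or
#'   `NULL` for defaults.
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(out_dir, n_participants = 200L, seed = 17L,
                         n_perm = 999L, n_boot = 500L, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- force(expr)
    message(sprintf("[httex1] stage %-10s %6.1fs", name,
                    proc.time()[3] - t0))
    r
  }
  cfg <- if (is.null(config))
    synth_config(n_participants = n_participants, seed = seed)
  else config
  # -- simulate ----------------------------------------------------------
  cohort <- stage("simulate", gen_cohort(cfg, reads = TRUE))
  ppl <- cohort$participants
  pheno_path <- file.path(out_dir, "phenotypes.csv")
  write_table_prov(ppl, pheno_path, seed = cfg$seed)
  write_table_prov(cohort$visits, file.path(out_dir, "visits.csv"),
                   seed = cfg$seed)
  write_table_prov(cbind(id = ppl$id, cohort$snps),
                   file.path(out_dir, "snps.tsv"), seed = cfg$seed)
  counts_path <- file.path(out_dir, "read_counts.tsv")
  write_table_prov(cohort$read_counts, counts_path, seed = cfg$seed)
  # -- mosaicism ---------------------------------------------------------
  .check_columns(ppl, c("id", "age", "sex", "cohort", "q1", "q2", "qt",
                        "qfl", "manifest", "onset_age", "censor_age",
                        "baseline_tms", "progression"), "phenotype")
  mos <- stage("mosaicism", mosaicism_table(cohort$read_counts))
  write_table_prov(mos, file.path(out_dir, "mosaicism.tsv"),
                   seed = cfg$seed, inputs = counts_path)
  ppl$expansion_ratio <-
    mos$expansion_ratio[match(ppl$id, mos$sample_id)]
  # -- score -------------------------------------------------------------
  score_stage <- stage("score", {
    fit_qt <- fit_se_model(ppl, "QT")
    fit_q1 <- fit_se_model(ppl, "Q1")
    fit_q1q2 <- fit_se_model(ppl, "Q1", include_q2 = TRUE)
    cmp <- compare_models_bootstrap(
      ppl, function(d) fit_se_model(d, "Q1"),
      function(d) fit_se_model(d, "QT"),
      statistic = "r_squared", n_boot = n_boot, seed = cfg$seed)
    anova_q2 <- permutation_anova(fit_q1, fit_q1q2, n_perm = n_perm,
                                  seed = cfg$seed)
    perm_q2 <- permute_q2(fit_q1q2, n_perm = n_perm, seed = cfg$seed)
    list(fit_qt = fit_qt, fit_q1 = fit_q1, fit_q1q2 = fit_q1q2,
         cmp = cmp, anova_q2 = anova_q2, perm_q2 = perm_q2)
  })
  ppl$expansion_score <- somatic_expansion_score(score_stage$fit_q1, ppl)
  write_table_prov(ppl[c("id", "expansion_ratio", "expansion_score")],
                   file.path(out_dir, "scores.tsv"), seed = cfg$seed)
  se_json <- list(
    models = lapply(score_stage[c("fit_qt", "fit_q1", "fit_q1q2")],
                    .fit_json),
    r2_comparison_Q1_minus_QT = list(
      difference = score_stage$cmp$difference,
      bca_ci = as.list(score_stage$cmp$ci), n_boot = n_boot),
    q2_model_comparison = as.list(score_stage$anova_q2),
    q2_term_permutation = score_stage$perm_q2)
  jsonlite::write_json(se_json, file.path(out_dir, "se_models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # -- clinical association ---------------------------------------------
  clin <- stage("associate", {
    rates <- participant_slopes(cohort$visits)
    ppl <- merge(ppl, rates, by.x = "id", by.y = "participant_id",
                 sort = FALSE)
    aao_qt <- fit_cox(ppl, "QT")
    aao_q1 <- fit_cox(ppl, "Q1")
    aao_q1q2 <- fit_cox(ppl, "Q1", include_q2 = TRUE,
                        include_score = "linear")
    aao_qflq2 <- fit_cox(ppl, "QFL", include_q2 = TRUE,
                         include_score = "linear")
    aao_sign <- fit_cox(ppl, "Q1", include_score = "sign")
    ph <- check_proportional_hazards(aao_q1q2)
    perm_aao <- permute_q2(aao_q1q2, n_perm = n_perm, seed = cfg$seed)
    surv_q2 <- adjusted_survival(aao_q1q2, "q2")
    surv_sign <- adjusted_survival(aao_sign, "score_sign")
    tms_q1q2 <- fit_outcome_linear(ppl, "baseline_tms", "Q1")
    tms_qflq2 <- fit_outcome_linear(ppl, "baseline_tms", "QFL")
    prog_q1 <- fit_outcome_linear(ppl, "progression", "Q1")
    prog_qfl <- fit_outcome_linear(ppl, "progression", "QFL")
    tmsrate <- fit_outcome_linear(ppl, "tms_rate", "Q1")
    tfcrate <- fit_outcome_linear(ppl, "tfc_rate", "Q1")
    perm_tms <- permute_q2(tms_q1q2, n_perm = n_perm, seed = cfg$seed)
    list(ppl = ppl, aao = list(AAOQT = aao_qt, AAOQ1 = aao_q1,
                               AAOQ1Q2 = aao_q1q2, AAOQFLQ2 = aao_qflq2),
         aao_sign = aao_sign, ph = ph, perm_aao = perm_aao,
         surv_q2 = surv_q2, surv_sign = surv_sign,
         outcomes = list(TMSQ1Q2 = tms_q1q2, TMSQFLQ2 = tms_qflq2,
                         ProgQ1 = prog_q1, ProgQFL = prog_qfl,
                         TMSrateQ1Q2 = tmsrate, TFCrateQ1Q2 = tfcrate),
         perm_tms = perm_tms)
  })
  # FDR within families: AAO Q2 terms; baseline TMS Q2 terms
  perm_aao <- clin$perm_aao
  perm_aao$p_fdr <- bh_fdr(perm_aao$p, family = "AAO")
  perm_tms <- clin$perm_tms
  perm_tms$p_fdr <- bh_fdr(perm_tms$p, family = "baseline_TMS")
  write_table_prov(rbind(cbind(family = "AAO", perm_aao),
                         cbind(family = "baseline_TMS", perm_tms)),
                   file.path(out_dir, "permutation_results.tsv"),
                   seed = cfg$seed)
  surv_tab <- do.call(rbind, lapply(
    c(clin$surv_q2, clin$surv_sign), function(g)
      data.frame(group = g$group, median_onset = g$median,
                 ci_lower = g$median_ci[1], ci_upper = g$median_ci[2])))
  write_table_prov(surv_tab, file.path(out_dir, "survival_summaries.tsv"),
                   seed = cfg$seed)
  clin_json <- list(
    aao_models = lapply(clin$aao, .fit_json),
    proportional_hazards = cbind(term = rownames(clin$ph), clin$ph),
    outcome_models = lapply(clin$outcomes, .fit_json))
  jsonlite::write_json(clin_json, file.path(out_dir, "clinical_models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # -- SNP association ---------------------------------------------------
  snp <- stage("snp", {
    ppl <- clin$ppl
    per_cohort <- lapply(split(seq_len(nrow(ppl)), ppl$cohort),
                         function(idx)
                           snp_assoc_table(cohort$snps[idx, , drop = FALSE],
                                           ppl[idx, , drop = FALSE],
                                           snp_info = cohort$snp_info))
    meta <- do.call(rbind, lapply(cohort$snp_info$rsid, function(rs) {
      per <- lapply(per_cohort, function(tab) tab[tab$rsid == rs, ])
      m <- meta_sample_size_weighted(
        p = vapply(per, function(x) x$p, numeric(1)),
        beta_sign = vapply(per, function(x) x$beta, numeric(1)),
        n = vapply(per, function(x) x$n, numeric(1)))
      data.frame(rsid = rs, z = m$z, p = m$p, stringsAsFactors = FALSE)
    }))
    meta$p_fdr <- bh_fdr(meta$p, family = "snp_meta")
    list(per_cohort = per_cohort, meta = meta)
  })
  for (cn in names(snp$per_cohort))
    write_table_prov(snp$per_cohort[[cn]],
                     file.path(out_dir, paste0("snp_", cn, ".tsv")),
                     seed = cfg$seed)
  write_table_prov(snp$meta, file.path(out_dir, "snp_meta.tsv"),
                   seed = cfg$seed)
  jsonlite::write_json(
    list(seed = cfg$seed, n_participants = cfg$n_participants,
         n_perm = n_perm, n_boot = n_boot),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  message(sprintf("[httex1] pipeline done in %.1fs",
                  proc.time()[3] - t_all))
  invisible(list(cohort = cohort, score = score_stage, clinical = clin,
                 snp = snp, out_dir = out_dir))
}
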