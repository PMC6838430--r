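# Seeded synthetic-data generator. Emulates every input the pipeline
# consumes: repeat-structure alleles at the observed population
# frequencies, stutter-contaminated read-length distributions (and FASTQ
# realizations), and full two-cohort participant tables whose statistical
# structure is the analysis models run forward.

#' Configuration for the synthetic-data generator
#'
#' Returns the full generator configuration with defaults calibrated to the
#' published cohort characteristics: disease-allele structure frequencies
#' (typical CAACAG-cassette alleles ~96%, duplication ~2.5%, deletion ~1%,
#' lone-CAA interruption ~0.5%), pure CAG drawn on 40-50 with mean ~43.2,
#' ages ~N(47.8, 11.8) truncated to 18-75, 54% female, two cohorts sized
#' 203:531. The expansion-ratio surface (intercept 0.45, age slope
#' 0.006/yr, Q1 slope 0.06/CAG, age-by-Q1 0.0015) and its noise components
#' (individual SD 0.065 including SNP effects, measurement SD 0.026) give
#' an analytic model r-squared near 0.84. Onset ages follow a Weibull(4,
#' 50.4) baseline (median onset ~46 y) under proportional hazards with a
#' score log-hazard of log(3.05) and a Q2 = 0 log-hazard of 1 (~10 y
#' earlier onset); baseline TMS carries a +2.3-unit Q2 = 0 shift; SNP
#' effects on the score sit at beta ~0.03-0.06. All defaults are
#' overridable via `...`.
#'
#' @param n_participants Cohort size (default 734).
#' @param seed Integer seed stored in the config (used by [gen_cohort()]).
#' @param ... Named overrides of any default listed below.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 734L, seed = 1L, ...) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    seed = as.integer(seed),
    # disease-allele structure frequency table (code: q1 slot left symbolic)
    structure_freqs = data.frame(
      name = c("typical", "duplication", "deletion", "caa_interrupt"),
      prob = c(0.960, 0.025, 0.010, 0.005),
      extra_caa = c(0L, 0L, 0L, 1L),
      caacag = c(1L, 2L, 0L, 1L),
      ccgcca = c(1L, 1L, 1L, 1L),
      p2 = c(7L, 7L, 7L, 7L),
      p3 = c(2L, 3L, 2L, 2L),
      stringsAsFactors = FALSE),
    q1_range = 40:50,
    q1_mean = 43.2, q1_sd = 2.3,
    normal_q1_range = 15:30, normal_q1_mode = 17L,
    # demographics
    age_mean = 47.8, age_sd = 11.8, age_range = c(18, 75),
    p_female = 0.54,
    cohorts = c(TRACK = 203, ENROLL = 531),
    # expansion-ratio linear model (centred at age_ref / q1_ref)
    age_ref = 47.8, q1_ref = 43.2,
    se_intercept = 0.45, se_age = 0.006, se_q1 = 0.06,
    se_age_q1 = 0.0015, se_sex = -0.01, se_cohort = 0.02,
    se_q2_shift = c(`0` = 0, `3` = 0, `4` = 0),
    ind_sd = 0.065, noise_sd = 0.026,
    # sequencing / stutter model
    depth = 1000L,
    stutter_down_mass = 0.9, stutter_down_decay = 0.55,
    stutter_up_mass = 0.002, stutter_up_decay = 0.3,
    expansion_decay = 0.5,
    flank5 = "GCGACCCTGGAAAAGCTGAT", flank3 = "CCTCCTCAGCTTCCTCAGCC",
    # time-to-onset model (Weibull baseline, proportional hazards)
    weibull_shape = 4, weibull_scale = 50.4,
    loghr_q1 = 0.45, loghr_score = log(3.05),
    loghr_q2 = c(`0` = 1.0, `3` = 0, `4` = 0),
    followup_range = c(2, 8),
    # baseline TMS / TFC and progression
    tms_intercept = 20, tms_q1 = 2.0, tms_age = 0.6, tms_score = 10,
    tms_q2 = c(`0` = 2.3, `3` = 0, `4` = 0), tms_sd = 8,
    tfc_intercept = 11.9, tfc_q1 = -0.3, tfc_age = -0.05, tfc_score = -2,
    tfc_q2 = c(`0` = -0.5, `3` = 0, `4` = 0), tfc_sd = 1.7,
    prog_score = 0.98, prog_q2 = c(`0` = 2.2, `3` = 0, `4` = -0.74),
    prog_sd = 1,
    # longitudinal visits (years 0..3)
    visit_years = 0:3,
    tms_rate_mean = 2.0, tms_rate_q1 = 0.25, tms_rate_score = 1.7,
    tms_rate_q2 = c(`0` = 1.0, `3` = 0, `4` = -0.3), tms_rate_sd = 1.2,
    tms_visit_sd = 3,
    tfc_rate_mean = -0.6, tfc_rate_q1 = -0.05, tfc_rate_score = -0.12,
    tfc_rate_q2 = c(`0` = -0.8, `3` = 0, `4` = 0.1), tfc_rate_sd = 0.35,
    tfc_visit_sd = 1,
    # candidate-SNP panel: betas act on the individual score component
    snp_panel = data.frame(
      rsid = c("rs3512", "rs175080", "rs1799977", "rs1382539",
               "rs2140734", "rs20579"),
      gene = c("FAN1", "MLH3", "MLH1", "MSH3", "FAN1", "LIG1"),
      maf = c(0.34, 0.27, 0.24, 0.28, 0.35, 0.30),
      beta = c(0.050, -0.029, -0.034, -0.023, 0.040, 0.000),
      stringsAsFactors = FALSE))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (abs(sum(cfg$structure_freqs$prob) - 1) > 1e-8)
    stop("structure frequencies must sum to 1")
  stopifnot(cfg$depth > 0, cfg$ind_sd >= 0, cfg$noise_sd >= 0)
  class(cfg) <- "synth_config"
  cfg
}

# truncated-normal draw by rejection (ranges are wide; this is cheap)
.rtnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

.draw_structure <- function(cfg, n, q1) {
  f <- cfg$structure_freqs
  idx <- sample.int(nrow(f), n, replace = TRUE, prob = f$prob)
  lapply(seq_len(n), function(i)
    allele_structure(q1 = q1[i], extra_caa = f$extra_caa[idx[i]],
                     caacag = f$caacag[idx[i]], ccgcca = f$ccgcca[idx[i]],
                     p2 = f$p2[idx[i]], p3 = f$p3[idx[i]]))
}

#' Draw allele pairs (normal and disease) for n individuals
#'
#' Disease-allele pure CAG lengths are drawn on the inclusion range (40-50,
#' discretized normal weights), structures from the configured frequency
#' table; normal-allele lengths are drawn below the disease range with a
#' mode at 17 CAG. All emitted disease alleles pass [pure_cag_inclusion()]
#' by construction.
#'
#' @param cfg A [synth_config()].
#' @param n Number of individuals (defaults to `cfg$n_participants`).
#' @return A list with elements `normal` and `disease`, each a list of
#'   [allele_structure()].
#' @export
gen_alleles <- function(cfg, n = cfg$n_participants) {
  w <- stats::dnorm(cfg$q1_range, cfg$q1_mean, cfg$q1_sd)
  q1_dis <- sample(cfg$q1_range, n, replace = TRUE, prob = w)
  wn <- stats::dnorm(cfg$normal_q1_range, cfg$normal_q1_mode, 3)
  q1_nor <- sample(cfg$normal_q1_range, n, replace = TRUE, prob = wn)
  list(normal = .draw_structure(cfg, n, q1_nor),
       disease = .draw_structure(cfg, n, q1_dis))
}

#' Simulate a stutter-contaminated read-length distribution
#'
#' Multinomial draw over CAG lengths around the progenitor: unit mass at
#' the progenitor, a heavy downward PCR-slippage tail with geometric decay,
#' a very small upward slippage tail, and a somatic-expansion tail above
#' the progenitor whose total mass relative to the progenitor equals the
#' target expansion ratio (so the definitional count ratio is unbiased for
#' `target_ratio` in expectation).
#'
#' @param cfg A [synth_config()].
#' @param structure Disease-allele [allele_structure()] (its `q1` is the
#'   progenitor length).
#' @param target_ratio Target expansion ratio (negative values are
#'   truncated to 0 with a flag).
#' @param depth Sequencing depth (default `cfg$depth`).
#' @return A [read_length_dist()]; attribute `truncated` marks a negative
#'   target.
#' @export
gen_read_distribution <- function(cfg, structure, target_ratio,
                                  depth = cfg$depth) {
  stopifnot(depth > 0)
  truncated <- FALSE
  if (target_ratio < 0) {
    target_ratio <- 0
    truncated <- TRUE
  }
  q1 <- structure$q1
  kdn <- seq_len(min(10L, q1 - 1L))
  kup <- 1:15
  up_mass <- min(cfg$stutter_up_mass, target_ratio)
  exp_mass <- target_ratio - up_mass
  w_dn <- cfg$stutter_down_mass * (1 - cfg$stutter_down_decay) *
    cfg$stutter_down_decay^(kdn - 1)
  w_up <- up_mass * (1 - cfg$stutter_up_decay) *
    cfg$stutter_up_decay^(kup - 1) +
    exp_mass * (1 - cfg$expansion_decay) * cfg$expansion_decay^(kup - 1)
  # renormalize the truncated upper tail so expected ratio is exact
  if (sum(w_up) > 0 && target_ratio > 0)
    w_up <- w_up * target_ratio / sum(w_up)
  lens <- c(q1 - rev(kdn), q1, q1 + kup)
  w <- c(rev(w_dn), 1, w_up)
  cnt <- stats::rmultinom(1, size = depth, prob = w / sum(w))[, 1]
  keep <- cnt > 0
  d <- read_length_dist(stats::setNames(cnt[keep], lens[keep]),
                        allele_label = attr(structure, "allele_label") %||%
                          "disease")
  attr(d, "truncated") <- truncated
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Realize a read-length distribution as FASTQ
#'
#' Expands each counted CAG length into a literal nucleotide read via
#' [to_sequence()] (the non-CAG cassette blocks are held at the allele's
#' structure), adds the configured constant flanks, and writes
#' Sanger-scaled FASTQ with uniform quality.
#'
#' @param cfg A [synth_config()].
#' @param structure The allele's [allele_structure()].
#' @param dist A [read_length_dist()] over pure-CAG lengths.
#' @param path Output FASTQ path.
#' @param sample_id Read-name prefix.
#' @param qual_char Quality character (default `"I"`, Phred 40).
#' @return Invisibly, the number of reads written.
#' @export
gen_reads_fastq <- function(cfg, structure, dist, path,
                            sample_id = "sample", qual_char = "I") {
  lens <- as.integer(names(dist))
  seqs <- character(sum(dist))
  j <- 0L
  for (i in seq_along(lens)) {
    s <- structure
    s$q1 <- lens[i]
    body <- to_sequence(allele_structure(lens[i], structure$extra_caa,
                                         structure$caacag,
                                         structure$ccgcca, structure$p2,
                                         structure$p3))
    read <- paste0(cfg$flank5, body, cfg$flank3)
    idx <- j + seq_len(dist[i])
    seqs[idx] <- read
    j <- j + dist[i]
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste0(sample_id, "_read", seq_along(seqs))
  qual <- Biostrings::PhredQuality(strrep(qual_char, nchar(seqs)))
  xq <- Biostrings::QualityScaledDNAStringSet(x, qual)
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(length(seqs))
}

.q2_effect <- function(tab, q2) {
  out <- numeric(length(q2))
  hit <- match(as.character(q2), names(tab))
  out[!is.na(hit)] <- tab[hit[!is.na(hit)]]
  out
}

#' Generate a full synthetic cohort
#'
#' Draws participants (alleles, demographics, cohort labels), then runs the
#' analysis models forward: the expansion ratio follows the configured
#' linear surface in age and pure CAG (plus sex/cohort shifts), an
#' individual-specific propensity (which the SNP panel perturbs
#' additively), and measurement noise, truncated at 0; onset ages come from
#' the Weibull-baseline proportional-hazards model driven by centred Q1,
#' the individual propensity and Q2 category, with censoring at a simulated
#' last-visit age; baseline TMS/TFC, the progression score and longitudinal
#' TMS/TFC trajectories follow the configured linear/mixed models; SNP
#' dosages are drawn in Hardy-Weinberg proportions. Everything is
#' reproducible from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param reads Also simulate per-participant disease-allele read-count
#'   distributions (column-bound long table in `$read_counts`)? Default
#'   `FALSE`.
#' @return A list of class `synth_cohort`: `participants` (one row per
#'   individual), `visits` (long TMS/TFC trajectories), `snps` (dosage
#'   matrix as data frame), `snp_info`, `truth` (the generator's latent
#'   individual effects and the config), and optionally `read_counts`.
#' @export
gen_cohort <- function(cfg, reads = FALSE) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_participants
  al <- gen_alleles(cfg, n)
  q1 <- vapply(al$disease, function(s) s$q1, integer(1))
  q2 <- vapply(al$disease, function(s) s$q2, integer(1))
  qt <- q1 + q2
  qfl <- vapply(al$disease, fragment_length_estimate, integer(1))
  age <- .rtnorm(n, cfg$age_mean, cfg$age_sd, cfg$age_range[1],
                 cfg$age_range[2])
  sex <- ifelse(stats::runif(n) < cfg$p_female, "female", "male")
  cohort <- sample(names(cfg$cohorts), n, replace = TRUE,
                   prob = cfg$cohorts / sum(cfg$cohorts))
  # SNP dosages in HWE; effects perturb the individual propensity
  panel <- cfg$snp_panel
  dos <- vapply(seq_len(nrow(panel)), function(j)
    stats::rbinom(n, 2L, panel$maf[j]), integer(n))
  colnames(dos) <- panel$rsid
  snp_var <- sum(panel$beta^2 * 2 * panel$maf * (1 - panel$maf))
  resid_sd <- sqrt(max(cfg$ind_sd^2 - snp_var, 0))
  ind <- stats::rnorm(n, 0, resid_sd) +
    drop(dos %*% panel$beta) - sum(panel$beta * 2 * panel$maf)
  age_c <- age - cfg$age_ref
  q1_c <- q1 - cfg$q1_ref
  ratio_mean <- cfg$se_intercept + cfg$se_age * age_c + cfg$se_q1 * q1_c +
    cfg$se_age_q1 * age_c * q1_c + cfg$se_sex * (sex == "male") +
    cfg$se_cohort * (cohort == names(cfg$cohorts)[2]) +
    .q2_effect(cfg$se_q2_shift, q2)
  target_ratio <- ratio_mean + ind
  ratio <- target_ratio + stats::rnorm(n, 0, cfg$noise_sd)
  n_truncated <- sum(ratio < 0)
  ratio <- pmax(ratio, 0)
  # time to motor onset: Weibull baseline, proportional hazards
  lp <- cfg$loghr_q1 * q1_c + cfg$loghr_score * ind +
    .q2_effect(cfg$loghr_q2, q2)
  u <- stats::runif(n)
  onset <- cfg$weibull_scale * (-log(u) / exp(lp))^(1 / cfg$weibull_shape)
  censor_age <- age + stats::runif(n, cfg$followup_range[1],
                                   cfg$followup_range[2])
  manifest <- onset <= censor_age
  # baseline clinical outcomes
  tms <- cfg$tms_intercept + cfg$tms_q1 * q1_c + cfg$tms_age * age_c +
    cfg$tms_score * ind + .q2_effect(cfg$tms_q2, q2) +
    stats::rnorm(n, 0, cfg$tms_sd)
  tfc <- cfg$tfc_intercept + cfg$tfc_q1 * q1_c + cfg$tfc_age * age_c +
    cfg$tfc_score * ind + .q2_effect(cfg$tfc_q2, q2) +
    stats::rnorm(n, 0, cfg$tfc_sd)
  prog <- cfg$prog_score * ind + .q2_effect(cfg$prog_q2, q2) +
    stats::rnorm(n, 0, cfg$prog_sd)
  # longitudinal trajectories with participant-specific random slopes
  tms_slope <- cfg$tms_rate_mean + cfg$tms_rate_q1 * q1_c +
    cfg$tms_rate_score * ind + .q2_effect(cfg$tms_rate_q2, q2) +
    stats::rnorm(n, 0, cfg$tms_rate_sd)
  tfc_slope <- cfg$tfc_rate_mean + cfg$tfc_rate_q1 * q1_c +
    cfg$tfc_rate_score * ind + .q2_effect(cfg$tfc_rate_q2, q2) +
    stats::rnorm(n, 0, cfg$tfc_rate_sd)
  ids <- sprintf("P%04d", seq_len(n))
  nv <- length(cfg$visit_years)
  yrs <- rep(cfg$visit_years, times = n)
  pid <- rep(seq_len(n), each = nv)
  visits <- data.frame(
    participant_id = ids[pid], years_followup = yrs,
    tms = tms[pid] + tms_slope[pid] * yrs +
      stats::rnorm(n * nv, 0, cfg$tms_visit_sd),
    tfc = tfc[pid] + tfc_slope[pid] * yrs +
      stats::rnorm(n * nv, 0, cfg$tfc_visit_sd),
    stringsAsFactors = FALSE)
  participants <- data.frame(
    id = ids, age = age, age_baseline = age, sex = sex, cohort = cohort,
    q1 = q1, q2 = q2, qt = qt, qfl = qfl,
    structure_code = vapply(al$disease, structure_code, character(1)),
    normal_q1 = vapply(al$normal, function(s) s$q1, integer(1)),
    expansion_ratio = ratio,
    manifest = manifest,
    onset_age = ifelse(manifest, onset, NA_real_),
    censor_age = censor_age,
    baseline_tms = tms, baseline_tfc = tfc, progression = prog,
    stringsAsFactors = FALSE)
  out <- list(participants = participants, visits = visits,
              snps = as.data.frame(dos), snp_info = panel,
              truth = list(ind = ind, target_ratio = target_ratio,
                           tms_slope = tms_slope, tfc_slope = tfc_slope,
                           n_truncated = n_truncated, config = cfg))
  if (reads) {
    rc <- do.call(rbind, lapply(seq_len(n), function(i) {
      d <- gen_read_distribution(cfg, al$disease[[i]], target_ratio[i])
      data.frame(sample_id = ids[i], allele_label = "disease",
                 cag_length = as.integer(names(d)), count = as.numeric(d),
                 stringsAsFactors = FALSE)
    }))
    out$read_counts <- rc
  }
  class(out) <- "synth_cohort"
  out
}

#' @export
print.synth_cohort <- function(x, ...) {
  p <- x$participants
  cat("<synth_cohort> n = ", nrow(p), " (", sum(p$manifest),
      " manifest); cohorts: ",
      paste(names(table(p$cohort)), table(p$cohort), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
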