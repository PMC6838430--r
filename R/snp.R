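# Candidate-SNP association with the somatic expansion score,
# Hardy-Weinberg exact testing, and sample-size-weighted meta-analysis.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the heterozygote count given the allele
#' counts: enumerates every heterozygote configuration compatible with the
#' observed allele counts, computes its conditional probability, and sums
#' the probabilities of all configurations no more probable than the
#' observed one (two-sided by probability ordering, the standard exact HWE
#' formulation). A `midp` flag halves the observed configuration's
#' contribution. Monomorphic markers return p = 1 with a flag.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (A the minor allele).
#' @param midp Use the mid-p variant? Default `FALSE` (plain exact test).
#' @return p-value, with attribute `monomorphic` when the marker has only
#'   one allele.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa, midp = FALSE) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("no genotypes")
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0) {
    p <- 1
    attr(p, "monomorphic") <- TRUE
    return(p)
  }
  # heterozygote counts share the parity of the minor-allele count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log conditional probability of each het count given allele counts
  logp <- vapply(hets, function(h) {
    a <- (n_minor - h) / 2         # minor homozygotes
    b <- n - a - h                 # major homozygotes
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- which(hets == n_Aa)
  if (length(obs) == 0L)
    stop("heterozygote count incompatible with allele counts")
  sel <- prob <= prob[obs] * (1 + 1e-10)
  p <- sum(prob[sel])
  if (midp) p <- p - prob[obs] / 2
  min(p, 1)
}

#' Additive-dosage regression of the somatic expansion score on one SNP
#'
#' Linear regression of the expansion score on minor-allele dosage (0/1/2)
#' with sex as the only covariate; two-sided p from the t statistic.
#' Missing genotypes are dropped (complete-case). A monomorphic SNP is not
#' testable; a single-sex cohort drops the sex covariate with a warning.
#'
#' @param score Numeric vector of somatic expansion scores.
#' @param dosage Integer vector of minor-allele dosages in `{0, 1, 2}`.
#' @param sex Factor or character vector.
#' @return A list: `beta`, `se`, `p`, `n`, `maf`, `testable`.
#' @export
snp_score_regression <- function(score, dosage, sex) {
  ok <- !is.na(score) & !is.na(dosage) & !is.na(sex)
  score <- score[ok]; dosage <- dosage[ok]; sex <- factor(sex[ok])
  if (!all(dosage %in% 0:2)) stop("dosages must be in {0, 1, 2}")
  n <- length(score)
  if (length(unique(dosage)) < 2L) {
    warning("monomorphic SNP: association not testable")
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                maf = sum(dosage) / (2 * n), testable = FALSE))
  }
  if (nlevels(sex) < 2L) {
    warning("single-sex cohort: dropping the sex covariate")
    fit <- stats::lm(score ~ dosage)
  } else {
    fit <- stats::lm(score ~ dosage + sex)
  }
  sm <- summary(fit)$coefficients["dosage", ]
  list(beta = unname(sm[1]), se = unname(sm[2]), p = unname(sm[4]), n = n,
       maf = min(mean(dosage) / 2, 1 - mean(dosage) / 2), testable = TRUE)
}

#' Per-cohort SNP association table
#'
#' Runs [snp_score_regression()] and [hwe_exact_test()] for every SNP in a
#' dosage table and applies FDR correction within the SNP family.
#'
#' @param dosages Data frame or matrix of minor-allele dosages, one column
#'   per SNP (rsID column names), rows aligned with `pheno`.
#' @param pheno Data frame with `expansion_score` and `sex`.
#' @param snp_info Optional data frame with `rsid`, `gene`, `a1`, `a2`
#'   merged into the output.
#' @return Data frame: `rsid, n, maf, hwe_p, beta, se, p, p_fdr`.
#' @export
snp_assoc_table <- function(dosages, pheno, snp_info = NULL) {
  rows <- lapply(colnames(dosages), function(rs) {
    dos <- dosages[, rs]
    r <- suppressWarnings(
      snp_score_regression(pheno$expansion_score, dos, pheno$sex))
    cc <- dos[!is.na(dos)]
    hwe <- hwe_exact_test(sum(cc == 2), sum(cc == 1), sum(cc == 0))
    data.frame(rsid = rs, n = r$n, maf = r$maf, hwe_p = as.numeric(hwe),
               beta = r$beta, se = r$se, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p, family = "snp_association")
  if (!is.null(snp_info)) {
    keep <- intersect(c("rsid", "chromosome", "gene", "a1", "a2"),
                      names(snp_info))
    out <- merge(snp_info[keep], out, by = "rsid", sort = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Sample-size-weighted meta-analysis of SNP associations
#'
#' Combines per-cohort two-sided p-values and effect directions in the
#' weighted-z scheme: each study contributes a signed z,
#' `z_i = sign(beta_i) * qnorm(1 - p_i/2)`, with weight `w_i = sqrt(n_i)`;
#' the combined statistic is `sum(w_i z_i) / sqrt(sum(w_i^2))` and the
#' combined p is two-sided normal.
#'
#' @param p Per-study two-sided p-values.
#' @param beta_sign Per-study effect directions (+1/-1, or the betas
#'   themselves: only the sign is used).
#' @param n Per-study analyzed sample sizes.
#' @return A list of class `meta_result`: `z`, `p`, `per_study` (data frame
#'   of inputs and signed z), `k`.
#' @export
meta_sample_size_weighted <- function(p, beta_sign, n) {
  k <- length(p)
  stopifnot(length(beta_sign) == k, length(n) == k, k >= 1)
  eps <- 1e-300
  if (any(p <= 0 | p >= 1)) {
    warning("p-values at 0 or 1 clamped for the normal-quantile transform")
    p <- pmin(pmax(p, eps), 1 - 1e-16)
  }
  z_i <- sign(beta_sign) * stats::qnorm(1 - p / 2)
  w <- sqrt(n)
  z <- sum(w * z_i) / sqrt(sum(w^2))
  out <- list(z = z, p = 2 * stats::pnorm(-abs(z)),
              per_study = data.frame(p = p, sign = sign(beta_sign), n = n,
                                     z = z_i),
              k = k)
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat("Sample-size-weighted meta-analysis of ", x$k, " studies: z = ",
      format(x$z, digits = 4), ", p = ", format(x$p, digits = 3), "\n",
      sep = "")
  invisible(x)
}
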