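# Permutation p-values for Q2 terms. Because only a handful of
# participants carry atypical alleles, asymptotic p-values for Q2 terms are
# unreliable; instead the Q2 labels are permuted across participants with
# every other column fixed, and the observed t (linear) or z (Cox)
# statistic is referred to its permutation null.

# least-squares fit statistics via the normal equations; X is assumed
# full rank (rank-deficient permutations return NULL and are dropped)
.lm_fit_stats <- function(X, y) {
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  V <- chol2inv(ch)
  beta <- drop(V %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  df <- nrow(X) - ncol(X)
  se <- sqrt(diag(V) * rss / df)
  list(t = beta / se, rss = rss, df = df)
}

# engine for linear fits: returns obs stats and a refit(perm) closure that
# permutes the Q2 dummy rows (and rebuilds Q2-by-age interactions)
.q2_engine_lm <- function(fit) {
  lmfit <- fit$lm
  X <- stats::model.matrix(lmfit)
  y <- stats::model.response(stats::model.frame(lmfit))
  aliased <- is.na(stats::coef(lmfit))
  if (any(aliased)) X <- X[, !aliased, drop = FALSE]
  cn <- colnames(X)
  main_cols <- grep("^q2f[0-9]+$", cn)
  int_cols <- grep("^q2f[0-9]+:age_c$|^age_c:q2f[0-9]+$", cn)
  if (length(main_cols) == 0L)
    stop("model contains no Q2 terms")
  # pair each interaction column with its main-effect dummy
  int_levels <- sub(":?age_c:?", "", cn[int_cols])
  main_for_int <- main_cols[match(int_levels, cn[main_cols])]
  age <- if (length(int_cols)) X[, "age_c"] else NULL
  q2_cols <- c(main_cols, int_cols)
  refit <- function(perm) {
    Xp <- X
    Xp[, main_cols] <- X[perm, main_cols, drop = FALSE]
    if (length(int_cols))
      Xp[, int_cols] <- X[perm, main_for_int, drop = FALSE] * age
    st <- .lm_fit_stats(Xp, y)
    if (is.null(st)) return(NULL)
    list(stat = st$t[q2_cols], rss = st$rss, df = st$df)
  }
  obs <- .lm_fit_stats(X, y)
  list(obs = list(stat = obs$t[q2_cols], rss = obs$rss, df = obs$df),
       refit = refit, terms = cn[q2_cols], p_full = ncol(X),
       type = "t")
}

.q2_engine_cox <- function(fit) {
  d <- fit$data
  fml <- stats::formula(fit$coxph)
  terms_all <- names(stats::coef(fit$coxph))
  q2_terms <- grep("^q2f", terms_all, value = TRUE)
  if (length(q2_terms) == 0L) stop("model contains no Q2 terms")
  refit <- function(perm) {
    d2 <- d
    d2$q2f <- d$q2f[perm]
    f2 <- tryCatch(
      suppressWarnings(survival::coxph(fml, data = d2, ties = fit$ties)),
      error = function(e) NULL)
    if (is.null(f2)) return(NULL)
    z <- stats::coef(f2) / sqrt(diag(stats::vcov(f2)))
    list(stat = z[q2_terms], loglik = f2$loglik[length(f2$loglik)])
  }
  z_obs <- stats::coef(fit$coxph) / sqrt(diag(stats::vcov(fit$coxph)))
  list(obs = list(stat = z_obs[q2_terms],
                  loglik = fit$loglik),
       refit = refit, terms = q2_terms, type = "z")
}

.q2_engine <- function(fit) {
  if (inherits(fit, "se_fit") || inherits(fit, "outcome_fit"))
    .q2_engine_lm(fit)
  else if (inherits(fit, "cox_aao_fit"))
    .q2_engine_cox(fit)
  else stop("unsupported fit class: ", paste(class(fit), collapse = "/"))
}

#' Permutation p-values for Q2 terms of a fitted model
#'
#' Permutes the Q2 category labels across participants (all other columns
#' fixed), refits, and computes the two-sided permutation p-value of each
#' Q2 term's t (linear) or z (Cox) statistic with the add-one rule
#' `p = (1 + #\{|stat_perm| >= |stat_obs|\}) / (n_perm + 1)`, so the
#' smallest attainable p is `1/(n_perm + 1)`. Permutation refits that fail
#' (e.g. rank-deficient relabellings) are dropped and counted; more than 5%
#' failures triggers a reliability warning.
#'
#' @param fit A fitted `se_fit`, `outcome_fit` or `cox_aao_fit` containing
#'   Q2 terms.
#' @param n_perm Number of permutations (>= 100; the reference analysis
#'   uses 1e5).
#' @param seed Integer seed.
#' @param perm_matrix Optional integer matrix of explicit permutations (one
#'   row each); overrides random sampling, e.g. for exhaustive enumeration
#'   on small fixtures.
#' @return An object of class `permutation_result`: a data.frame with one
#'   row per Q2 term (`term`, `stat`, `n_perm`, `n_failed`, `p`) plus
#'   attributes `seed` and `type`.
#' @export
permute_q2 <- function(fit, n_perm = 1e5L, seed = 1L, perm_matrix = NULL) {
  eng <- .q2_engine(fit)
  n <- if (inherits(fit, "cox_aao_fit")) nrow(fit$data) else
    length(stats::residuals(fit$lm))
  if (is.null(perm_matrix)) {
    if (n_perm < 100L) stop("n_perm must be >= 100")
    set.seed(seed)
    perm_matrix <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                            integer(n)))
  }
  n_perm <- nrow(perm_matrix)
  stats_obs <- eng$obs$stat
  k <- length(stats_obs)
  exceed <- numeric(k)
  valid <- integer(k)
  for (b in seq_len(n_perm)) {
    r <- eng$refit(perm_matrix[b, ])
    if (is.null(r)) next
    ok <- is.finite(r$stat) & is.finite(stats_obs)
    valid[ok] <- valid[ok] + 1L
    exceed[ok] <- exceed[ok] + (abs(r$stat[ok]) >= abs(stats_obs[ok]))
  }
  n_failed <- n_perm - valid
  if (any(n_failed > 0.05 * n_perm))
    warning("more than 5% of permutation refits failed (up to ",
            max(n_failed), "/", n_perm, "); p-values may be unreliable")
  res <- data.frame(term = eng$terms,
                    stat = unname(stats_obs),
                    n_perm = valid,
                    n_failed = n_failed,
                    p = ifelse(is.finite(stats_obs) & valid > 0,
                               (1 + exceed) / (valid + 1), NA_real_),
                    stringsAsFactors = FALSE)
  attr(res, "seed") <- seed
  attr(res, "type") <- eng$type
  class(res) <- c("permutation_result", "data.frame")
  res
}

#' Permutation ANOVA comparing nested models with and without Q2 terms
#'
#' The observed F statistic (linear regressions) or likelihood-ratio
#' chi-squared (Cox regressions) for the Q2 block is referred to its
#' permutation null: Q2 labels are permuted, the larger model refitted, and
#' the statistic recomputed. The smaller model contains no Q2 terms, so its
#' fit is unchanged by the permutation. One-sided by construction (large
#' statistics are extreme), with the add-one rule.
#'
#' @param small_fit,big_fit Nested fits of the same class on the same data,
#'   differing only in the Q2 terms (e.g. SEQ1 vs SEQ1Q2, AAOQ1 vs
#'   AAOQ1Q2). Identical models give statistic 0 and p = 1.
#' @inheritParams permute_q2
#' @return A `permutation_result` with a single row (`term = "Q2_block"`).
#' @export
permutation_anova <- function(small_fit, big_fit, n_perm = 1e5L, seed = 1L,
                              perm_matrix = NULL) {
  if (!identical(class(small_fit), class(big_fit)))
    stop(errorCondition("models are not of the same class",
                        class = c("httex1_nesting_violation", "error",
                                  "condition")))
  is_cox <- inherits(big_fit, "cox_aao_fit")
  # the Q2-contrast model may have dropped the lone-CAA (q2 = 3) records;
  # the nested comparison then refits the smaller model on the same records
  if (small_fit$n != big_fit$n) {
    if (is_cox) {
      small_fit$coxph <- survival::coxph(stats::formula(small_fit$coxph),
                                         data = big_fit$data,
                                         ties = big_fit$ties)
      small_fit$loglik <-
        small_fit$coxph$loglik[length(small_fit$coxph$loglik)]
    } else {
      small_fit$lm <- stats::lm(stats::formula(small_fit$lm),
                                data = stats::model.frame(big_fit$lm))
    }
    small_fit$n <- big_fit$n
  }
  estimable <- function(f) {
    cf <- stats::coef(f)
    names(cf)[!is.na(cf)]
  }
  if (is_cox) {
    small_terms <- estimable(small_fit$coxph)
    big_terms <- estimable(big_fit$coxph)
  } else {
    small_terms <- estimable(small_fit$lm)
    big_terms <- estimable(big_fit$lm)
  }
  extra <- setdiff(big_terms, small_terms)
  if (!all(small_terms %in% big_terms) ||
      (length(extra) && !all(grepl("q2f", extra))))
    stop(errorCondition(
      "small model is not nested in the big model via Q2 terms only",
      class = c("httex1_nesting_violation", "error", "condition")))
  if (length(extra) == 0L) {
    res <- data.frame(term = "Q2_block", stat = 0, n_perm = 0L,
                      n_failed = 0L, p = 1, stringsAsFactors = FALSE)
    attr(res, "seed") <- seed
    class(res) <- c("permutation_result", "data.frame")
    return(res)
  }
  df_diff <- length(extra)
  if (is_cox) {
    stat_fun <- function(big_ll) 2 * (big_ll - small_fit$loglik)
    eng <- .q2_engine_cox(big_fit)
    obs <- stat_fun(eng$obs$loglik)
    get_stat <- function(r) stat_fun(r$loglik)
    n <- nrow(big_fit$data)
  } else {
    eng <- .q2_engine_lm(big_fit)
    rss_small <- sum(stats::residuals(small_fit$lm)^2)
    stat_fun <- function(rss_big, df_big)
      ((rss_small - rss_big) / df_diff) / (rss_big / df_big)
    obs <- stat_fun(eng$obs$rss, eng$obs$df)
    get_stat <- function(r) stat_fun(r$rss, r$df)
    n <- length(stats::residuals(big_fit$lm))
  }
  if (is.null(perm_matrix)) {
    if (n_perm < 100L) stop("n_perm must be >= 100")
    set.seed(seed)
    perm_matrix <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                            integer(n)))
  }
  n_perm <- nrow(perm_matrix)
  exceed <- 0L
  valid <- 0L
  for (b in seq_len(n_perm)) {
    r <- eng$refit(perm_matrix[b, ])
    if (is.null(r)) next
    s <- get_stat(r)
    if (!is.finite(s)) next
    valid <- valid + 1L
    if (s >= obs) exceed <- exceed + 1L
  }
  n_failed <- n_perm - valid
  if (n_failed > 0.05 * n_perm)
    warning("more than 5% of permutation refits failed (",
            n_failed, "/", n_perm, ")")
  res <- data.frame(term = "Q2_block", stat = obs, n_perm = valid,
                    n_failed = n_failed, p = (1 + exceed) / (valid + 1),
                    stringsAsFactors = FALSE)
  attr(res, "seed") <- seed
  attr(res, "type") <- if (is_cox) "chisq" else "F"
  class(res) <- c("permutation_result", "data.frame")
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test (", attr(x, "type"), " statistic, seed ",
      attr(x, "seed"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
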