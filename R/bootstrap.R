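# Nonparametric bootstrap comparison of equal-df models with BCA intervals.

# normal-quantile interpolation of the alpha-quantile of a bootstrap sample,
# as conventional for BCA endpoints
.norm_interp_quantile <- function(t, alpha) {
  ts <- sort(t)
  B <- length(ts)
  vapply(alpha, function(a) {
    r <- (B + 1) * a
    k <- floor(r)
    if (k <= 0) return(ts[1])
    if (k >= B) return(ts[B])
    qk <- stats::qnorm(k / (B + 1))
    qk1 <- stats::qnorm((k + 1) / (B + 1))
    frac <- (stats::qnorm(a) - qk) / (qk1 - qk)
    ts[k] + frac * (ts[k + 1] - ts[k])
  }, numeric(1))
}

#' Bias-corrected accelerated (BCA) bootstrap interval
#'
#' Computes the BCA interval from a bootstrap sample of a statistic: the
#' bias correction `z0` is the normal quantile of the proportion of
#' bootstrap values below the observed statistic, and the acceleration `a`
#' comes from the skewness of jackknife leave-one-out values. Endpoint
#' quantiles use normal-quantile interpolation of the order statistics.
#'
#' @param t0 Observed statistic.
#' @param t_boot Bootstrap replicates of the statistic.
#' @param t_jack Jackknife (leave-one-out) values of the statistic.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
bca_interval <- function(t0, t_boot, t_jack, conf = 0.95) {
  t_boot <- t_boot[is.finite(t_boot)]
  B <- length(t_boot)
  if (B >= 2L && stats::var(t_boot) == 0 && all(t_boot == t0))
    return(c(lower = t0, upper = t0))  # identical models: point interval
  if (B < 2L || stats::var(t_boot) == 0)
    stop(errorCondition("degenerate bootstrap distribution: interval undefined",
                        class = c("httex1_interval_undefined", "error",
                                  "condition")))
  prop <- sum(t_boot < t0) / B
  if (prop == 0 || prop == 1)
    stop(errorCondition(
      "observed statistic outside the bootstrap range: interval undefined",
      class = c("httex1_interval_undefined", "error", "condition")))
  z0 <- stats::qnorm(prop)
  L <- mean(t_jack) - t_jack
  denom <- sum(L^2)^1.5
  a <- if (denom == 0) 0 else sum(L^3) / (6 * denom)
  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  zalpha <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zalpha) / (1 - a * (z0 + zalpha)))
  out <- .norm_interp_quantile(t_boot, adj)
  names(out) <- c("lower", "upper")
  out
}

#' Bootstrap comparison of two equal-df models
#'
#' Compares the goodness of fit of two regression models with the same
#' degrees of freedom (e.g. the QT- vs Q1-based somatic-expansion or
#' time-to-onset models) by nonparametric bootstrap of the difference in
#' r-squared (linear models) or log-likelihood (Cox models). Participants
#' are resampled with replacement; both models are refitted on every
#' replicate; the confidence interval of the difference uses the
#' bias-corrected accelerated (BCA) method with jackknife acceleration.
#'
#' @param data Participant data frame.
#' @param builder_a,builder_b Functions `data -> fit` returning objects for
#'   which `statistic` can be extracted (`se_fit`, `outcome_fit`,
#'   `cox_aao_fit`, `lm`, or `coxph`).
#' @param statistic `"r_squared"` or `"log_likelihood"`.
#' @param n_boot Number of bootstrap replicates (default 5000).
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level (default 0.95).
#' @return A list of class `boot_compare`: `difference` (statistic A minus
#'   B on the full data), `ci` (BCA interval), `n_boot`, `n_failed`,
#'   `seed`, `t_boot`.
#' @export
compare_models_bootstrap <- function(data, builder_a, builder_b,
                                     statistic = c("r_squared",
                                                   "log_likelihood"),
                                     n_boot = 5000L, seed = 1L,
                                     conf = 0.95) {
  statistic <- match.arg(statistic)
  if (n_boot < 100L)
    warning("n_boot < 100: BCA endpoints will be imprecise")
  ex <- function(fit) .extract_stat(fit, statistic)
  stat_diff <- function(d) ex(builder_a(d)) - ex(builder_b(d))
  t0 <- stat_diff(data)
  n <- nrow(data)
  set.seed(seed)
  t_boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(stat_diff(data[idx, , drop = FALSE]),
             error = function(e) NA_real_)
  }, numeric(1))
  n_failed <- sum(!is.finite(t_boot))
  t_jack <- vapply(seq_len(n), function(i)
    stat_diff(data[-i, , drop = FALSE]), numeric(1))
  ci <- bca_interval(t0, t_boot, t_jack, conf)
  out <- list(difference = t0, ci = ci, statistic = statistic,
              n_boot = n_boot, n_failed = n_failed, seed = seed,
              t_boot = t_boot[is.finite(t_boot)])
  class(out) <- "boot_compare"
  out
}

#' @export
print.boot_compare <- function(x, ...) {
  cat("Bootstrap model comparison (", x$statistic, ", ", x$n_boot,
      " replicates)\n  difference = ", format(x$difference, digits = 4),
      ", BCA 95% CI = [", format(x$ci[1], digits = 4), ", ",
      format(x$ci[2], digits = 4), "]\n", sep = "")
  invisible(x)
}

.extract_stat <- function(fit, statistic) {
  if (statistic == "r_squared") {
    if (inherits(fit, "se_fit") || inherits(fit, "outcome_fit"))
      return(fit$r_squared)
    if (inherits(fit, "lm")) return(summary(fit)$r.squared)
    stop("r_squared undefined for class ", paste(class(fit), collapse = "/"))
  }
  if (inherits(fit, "cox_aao_fit")) return(fit$loglik)
  as.numeric(stats::logLik(if (!is.null(fit$lm)) fit$lm else fit))
}
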