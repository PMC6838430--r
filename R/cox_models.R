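# Stratified Cox time-to-onset models (AAOQT, AAOQ1, AAOQ1Q2, AAOQFLQ2),
# proportional-hazards checks, and covariate-adjusted survival summaries.

.prepare_cox_data <- function(data, cag_measure, include_q2, include_score,
                              centres = NULL) {
  cag_col <- switch(cag_measure, Q1 = "q1", QT = "qt", QFL = "qfl",
                    stop("unknown CAG measure: ", cag_measure))
  need <- c("manifest", "onset_age", "censor_age", cag_col, "sex", "cohort")
  if (include_q2) need <- c(need, "q2")
  if (include_score != "none") need <- c(need, "expansion_score")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing phenotype columns: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(data[setdiff(need, "onset_age")]) &
    (!data$manifest | !is.na(data$onset_age))
  d <- data[keep, , drop = FALSE]
  if (include_q2 && any(d$q2 == 3L)) {
    message("dropping ", sum(d$q2 == 3L),
            " record(s) with q2 = 3 from the Q2-contrast model")
    d <- d[d$q2 != 3L, , drop = FALSE]
  }
  if (is.null(centres)) centres <- c(cag = mean(d[[cag_col]]))
  d$cag_c <- d[[cag_col]] - centres[["cag"]]
  d$time <- ifelse(d$manifest, d$onset_age, d$censor_age)
  d$event <- as.integer(d$manifest)
  d$sex <- factor(d$sex)
  d$cohort <- factor(d$cohort)
  if (include_q2)
    d$q2f <- factor(d$q2, levels = intersect(c(2, 0, 4), unique(d$q2)))
  if (include_score == "sign")
    d$score_sign <- factor(ifelse(d$expansion_score >= 0, "positive",
                                  "negative"),
                           levels = c("negative", "positive"))
  list(data = d, centres = centres, cag_col = cag_col)
}

#' Fit a stratified Cox model of age at motor onset
#'
#' Time-to-event regression of HD motor onset on the age scale: the event
#' is motor onset, non-manifest participants are censored at their last
#' visit. Sex-by-cohort cells are strata (each has its own baseline
#' hazard); the CAG measure is centred; ties are handled by the Breslow
#' approximation by default. The somatic expansion score can enter as a
#' linear covariate or dichotomized at zero (non-negative scores form the
#' `positive` group, matching sign-based survival displays).
#'
#' @param data Participant data frame with columns `manifest` (logical),
#'   `onset_age`, `censor_age`, `q1`/`qt`/`qfl`, `sex`, `cohort`, and
#'   `q2` / `expansion_score` as needed.
#' @param cag_measure `"Q1"`, `"QT"` or `"QFL"`.
#' @param include_q2 Add Q2 category terms (reference Q2 = 2)?
#' @param include_score `"none"`, `"linear"` or `"sign"`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `cox_aao_fit`: `coxph` (the underlying
#'   [survival::coxph] fit), `model_name`, `hr_table` (hazard ratios with
#'   95% CIs and z statistics), `loglik`, `n`, `n_events`, `centres`.
#' @examples
#' cohort <- gen_cohort(synth_config(n_participants = 200, seed = 2))
#' ppl <- cohort$participants
#' ppl$expansion_score <- somatic_expansion_score(fit_se_model(ppl, "Q1"))
#' fit_cox(ppl, "Q1", include_score = "linear")
#' @export
fit_cox <- function(data, cag_measure = c("Q1", "QT", "QFL"),
                    include_q2 = FALSE,
                    include_score = c("none", "linear", "sign"),
                    ties = c("breslow", "efron")) {
  cag_measure <- match.arg(cag_measure)
  include_score <- match.arg(include_score)
  ties <- match.arg(ties)
  prep <- .prepare_cox_data(data, cag_measure, include_q2, include_score)
  d <- prep$data
  if (sum(d$event) < 10L)
    warning("fewer than 10 onset events (", sum(d$event), ")")
  strata_n <- table(d$sex, d$cohort, d$event)
  rhs <- "cag_c"
  if (include_q2 && !is.null(d$q2f) && nlevels(d$q2f) > 1L)
    rhs <- paste(rhs, "+ q2f")
  if (include_score == "linear") rhs <- paste(rhs, "+ expansion_score")
  if (include_score == "sign") rhs <- paste(rhs, "+ score_sign")
  rhs <- paste(rhs, "+ survival::strata(sex, cohort)")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = d, ties = ties)
  co <- summary(fit)
  degenerate <- anyNA(stats::coef(fit))
  if (degenerate)
    warning("unidentifiable covariate(s): ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  hr <- data.frame(hr = exp(stats::coef(fit)),
                   lower = exp(stats::confint(fit)[, 1]),
                   upper = exp(stats::confint(fit)[, 2]),
                   z = co$coefficients[, "z"],
                   p = co$coefficients[, "Pr(>|z|)"])
  out <- list(coxph = fit,
              model_name = paste0("AAO", cag_measure,
                                  if (include_q2) "Q2" else ""),
              cag_measure = cag_measure, include_q2 = include_q2,
              include_score = include_score, ties = ties,
              hr_table = hr,
              loglik = fit$loglik[length(fit$loglik)],
              n = nrow(d), n_events = sum(d$event),
              n_censored = sum(1L - d$event),
              centres = prep$centres, data = d)
  class(out) <- "cox_aao_fit"
  out
}

#' @export
print.cox_aao_fit <- function(x, ...) {
  cat("Stratified Cox model ", x$model_name, " (", x$n_events,
      " events / ", x$n_censored, " censored; ties = ", x$ties, ")\n",
      sep = "")
  print(round(x$hr_table, 4))
  invisible(x)
}

#' @export
summary.cox_aao_fit <- function(object, ...) summary(object$coxph, ...)

#' @export
coef.cox_aao_fit <- function(object, ...) stats::coef(object$coxph)

#' @export
logLik.cox_aao_fit <- function(object, ...)
  stats::logLik(object$coxph, ...)

#' Scaled-Schoenfeld proportional-hazards check
#'
#' Per-covariate and global tests of the proportional-hazards assumption
#' based on scaled Schoenfeld residuals. Covariates for which the test is
#' undefined (e.g. constant within strata) are flagged with `NA`.
#'
#' @param fit A `cox_aao_fit`.
#' @return Data frame with columns `chisq`, `df`, `p` per covariate plus a
#'   `GLOBAL` row.
#' @export
check_proportional_hazards <- function(fit) {
  stopifnot(inherits(fit, "cox_aao_fit"))
  z <- tryCatch(survival::cox.zph(fit$coxph, transform = "km"),
                error = function(e) NULL)
  if (is.null(z)) {
    warning("proportional-hazards test undefined for this fit")
    return(data.frame(chisq = NA_real_, df = NA_real_, p = NA_real_,
                      row.names = "GLOBAL"))
  }
  as.data.frame(z$table)
}

#' Covariate-adjusted survival curves and median onset ages
#'
#' Adjusted onset curves per level of a grouping covariate (Q2 category or
#' the sign of the somatic expansion score), evaluated at the means of the
#' other covariates. Each stratum contributes its own Breslow baseline
#' hazard; the displayed curve is the stratum-size-weighted average of the
#' per-stratum adjusted curves. The median onset age is the first age at
#' which the adjusted survival drops to 0.5 or below; its CI comes from the
#' same crossing rule applied to the averaged confidence envelope. Groups
#' whose curve never reaches 0.5 report a `NA` (not reached) median.
#'
#' @param fit A `cox_aao_fit` whose model contains the grouping covariate.
#' @param grouping `"q2"` or `"score_sign"`.
#' @return A list of class `survival_summary_list`; one element per group
#'   level with `group`, `time`, `surv`, `lower`, `upper`, `median`,
#'   `median_ci`.
#' @export
adjusted_survival <- function(fit, grouping = c("q2", "score_sign")) {
  stopifnot(inherits(fit, "cox_aao_fit"))
  grouping <- match.arg(grouping)
  d <- fit$data
  gvar <- switch(grouping, q2 = "q2f", score_sign = "score_sign")
  if (is.null(d[[gvar]]))
    stop("fitted model does not contain the grouping covariate ", gvar)
  levs <- levels(d[[gvar]])
  out <- lapply(levs, function(lv) {
    nd <- data.frame(cag_c = 0)
    nd[[gvar]] <- factor(lv, levels = levs)
    if (fit$include_score == "linear")
      nd$expansion_score <- mean(d$expansion_score)
    if (fit$include_q2 && gvar != "q2f" && !is.null(d$q2f))
      nd$q2f <- factor(levels(d$q2f)[1], levels = levels(d$q2f))
    # newdata omits the strata variables, so survfit returns one adjusted
    # curve per sex-by-cohort stratum; average them weighted by stratum size
    sf <- survival::survfit(fit$coxph, newdata = nd)
    grid <- sort(unique(d$time))
    if (is.null(sf$strata)) {
      blocks <- list(seq_along(sf$time))
      w <- 1
    } else {
      ends <- cumsum(sf$strata)
      blocks <- mapply(seq, c(1L, utils::head(ends, -1) + 1L), ends,
                       SIMPLIFY = FALSE)
      w <- vapply(names(sf$strata), function(nm) {
        parts <- strsplit(nm, ", ", fixed = TRUE)[[1]]
        sum(d$sex == parts[1] & d$cohort == parts[2])
      }, numeric(1))
      w <- w / sum(w)
    }
    eval_block <- function(vals, idx) {
      stats::stepfun(sf$time[idx], c(1, vals[idx]))(grid)
    }
    surv_mat <- vapply(blocks, function(idx) eval_block(sf$surv, idx),
                       numeric(length(grid)))
    low_mat <- vapply(blocks, function(idx) eval_block(sf$lower, idx),
                      numeric(length(grid)))
    up_mat <- vapply(blocks, function(idx) eval_block(sf$upper, idx),
                     numeric(length(grid)))
    surv <- drop(cbind(surv_mat) %*% w)
    lower <- drop(cbind(low_mat) %*% w)
    upper <- drop(cbind(up_mat) %*% w)
    med <- function(s) {
      i <- which(s <= 0.5)
      if (length(i) == 0L) NA_real_ else grid[min(i)]
    }
    list(group = lv, time = grid, surv = surv, lower = lower,
         upper = upper, median = med(surv),
         median_ci = c(lower = med(lower), upper = med(upper)))
  })
  names(out) <- levs
  class(out) <- "survival_summary_list"
  out
}

#' @export
print.survival_summary_list <- function(x, ...) {
  cat("Adjusted survival summaries:\n")
  for (g in x) {
    ci <- g$median_ci
    cat("  ", format(g$group, width = 10), " median onset = ",
        ifelse(is.na(g$median), "not reached", format(g$median, digits = 4)),
        "  (95% CI ", format(ci[1], digits = 4), " to ",
        format(ci[2], digits = 4), ")\n", sep = "")
  }
  invisible(x)
}
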