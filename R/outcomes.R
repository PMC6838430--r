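# Clinical outcome linear models (baseline TMS, progression score, TMS/TFC
# rates of change), participant-specific longitudinal slopes, least-square
# means per Q2 genotype, and FDR correction.

#' Participant-specific rates of change of TMS and TFC
#'
#' Fits a mixed-effect model per outcome with a fixed years-of-follow-up
#' effect and correlated random intercepts and slopes per participant; the
#' participant-specific rate of change is the fixed slope plus the
#' participant's predicted (shrunken, BLUP) random slope. If the
#' random-effects covariance is singular or the fit fails, per-participant
#' ordinary least-squares slopes are used instead, with a warning.
#'
#' @param visits Long-format data frame with columns `participant_id`,
#'   `years_followup`, and the outcome columns (`tms`, `tfc`).
#' @param outcomes Which outcome columns to model.
#' @return Data frame with `participant_id` and one `<outcome>_rate` column
#'   per outcome (units per year).
#' @export
participant_slopes <- function(visits, outcomes = c("tms", "tfc")) {
  need <- c("participant_id", "years_followup", outcomes)
  miss <- setdiff(need, names(visits))
  if (length(miss))
    stop("missing visit columns: ", paste(miss, collapse = ", "))
  nvis <- table(visits$participant_id)
  if (length(nvis) < 20L)
    warning("fewer than 20 participants with visits (", length(nvis), ")")
  if (mean(nvis >= 2L) < 0.8)
    warning("fewer than 80% of participants have >= 2 visits")
  ids <- names(nvis)
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (oc in outcomes) {
    v <- visits[!is.na(visits[[oc]]), ]
    v$y <- v[[oc]]
    fit <- tryCatch(
      lme4::lmer(y ~ years_followup + (years_followup | participant_id),
                 data = v,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
      fx <- lme4::fixef(fit)[["years_followup"]]
      re <- lme4::ranef(fit)$participant_id
      rate <- fx + re[match(ids, rownames(re)), "years_followup"]
    } else {
      warning("singular random-effects fit for ", oc,
              ": falling back to per-participant OLS slopes")
      rate <- vapply(ids, function(id) {
        g <- v[v$participant_id == id, ]
        if (nrow(g) < 2L) return(NA_real_)
        stats::coef(stats::lm(y ~ years_followup, data = g))[[2]]
      }, numeric(1))
    }
    out[[paste0(oc, "_rate")]] <- rate
  }
  out
}

.outcome_spec <- function(response) {
  switch(response,
    baseline_tms = list(col = "baseline_tms", label = "TMS",
                        adjust = c("age")),
    progression = list(col = "progression", label = "Prog",
                       adjust = character(0)),
    tms_rate = list(col = "tms_rate", label = "TMSrate",
                    adjust = c("age", "baseline_tms")),
    tfc_rate = list(col = "tfc_rate", label = "TFCrate",
                    adjust = c("age", "baseline_tfc")),
    stop("unknown response: ", response))
}

#' Linear model for a clinical outcome with least-square means per Q2 level
#'
#' Fits the named outcome regressions: baseline TMS (models TMSQT / TMSQ1 /
#' TMSQ1Q2 / TMSQFLQ2), progression score (ProgQ1 / ProgQFL), and the rates
#' of change of TMS and TFC (TMSrateQ1Q2 / TFCrateQ1Q2, which additionally
#' adjust for the baseline value of the outcome and age). Continuous
#' covariates are centred; sex and cohort always enter; the somatic
#' expansion score enters uncentred (it is already quasi-centred as a
#' regression residual). Least-square means per Q2 genotype are the model
#' predictions at the cohort-average design row with Q2 forced to each
#' level (equivalently, the average prediction over the cohort under each
#' Q2 assignment).
#'
#' @param data Participant data frame.
#' @param response One of `"baseline_tms"`, `"progression"`, `"tms_rate"`,
#'   `"tfc_rate"`.
#' @param cag_measure `"Q1"`, `"QT"` or `"QFL"`.
#' @param include_q2 Add Q2 genotype terms (reference Q2 = 2)?
#' @param include_score Add the somatic expansion score as a covariate?
#' @return An object of class `outcome_fit`: `lm`, `model_name`,
#'   `coefficients`, `r_squared`, `n`, `lsmeans` (per Q2 level: estimate,
#'   se, 95% CI), `centres`.
#' @export
fit_outcome_linear <- function(data, response, cag_measure = c("Q1", "QT",
                                                               "QFL"),
                               include_q2 = TRUE, include_score = TRUE) {
  cag_measure <- match.arg(cag_measure)
  spec <- .outcome_spec(response)
  cag_col <- switch(cag_measure, Q1 = "q1", QT = "qt", QFL = "qfl")
  need <- c(spec$col, cag_col, "sex", "cohort", spec$adjust)
  if (include_q2) need <- c(need, "q2")
  if (include_score) need <- c(need, "expansion_score")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing phenotype columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[need]), , drop = FALSE]
  if (include_q2 && any(d$q2 == 3L)) {
    message("dropping ", sum(d$q2 == 3L),
            " record(s) with q2 = 3 from the Q2-contrast model")
    d <- d[d$q2 != 3L, , drop = FALSE]
  }
  centres <- c(cag = mean(d[[cag_col]]))
  d$cag_c <- d[[cag_col]] - centres[["cag"]]
  d$y <- d[[spec$col]]
  d$sex <- factor(d$sex)
  d$cohort <- factor(d$cohort)
  rhs <- "cag_c"
  for (a in spec$adjust) {
    ac <- paste0(a, "_c")
    centres[[a]] <- mean(d[[a]])
    d[[ac]] <- d[[a]] - centres[[a]]
    rhs <- paste(rhs, "+", ac)
  }
  if (nlevels(d$sex) > 1L) rhs <- paste(rhs, "+ sex")
  if (nlevels(d$cohort) > 1L) rhs <- paste(rhs, "+ cohort")
  if (include_q2) {
    d$q2f <- factor(d$q2, levels = intersect(c(2, 0, 4), unique(d$q2)))
    if (nlevels(d$q2f) > 1L) rhs <- paste(rhs, "+ q2f")
  }
  if (include_score) rhs <- paste(rhs, "+ expansion_score")
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = d)
  sm <- summary(fit)
  coefs <- .lm_coef_table(fit, sm)
  lsm <- NULL
  if (include_q2 && !is.null(d$q2f) && nlevels(d$q2f) > 1L)
    lsm <- .lsmeans_q2(fit, d)
  out <- list(lm = fit,
              model_name = paste0(spec$label, cag_measure,
                                  if (include_q2) "Q2" else ""),
              response = response, cag_measure = cag_measure,
              include_q2 = include_q2, include_score = include_score,
              coefficients = coefs, r_squared = sm$r.squared,
              n = nrow(d), lsmeans = lsm, centres = centres)
  class(out) <- "outcome_fit"
  out
}

# adjusted mean per Q2 level: prediction at the column-mean design row with
# the Q2 dummies forced to the level's indicator
.lsmeans_q2 <- function(fit, d) {
  X <- stats::model.matrix(fit)
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  main_cols <- grep("^q2f[0-9]+$", colnames(X))
  levs <- levels(d$q2f)
  rows <- lapply(levs, function(lv) {
    xbar <- colMeans(X)
    xbar[main_cols] <- as.numeric(paste0("q2f", lv) == colnames(X)[main_cols])
    est <- sum(xbar * beta)
    se <- sqrt(drop(t(xbar) %*% V %*% xbar))
    tcrit <- stats::qt(0.975, df = fit$df.residual)
    data.frame(q2 = lv, estimate = est, se = se,
               lower = est - tcrit * se, upper = est + tcrit * se,
               n = sum(d$q2f == lv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat("Outcome model ", x$model_name, " (n = ", x$n, ", r^2 = ",
      format(x$r_squared, digits = 3), ")\n", sep = "")
  print(round(x$coefficients, 4))
  if (!is.null(x$lsmeans)) {
    cat("Least-square means per Q2 genotype:\n")
    print(x$lsmeans, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.outcome_fit <- function(object, ...) summary(object$lm, ...)

#' @export
coef.outcome_fit <- function(object, ...) stats::coef(object$lm)

#' @export
residuals.outcome_fit <- function(object, ...) stats::residuals(object$lm)

#' Benjamini-Hochberg false discovery rate correction within a family
#'
#' Step-up FDR adjustment applied within one named analysis family (age at
#' onset models; progression; TMS/TFC rates; baseline TMS; SNP
#' association), as multiple testing is controlled per family rather than
#' globally.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @param family Optional family label carried as an attribute.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues, family = NULL) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop(errorCondition("p-values must lie in [0, 1]",
                        class = c("httex1_input_error", "error",
                                  "condition")))
  adj <- stats::p.adjust(pvalues, method = "BH")
  if (!is.null(family)) attr(adj, "family") <- family
  adj
}
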