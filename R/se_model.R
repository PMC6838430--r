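# Somatic-expansion regression models (SEQT, SEQ1, SEQ1Q2) and the
# individual somatic expansion score.

# coefficient table robust to aliased (NA) coefficients in small Q2 cells
.lm_coef_table <- function(fit, sm = summary(fit)) {
  cf <- stats::coef(fit)
  ci <- suppressWarnings(stats::confint(fit))
  coefs <- data.frame(estimate = cf, lower = ci[, 1], upper = ci[, 2],
                      t = NA_real_, p = NA_real_)
  est <- rownames(sm$coefficients)
  coefs[est, "t"] <- sm$coefficients[, 3]
  coefs[est, "p"] <- sm$coefficients[, 4]
  coefs
}

# internal: add centred covariates and the q2 factor (reference level "2")
.prepare_se_data <- function(data, cag_measure, include_q2, centres = NULL) {
  cag_col <- switch(cag_measure, Q1 = "q1", QT = "qt", QFL = "qfl",
                    stop("unknown CAG measure: ", cag_measure))
  need <- c("expansion_ratio", "age", cag_col, "sex", "cohort")
  if (include_q2) need <- c(need, "q2")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing phenotype columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[need]), , drop = FALSE]
  if (include_q2 && any(d$q2 == 3L)) {
    # single-carrier category: excluded from Q2 contrasts, kept in Q1-only models
    message("dropping ", sum(d$q2 == 3L),
            " record(s) with q2 = 3 from the Q2-contrast model")
    d <- d[d$q2 != 3L, , drop = FALSE]
  }
  if (is.null(centres))
    centres <- c(age = mean(d$age), cag = mean(d[[cag_col]]))
  d$age_c <- d$age - centres[["age"]]
  d$cag_c <- d[[cag_col]] - centres[["cag"]]
  d$sex <- factor(d$sex)
  d$cohort <- factor(d$cohort)
  if (include_q2)
    d$q2f <- factor(d$q2, levels = intersect(c(2, 0, 4), unique(d$q2)))
  list(data = d, centres = centres, cag_col = cag_col)
}

.se_formula <- function(include_q2, d) {
  rhs <- "age_c * cag_c"
  if (nlevels(d$sex) > 1L) rhs <- paste(rhs, "+ sex")
  if (nlevels(d$cohort) > 1L) rhs <- paste(rhs, "+ cohort")
  if (!is.null(d$q2f) && nlevels(d$q2f) > 1L)
    rhs <- paste(rhs, "+ q2f + q2f:age_c")
  stats::as.formula(paste("expansion_ratio ~", rhs))
}

#' Fit a somatic-expansion regression model (SEQT, SEQ1 or SEQ1Q2)
#'
#' Linear regression of the ratio of somatic expansions on centred age at
#' sampling, the centred CAG measure (pure CAG `Q1` or total glutamines
#' `QT`), their interaction, sex and cohort. With `include_q2 = TRUE`, the
#' number of additional glutamine codons enters as a categorical factor
#' (reference level Q2 = 2) with main effects and Q2-by-age interactions;
#' the single-carrier Q2 = 3 category is dropped from contrast models.
#' Continuous covariates are centred internally, so fits are invariant to
#' translations of age or CAG length. The response is the raw ratio.
#'
#' @param data Participant data frame with columns `expansion_ratio`, `age`
#'   (age at sampling, years), `q1`/`qt`, `sex`, `cohort` and (for
#'   `include_q2`) `q2`. Records with missing values are excluded.
#' @param cag_measure `"Q1"` or `"QT"` (`"QFL"` is also accepted).
#' @param include_q2 Add Q2 factor terms (model SEQ1Q2)?
#' @return An object of class `se_fit` with components `lm` (the underlying
#'   [stats::lm] fit), `model_name`, `coefficients` (estimate, 95% CI, t,
#'   p), `r_squared`, `n`, `centres`.
#' @examples
#' cohort <- gen_cohort(synth_config(n_participants = 150, seed = 1))
#' fit <- fit_se_model(cohort$participants, "Q1")
#' coef(fit)[1:3]
#' @export
fit_se_model <- function(data, cag_measure = c("Q1", "QT"),
                         include_q2 = FALSE) {
  cag_measure <- match.arg(cag_measure)
  prep <- .prepare_se_data(data, cag_measure, include_q2)
  d <- prep$data
  if (nrow(d) < 30L)
    warning("fewer than 30 complete records (n = ", nrow(d), ")")
  fml <- .se_formula(include_q2, d)
  fit <- stats::lm(fml, data = d)
  if (include_q2 && !is.null(d$q2f)) {
    cells <- table(d$q2f)
    if (any(cells[-1] == 1L))
      warning("Q2 level(s) with a single record: ",
              paste(names(cells)[cells == 1L], collapse = ", "))
  }
  sm <- summary(fit)
  coefs <- .lm_coef_table(fit, sm)
  out <- list(lm = fit,
              model_name = paste0("SE", cag_measure,
                                  if (include_q2) "Q2" else ""),
              cag_measure = cag_measure, include_q2 = include_q2,
              coefficients = coefs,
              r_squared = sm$r.squared,
              n = nrow(d), centres = prep$centres)
  class(out) <- "se_fit"
  out
}

#' @export
print.se_fit <- function(x, ...) {
  cat("Somatic-expansion model ", x$model_name, " (n = ", x$n,
      ", r^2 = ", format(x$r_squared, digits = 3), ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.se_fit <- function(object, ...) summary(object$lm, ...)

#' @export
coef.se_fit <- function(object, ...) stats::coef(object$lm)

#' @export
residuals.se_fit <- function(object, ...) stats::residuals(object$lm)

#' Predict the expected expansion ratio for new participants
#'
#' Applies the frozen centring of the fitted model, so new individuals can
#' be scored against a training fit.
#'
#' @param object An `se_fit`.
#' @param newdata Participant data frame (same columns as the fit).
#' @param ... Unused.
#' @export
predict.se_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::fitted(object$lm))
  prep <- .prepare_se_data(newdata, object$cag_measure, object$include_q2,
                           centres = object$centres)
  stats::predict(object$lm, newdata = prep$data)
}

#' Individual-specific somatic expansion score
#'
#' The score is the residual of the SEQ1 regression: observed ratio minus
#' the ratio predicted from age at sampling, pure CAG length, sex and
#' cohort. Positive scores mean more somatic expansion than expected for
#' the individual's age and allele; over the fitting cohort the scores
#' average to zero. Records with missing covariates get `NA`.
#'
#' @param fit An `se_fit` (normally model SEQ1).
#' @param data Participant data frame to score; defaults to the fitting
#'   data, in which case the scores are exactly the fit residuals.
#' @return Numeric vector of scores aligned with `data` rows.
#' @export
somatic_expansion_score <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "se_fit"))
  if (is.null(data)) return(unname(stats::residuals(fit$lm)))
  cag_col <- switch(fit$cag_measure, Q1 = "q1", QT = "qt", QFL = "qfl")
  need <- c("expansion_ratio", "age", cag_col, "sex", "cohort")
  ok <- stats::complete.cases(data[need])
  score <- rep(NA_real_, nrow(data))
  if (any(ok))
    score[ok] <- data$expansion_ratio[ok] -
      predict(fit, data[ok, , drop = FALSE])
  score
}
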