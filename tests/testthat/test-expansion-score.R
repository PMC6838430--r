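# SE regression models, the somatic expansion score, and the BCA bootstrap
# model comparison.

test_that("noiseless linear ratios are recovered to machine precision", {
  d <- make_se_cohort(120, seed = 21, noise_sd = 0)
  fit <- suppressWarnings(fit_se_model(d, "Q1"))  # perfect-fit notice
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  cf <- coef(fit)
  expect_equal(unname(cf[["age_c"]]), 0.004, tolerance = 1e-9)
  expect_equal(unname(cf[["cag_c"]]), 0.04, tolerance = 1e-9)
  expect_equal(unname(cf[["age_c:cag_c"]]), 0.001, tolerance = 1e-9)
})

test_that("coefficients match an independent normal-equations oracle", {
  d <- make_se_cohort(50, seed = 22)
  fit <- fit_se_model(d, "Q1")
  # oracle: build the design by hand and solve the normal equations
  ac <- d$age - mean(d$age)
  qc <- d$q1 - mean(d$q1)
  X <- cbind(1, ac, qc, as.numeric(d$sex == "male"),
             as.numeric(d$cohort == "B"), ac * qc)
  beta <- solve(t(X) %*% X, t(X) %*% d$expansion_ratio)
  got <- coef(fit)[c("(Intercept)", "age_c", "cag_c", "sexmale",
                     "cohortB", "age_c:cag_c")]
  expect_equal(unname(got), unname(drop(beta)), tolerance = 1e-10)
  # r^2 oracle
  pred <- drop(X %*% beta)
  r2 <- 1 - sum((d$expansion_ratio - pred)^2) /
    sum((d$expansion_ratio - mean(d$expansion_ratio))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
})

test_that("scores are residuals: zero on-surface, zero cohort mean", {
  d <- make_se_cohort(100, seed = 23)
  fit <- fit_se_model(d, "Q1")
  sc <- somatic_expansion_score(fit)
  expect_lt(abs(mean(sc)), 1e-10 * stats::sd(sc))
  expect_equal(sc, unname(residuals(fit)))
  # a record lying exactly on the fitted surface scores zero
  on_surface <- d[1, ]
  on_surface$expansion_ratio <- predict(fit, d[1, , drop = FALSE])[[1]]
  expect_equal(somatic_expansion_score(fit, on_surface), 0,
               tolerance = 1e-10)
  # missing covariates give NA, others are scored
  d2 <- d[1:5, ]
  d2$age[2] <- NA
  sc2 <- somatic_expansion_score(fit, d2)
  expect_true(is.na(sc2[2]))
  expect_false(anyNA(sc2[-2]))
})

test_that("fits are invariant to translations of age (internal centring)", {
  d <- make_se_cohort(150, seed = 24)
  f1 <- fit_se_model(d, "Q1")
  d2 <- d
  d2$age <- d$age + 100
  f2 <- fit_se_model(d2, "Q1")
  keep <- c("age_c", "cag_c", "age_c:cag_c", "sexmale", "cohortB")
  expect_equal(coef(f1)[keep], coef(f2)[keep], tolerance = 1e-10)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("score signs track the generator's injected individual effects", {
  cohort <- gen_cohort(synth_config(n_participants = 734, seed = 25))
  fit <- fit_se_model(cohort$participants, "Q1")
  sc <- somatic_expansion_score(fit)
  ind <- cohort$truth$ind
  big <- abs(ind) > stats::quantile(abs(ind), 0.75)
  expect_gte(mean(sign(sc[big]) == sign(ind[big])), 0.9)
})

test_that("SEQ1 coefficient CIs cover generator truth across replicates", {
  # scaled-down recovery loop; the full 200-replicate version backs the
  # acceptance suite
  hits <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    co <- gen_cohort(synth_config(n_participants = 400, seed = 3000 + r))
    cfg <- co$truth$config
    fit <- fit_se_model(co$participants, "Q1")
    ci <- fit$coefficients["age_c:cag_c", c("lower", "upper")]
    hits <- hits + (cfg$se_age_q1 >= ci[[1]] && cfg$se_age_q1 <= ci[[2]])
  }
  expect_gte(hits / reps, 0.85)
})

test_that("q2 = 3 records are dropped from Q2-contrast models only", {
  d <- make_se_cohort(80, seed = 26)
  d$q2[1:2] <- 3
  d$qt <- d$q1 + d$q2
  f_q1 <- fit_se_model(d, "Q1")
  expect_equal(f_q1$n, 80)
  expect_message(f_q2 <- fit_se_model(d, "Q1", include_q2 = TRUE),
                 "q2 = 3")
  expect_equal(f_q2$n, 78)
})

test_that("BCA interval matches boot's implementation on the same draws", {
  skip_if_not_installed("boot")
  set.seed(31)
  x <- rexp(40)               # skewed so z0 and acceleration matter
  stat <- function(d, i) mean(d[i])
  set.seed(32)
  bt <- boot::boot(x, stat, R = 1999)
  n <- length(x)
  t_jack <- vapply(seq_len(n), function(i) mean(x[-i]), numeric(1))
  L <- (n - 1) * (mean(x) - t_jack)
  mine <- bca_interval(bt$t0, as.numeric(bt$t), t_jack)
  ref <- boot::boot.ci(bt, type = "bca", L = L)$bca[4:5]
  expect_equal(unname(mine), ref, tolerance = 1e-8)
})

test_that("bootstrap comparison reproduces a seeded resample oracle", {
  d <- make_se_cohort(30, seed = 33)
  ba <- function(dd) fit_se_model(dd, "Q1")
  bb <- function(dd) fit_se_model(dd, "QT")
  res <- suppressWarnings(       # n = 29 jackknife subsets trip the n >= 30 notice
    compare_models_bootstrap(d, ba, bb, "r_squared", n_boot = 400,
                             seed = 99))
  # oracle: replay the identical resamples and recompute everything with
  # plain lm() calls and a textbook BCA formula
  r2 <- function(dd, cag) {
    ac <- dd$age - mean(dd$age)
    qc <- dd[[cag]] - mean(dd[[cag]])
    summary(stats::lm(dd$expansion_ratio ~ ac * qc + factor(dd$sex) +
                        factor(dd$cohort)))$r.squared
  }
  dstat <- function(dd) r2(dd, "q1") - r2(dd, "qt")
  t0 <- dstat(d)
  set.seed(99)
  t_boot <- replicate(400, dstat(d[sample.int(30, 30, replace = TRUE), ]))
  expect_equal(res$difference, t0, tolerance = 1e-12)
  expect_equal(sort(res$t_boot), sort(t_boot), tolerance = 1e-12)
  t_jack <- vapply(1:30, function(i) dstat(d[-i, ]), numeric(1))
  z0 <- qnorm(sum(t_boot < t0) / length(t_boot))
  Lj <- mean(t_jack) - t_jack
  a <- sum(Lj^3) / (6 * sum(Lj^2)^1.5)
  alph <- pnorm(z0 + (z0 + qnorm(c(0.025, 0.975))) /
                  (1 - a * (z0 + qnorm(c(0.025, 0.975)))))
  srt <- sort(t_boot)
  B <- length(srt)
  interp <- vapply(alph, function(aa) {
    r <- (B + 1) * aa
    k <- floor(r)
    if (k <= 0) return(srt[1])
    if (k >= B) return(srt[B])
    frac <- (qnorm(aa) - qnorm(k / (B + 1))) /
      (qnorm((k + 1) / (B + 1)) - qnorm(k / (B + 1)))
    srt[k] + frac * (srt[k + 1] - srt[k])
  }, numeric(1))
  expect_equal(unname(res$ci), interp, tolerance = 1e-10)
})

test_that("identical models give a degenerate zero-width interval at 0", {
  d <- make_se_cohort(40, seed = 34)
  b <- function(dd) fit_se_model(dd, "Q1")
  res <- suppressWarnings(
    compare_models_bootstrap(d, b, b, "r_squared", n_boot = 120, seed = 1))
  expect_equal(res$difference, 0)
  expect_equal(unname(res$ci), c(0, 0))
  expect_warning(
    compare_models_bootstrap(d, b, b, "r_squared", n_boot = 99, seed = 1),
    "n_boot")
})

test_that("Q1-driven generator yields r2 differences favouring Q1 over QT", {
  # power check, scaled down: Q1 (not QT) drives the ratio, so the Q1-model
  # r2 should beat the QT model in most bootstrap comparisons
  wins <- 0L
  reps <- 12L
  for (r in seq_len(reps)) {
    co <- gen_cohort(synth_config(n_participants = 400, seed = 5000 + r))
    cmp <- compare_models_bootstrap(
      co$participants,
      function(dd) fit_se_model(dd, "Q1"),
      function(dd) fit_se_model(dd, "QT"),
      "r_squared", n_boot = 500, seed = r)
    wins <- wins + (cmp$ci[["lower"]] > 0)
  }
  expect_gte(wins / reps, 0.8)
})
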