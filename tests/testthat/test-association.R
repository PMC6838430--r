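# Cox onset models against a brute-force partial-likelihood oracle,
# permutation machinery against exhaustive enumeration, adjusted survival
# against direct cumulative-hazard integration, mixed-model slopes,
# least-square means against g-computation, and BH-FDR against a slow
# step-up oracle.

cox_fixture8 <- function() {
  # printed 8-subject fixture: 6 onsets, 2 censored, binary allele length
  data.frame(
    manifest = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    onset_age = c(42, 45, 47, 50, 52, 55, NA, NA),
    censor_age = c(42, 45, 47, 50, 52, 55, 58, 60),
    q1 = c(41, 40, 41, 40, 41, 40, 40, 41),
    sex = "female", cohort = "A")
}

test_that("Cox fit matches a grid-search partial-likelihood maximizer", {
  d <- cox_fixture8()
  fit <- suppressWarnings(fit_cox(d, "Q1"))
  # oracle: Breslow partial log-likelihood over a fine beta grid
  x <- d$q1 - mean(d$q1)
  time <- ifelse(d$manifest, d$onset_age, d$censor_age)
  ev <- which(d$manifest)
  pl <- function(beta) {
    sum(vapply(ev, function(i) {
      risk <- time >= time[i]
      beta * x[i] - log(sum(exp(beta * x[risk])))
    }, numeric(1)))
  }
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, pl, numeric(1))
  beta_hat <- grid[which.max(ll)]
  expect_lt(abs(unname(coef(fit)[["cag_c"]]) - beta_hat), 1e-4)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
  expect_equal(fit$n_events, 6)
})

test_that("a constant covariate is flagged as unidentifiable", {
  d <- cox_fixture8()
  d$q1 <- 43
  w <- capture_warnings(fit <- fit_cox(d, "Q1"))  # coxph warns too
  expect_true(any(grepl("unidentifiable", w)))
  expect_true(anyNA(coef(fit)))
})

test_that("Cox log-likelihood never drops when adding the score", {
  co <- gen_cohort(synth_config(n_participants = 400, seed = 41))
  ppl <- co$participants
  ppl$expansion_score <- somatic_expansion_score(fit_se_model(ppl, "Q1"))
  f0 <- fit_cox(ppl, "Q1")
  f1 <- fit_cox(ppl, "Q1", include_score = "linear")
  expect_gte(f1$loglik, f0$loglik - 1e-8)
})

test_that("Cox score log-HR coverage holds across scaled replicates", {
  hits <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    co <- gen_cohort(synth_config(n_participants = 400, seed = 6000 + r))
    ppl <- co$participants
    ppl$expansion_score <- co$truth$ind  # latent truth as the predictor
    fit <- fit_cox(ppl, "Q1", include_score = "linear")
    ci <- log(fit$hr_table["expansion_score", c("lower", "upper")])
    truth <- co$truth$config$loghr_score
    hits <- hits + (truth >= ci[[1]] && truth <= ci[[2]])
  }
  expect_gte(hits / reps, 0.85)
})

test_that("proportional-hazards test is calibrated and has power", {
  # null: generator hazards are proportional by construction
  set.seed(42)
  p_null <- vapply(1:40, function(r) {
    co <- gen_cohort(synth_config(n_participants = 200, seed = 7000 + r))
    fit <- fit_cox(co$participants, "Q1")
    tab <- check_proportional_hazards(fit)
    tab["cag_c", "p"]
  }, numeric(1))
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)
  # power: crossing hazards violate proportionality
  set.seed(43)
  p_alt <- vapply(1:30, function(r) {
    n <- 150
    x <- rep(c(40, 41), length.out = n)
    t_onset <- ifelse(x == 41, runif(n, 38, 44), runif(n, 20, 62))
    d <- data.frame(manifest = TRUE, onset_age = t_onset,
                    censor_age = t_onset, q1 = x, sex = "female",
                    cohort = "A")
    tab <- check_proportional_hazards(suppressWarnings(fit_cox(d, "Q1")))
    tab["cag_c", "p"]
  }, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.8)
  # degenerate: constant covariate
  d <- cox_fixture8()
  d$q1 <- 43
  fit <- suppressWarnings(fit_cox(d, "Q1"))
  expect_warning(tab <- check_proportional_hazards(fit), "undefined")
  expect_true(all(is.na(tab$p)))
})

# exhaustive enumeration helpers: index permutations realizing every
# distinct placement of the atypical labels
perm_for_assignment <- function(target_pos, source_pos, n) {
  perm <- integer(n)
  perm[target_pos] <- source_pos
  perm[setdiff(seq_len(n), target_pos)] <-
    setdiff(seq_len(n), source_pos)
  perm
}

test_that("permutation p for Q2 terms equals exhaustive enumeration", {
  n <- 12
  set.seed(51)
  d <- data.frame(age = runif(n, 30, 60),
                  q1 = sample(40:46, n, replace = TRUE),
                  q2 = c(4, 4, rep(2, n - 2)),
                  sex = "female", cohort = "A")
  d$qt <- d$q1 + d$q2
  d$expansion_ratio <- 0.3 + 0.01 * d$q1 + 0.05 * (d$q2 == 4) +
    rnorm(n, 0, 0.03)
  fit <- suppressWarnings(fit_se_model(d, "Q1", include_q2 = TRUE))
  pairs <- t(utils::combn(n, 2))
  pm <- t(apply(pairs, 1, function(tp)
    perm_for_assignment(tp, c(1, 2), n)))
  res <- permute_q2(fit, perm_matrix = pm)
  # oracle: refit with plain lm() for every assignment
  ac <- d$age - mean(d$age)
  qc <- d$q1 - mean(d$q1)
  t_oracle <- apply(pairs, 1, function(tp) {
    z <- as.numeric(seq_len(n) %in% tp)
    f <- stats::lm(d$expansion_ratio ~ ac * qc + z + z:ac)
    summary(f)$coefficients["z", "t value"]
  })
  i4 <- match("q2f4", res$term)
  t_obs <- res$stat[i4]
  # the identity assignment ties the observed statistic up to float noise
  expect_equal(res$p[i4],
               (1 + sum(abs(t_oracle) >= abs(t_obs) - 1e-9)) /
                 (nrow(pairs) + 1),
               tolerance = 1e-12)
  # the identity assignment reproduces the observed statistic
  id_row <- which(pairs[, 1] == 1 & pairs[, 2] == 2)
  expect_equal(t_oracle[id_row], t_obs, tolerance = 1e-8)
  expect_gte(min(res$p), 1 / (nrow(pairs) + 1))
})

test_that("permutation ANOVA matches an enumeration oracle on 10 records", {
  n <- 10
  set.seed(52)
  d <- data.frame(age = runif(n, 30, 60),
                  q1 = sample(40:46, n, replace = TRUE),
                  q2 = c(4, 4, rep(2, n - 2)),
                  sex = "female", cohort = "A")
  d$qt <- d$q1 + d$q2
  d$expansion_ratio <- 0.3 + 0.01 * d$q1 + 0.08 * (d$q2 == 4) +
    rnorm(n, 0, 0.03)
  small <- suppressWarnings(fit_se_model(d, "Q1"))
  big <- suppressWarnings(fit_se_model(d, "Q1", include_q2 = TRUE))
  pairs <- t(utils::combn(n, 2))
  pm <- t(apply(pairs, 1, function(tp)
    perm_for_assignment(tp, c(1, 2), n)))
  res <- permutation_anova(small, big, perm_matrix = pm)
  ac <- d$age - mean(d$age)
  qc <- d$q1 - mean(d$q1)
  f_small <- stats::lm(d$expansion_ratio ~ ac * qc)
  F_oracle <- apply(pairs, 1, function(tp) {
    z <- as.numeric(seq_len(n) %in% tp)
    f_big <- stats::lm(d$expansion_ratio ~ ac * qc + z + z:ac)
    stats::anova(f_small, f_big)$F[2]
  })
  id_row <- which(pairs[, 1] == 1 & pairs[, 2] == 2)
  expect_equal(res$stat, F_oracle[id_row], tolerance = 1e-8)
  expect_equal(res$p,
               (1 + sum(F_oracle >= res$stat - 1e-9)) / (nrow(pairs) + 1),
               tolerance = 1e-12)
})

test_that("permutation ANOVA handles identity and non-nested inputs", {
  d <- make_se_cohort(60, seed = 53)
  f1 <- fit_se_model(d, "Q1")
  res <- permutation_anova(f1, f1)
  expect_equal(res$stat, 0)
  expect_equal(res$p, 1)
  f2 <- fit_se_model(d, "Q1", include_q2 = TRUE)
  expect_error(permutation_anova(f2, f1),
               class = "httex1_nesting_violation")
})

test_that("permutation p-values are reproducible bit-for-bit from the seed", {
  d <- make_se_cohort(80, seed = 54)
  fit <- fit_se_model(d, "Q1", include_q2 = TRUE)
  r1 <- permute_q2(fit, n_perm = 300, seed = 7)
  r2 <- permute_q2(fit, n_perm = 300, seed = 7)
  expect_identical(r1$p, r2$p)
  r3 <- permute_q2(fit, n_perm = 300, seed = 8)
  expect_false(identical(r1$p, r3$p))
})

test_that("adjusted survival matches direct cumulative-hazard integration", {
  co <- gen_cohort(synth_config(n_participants = 300, seed = 55))
  ppl <- co$participants
  ppl$expansion_score <- somatic_expansion_score(fit_se_model(ppl, "Q1"))
  fit <- fit_cox(ppl, "Q1", include_score = "sign")
  sv <- adjusted_survival(fit, "score_sign")
  # oracle: survival from the Breslow cumulative baseline hazard
  bh <- survival::basehaz(fit$coxph, centered = FALSE)
  d <- fit$data
  strata_names <- levels(bh$strata)
  w <- vapply(strata_names, function(nm) {
    parts <- strsplit(nm, ", ", fixed = TRUE)[[1]]
    sum(d$sex == parts[1] & d$cohort == parts[2])
  }, numeric(1))
  w <- w / sum(w)
  grid <- sort(unique(d$time))
  for (g in c("negative", "positive")) {
    lp <- unname(coef(fit)[["score_signpositive"]]) * (g == "positive")
    smat <- vapply(strata_names, function(nm) {
      hh <- bh[bh$strata == nm, ]
      Hfun <- stats::stepfun(hh$time, c(0, hh$hazard))
      exp(-Hfun(grid) * exp(lp))
    }, numeric(length(grid)))
    s_avg <- drop(smat %*% w)
    med_oracle <- grid[min(which(s_avg <= 0.5))]
    expect_equal(sv[[g]]$median, med_oracle)
    expect_equal(sv[[g]]$surv, s_avg, tolerance = 1e-8)
  }
  # monotonicity: the higher-hazard group has the earlier median
  if (coef(fit)[["score_signpositive"]] > 0)
    expect_lte(sv$positive$median, sv$negative$median)
  else
    expect_gte(sv$positive$median, sv$negative$median)
})

test_that("null grouping coefficients give identical adjusted curves", {
  co <- gen_cohort(synth_config(n_participants = 250, seed = 56))
  ppl <- co$participants
  ppl$expansion_score <- somatic_expansion_score(fit_se_model(ppl, "Q1"))
  fit <- fit_cox(ppl, "Q1", include_score = "sign")
  fit$coxph$coefficients["score_signpositive"] <- 0
  sv <- adjusted_survival(fit, "score_sign")
  expect_equal(sv$positive$surv, sv$negative$surv, tolerance = 1e-12)
  expect_equal(sv$positive$median, sv$negative$median)
})

test_that("noiseless trajectories give every participant the same rate", {
  visits <- do.call(rbind, lapply(1:25, function(i)
    data.frame(participant_id = paste0("P", i), years_followup = 0:3,
               tms = 10 + i + 2.5 * (0:3), tfc = 12 - 0.5 * (0:3))))
  rates <- suppressWarnings(participant_slopes(visits))
  expect_equal(rates$tms_rate, rep(2.5, 25), tolerance = 1e-6)
  expect_equal(rates$tfc_rate, rep(-0.5, 25), tolerance = 1e-6)
})

test_that("BLUP rates are shrunken relative to raw per-participant slopes", {
  co <- gen_cohort(synth_config(n_participants = 200, seed = 57))
  rates <- participant_slopes(co$visits)
  raw <- vapply(split(co$visits, co$visits$participant_id), function(g)
    stats::coef(stats::lm(tms ~ years_followup, data = g))[[2]],
    numeric(1))
  raw <- raw[match(rates$participant_id, names(raw))]
  expect_lte(stats::var(rates$tms_rate), stats::var(raw))
  # with 4 visits the OLS slope noise roughly equals the true slope
  # spread, so cor(BLUP, truth) is expected near 1/sqrt(2)
  expect_gt(stats::cor(rates$tms_rate,
                       co$truth$tms_slope[match(rates$participant_id,
                                                co$participants$id)]),
            0.6)
})

test_that("mixed model recovers the generator's slope spread at n = 200", {
  co <- gen_cohort(synth_config(n_participants = 200, seed = 58))
  v <- co$visits
  fit <- lme4::lmer(tms ~ years_followup + (years_followup | participant_id),
                    data = v)
  tau <- attr(lme4::VarCorr(fit)$participant_id, "stddev")[["years_followup"]]
  truth <- stats::sd(co$truth$tms_slope)
  expect_lt(abs(tau - truth) / truth, 0.2)
})

test_that("least-square means match the g-computation oracle", {
  co <- gen_cohort(synth_config(n_participants = 500, seed = 59))
  ppl <- co$participants
  ppl$expansion_score <- somatic_expansion_score(fit_se_model(ppl, "Q1"))
  rates <- participant_slopes(co$visits)
  ppl <- merge(ppl, rates, by.x = "id", by.y = "participant_id",
               sort = FALSE)
  for (resp in c("baseline_tms", "progression", "tms_rate")) {
    fit <- suppressMessages(fit_outcome_linear(ppl, resp, "Q1"))
    mf <- fit$lm$model
    for (k in seq_len(nrow(fit$lsmeans))) {
      lv <- fit$lsmeans$q2[k]
      nd <- mf
      nd$q2f <- factor(lv, levels = levels(mf$q2f))
      oracle <- mean(stats::predict(fit$lm, newdata = nd))
      expect_equal(fit$lsmeans$estimate[k], oracle, tolerance = 1e-10)
    }
  }
})

test_that("least-square means agree with emmeans under proportional weights", {
  skip_if_not_installed("emmeans")
  co <- gen_cohort(synth_config(n_participants = 500, seed = 60))
  ppl <- co$participants
  ppl$expansion_score <- somatic_expansion_score(fit_se_model(ppl, "Q1"))
  fit <- suppressMessages(fit_outcome_linear(ppl, "baseline_tms", "Q1"))
  em <- as.data.frame(emmeans::emmeans(fit$lm, "q2f",
                                       weights = "proportional"))
  got <- fit$lsmeans[match(em$q2f, fit$lsmeans$q2), ]
  expect_equal(got$estimate, em$emmean, tolerance = 1e-8)
  expect_equal(got$se, em$SE, tolerance = 1e-8)
})

test_that("zeroed Q2 coefficients collapse ls-means to the grand mean", {
  co <- gen_cohort(synth_config(n_participants = 400, seed = 61))
  ppl <- co$participants
  ppl$expansion_score <- somatic_expansion_score(fit_se_model(ppl, "Q1"))
  fit <- suppressMessages(fit_outcome_linear(ppl, "baseline_tms", "Q1"))
  zeroed <- fit$lm
  q2cols <- grep("^q2f", names(stats::coef(zeroed)))
  zeroed$coefficients[q2cols] <- 0
  d <- zeroed$model
  d$q2f <- d$q2f
  lsm <- httex1:::.lsmeans_q2(zeroed, d)
  expect_equal(diff(range(lsm$estimate)), 0, tolerance = 1e-12)
})

test_that("baseline TMS Q2 = 0 contrast recovers the injected 2.3-unit shift", {
  co <- gen_cohort(synth_config(n_participants = 734, seed = 62))
  ppl <- co$participants
  ppl$expansion_score <- somatic_expansion_score(fit_se_model(ppl, "Q1"))
  fit <- suppressMessages(fit_outcome_linear(ppl, "baseline_tms", "Q1"))
  row <- fit$coefficients["q2f0", ]
  expect_true(row$lower <= 2.3 && 2.3 <= row$upper)
})

test_that("BH-FDR matches hand cases and a slow step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_error(bh_fdr(c(0.1, 1.2)), class = "httex1_input_error")
  slow_bh <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- numeric(m)
    run_min <- Inf
    for (i in seq_len(m)) {
      rank_i <- m - i + 1
      run_min <- min(run_min, p[o[i]] * m / rank_i)
      adj[o[i]] <- min(run_min, 1)
    }
    adj
  }
  set.seed(63)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))
    adj <- bh_fdr(p)
    expect_equal(unname(adj), slow_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})
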