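test_that("2x2 statistics reproduce the published training-cohort rows", {
  # age >= 60: 63/162 AA vs 11/50 IBMFS
  cs <- contingency_stats(63, 99, 11, 39)
  expect_equal(round(cs$odds_ratio, 3), 2.256)
  expect_equal(round(cs$ci_low, 3), 1.077)
  expect_equal(round(cs$ci_high, 3), 4.729)
  # severe cytopenias
  cs <- contingency_stats(129, 33, 4, 46)
  expect_equal(round(cs$odds_ratio, 3), 44.955)
  expect_equal(round(cs$ci_low, 3), 15.101)
  expect_equal(round(cs$ci_high, 3), 133.830)
  # red flags (IBMFS direction, OR << 1)
  expect_equal(round(contingency_stats(6, 156, 45, 5)$odds_ratio, 3), 0.004)
  # AA-associated conditions: zero cell triggers the +0.5 correction
  cs <- contingency_stats(10, 152, 0, 50)
  expect_true(cs$corrected)
  expect_equal(round(cs$odds_ratio, 3), 6.954)
  # symmetric tables have OR exactly 1
  for (k in c(1, 7, 40))
    expect_equal(contingency_stats(k, k, k, k)$odds_ratio, 1)
  expect_error(contingency_stats(0, 0, 0, 0), "all-zero")
  expect_error(contingency_stats(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p-value equals hypergeometric enumeration on small tables", {
  tables <- list(c(3, 2, 1, 4), c(5, 0, 2, 6), c(2, 2, 2, 2), c(8, 1, 3, 7))
  for (tb in tables) {
    cs <- contingency_stats(tb[1], tb[2], tb[3], tb[4])
    expect_equal(cs$p_value, fisher_p_enum(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-10)
  }
})

test_that("AUC equals exhaustive pair counting, including heavy ties", {
  expect_equal(roc_auc_delong(c(1, 2, 3, 10, 11, 12),
                              c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc_delong(rep(5, 10), rep(c(0, 1), 5))$auc, 0.5)
  for (seed in 1:25) {
    inst <- tied_instance(seed)
    if (length(unique(inst$labels)) < 2) next
    expect_equal(roc_auc_delong(inst$scores, inst$labels)$auc,
                 auc_pair_count(inst$scores, inst$labels))
  }
  expect_error(roc_auc_delong(1:5, rep(1, 5)), "both classes")
})

test_that("label swap maps AUC to its complement and keeps the CI valid", {
  for (seed in 1:10) {
    inst <- tied_instance(seed, n = 20)
    if (length(unique(inst$labels)) < 2) next
    r <- roc_auc_delong(inst$scores, inst$labels)
    r_sw <- roc_auc_delong(inst$scores, 1 - inst$labels)
    expect_equal(r_sw$auc, 1 - r$auc)
    expect_equal(r_sw$variance, r$variance)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
    expect_true(r$ci_low >= 0 && r$ci_high <= 1)
  }
})

test_that("DeLong variance and CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:8) {
    set.seed(seed)
    y <- rep(c(0, 1), times = c(40, 60))
    s <- rnorm(100, mean = y)
    r <- roc_auc_delong(s, y)
    pr <- pROC::roc(y, s, quiet = TRUE, direction = "<")
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$variance, as.numeric(pROC::var(pr, method = "delong")),
                 tolerance = 1e-10)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(c(r$ci_low, r$ci_high), ci[c(1, 3)], tolerance = 1e-9)
  }
})

test_that("paired DeLong test is null for identical or rank-equivalent scores", {
  inst <- tied_instance(3, n = 20)
  r <- delong_paired_test(inst$scores, inst$scores, inst$labels)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  # AUC is rank-invariant, so a monotone transform gives the same AUC and
  # identical structural components
  r2 <- delong_paired_test(inst$scores, exp(inst$scores / 20), inst$labels)
  expect_equal(r2$chi2, 0)
})

test_that("paired DeLong chi-square matches an independent implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:6) {
    set.seed(seed)
    y <- rep(c(0, 1), times = c(35, 45))
    a <- rnorm(80, mean = 1.2 * y)
    b <- 0.6 * a + rnorm(80, mean = 0.7 * y)
    r <- delong_paired_test(a, b, y)
    pr <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                         pROC::roc(y, b, quiet = TRUE, direction = "<"),
                         method = "delong", paired = TRUE)
    expect_equal(r$chi2, as.numeric(pr$statistic)^2, tolerance = 1e-9)
    expect_equal(r$p_value, pr$p.value, tolerance = 1e-9)
    # label swap leaves the test statistic unchanged
    r_sw <- delong_paired_test(a, b, 1 - y)
    expect_equal(r_sw$chi2, r$chi2, tolerance = 1e-12)
  }
})

test_that("Brier score closed forms and hand-computed cases hold", {
  expect_equal(brier_score(c(0, 1, 1, 0), c(0, 1, 1, 0)), 0)
  expect_equal(brier_score(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  # direct arithmetic: mean((p - y)^2)
  p <- c(0.9, 0.2, 0.6, 0.4)
  y <- c(1, 0, 0, 1)
  expect_equal(brier_score(p, y), (0.01 + 0.04 + 0.36 + 0.36) / 4)
  expect_error(brier_score(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("calibration recovers parameters of a known logistic model", {
  set.seed(1)
  n <- 4000
  s <- sample(seq(-70, 80, by = 10), n, replace = TRUE)
  b0 <- -1; b1 <- 0.08
  y <- rbinom(n, 1, plogis(b0 + b1 * s))
  rep_ <- calibrate_and_test(s, y)
  se <- summary(stats::glm(y ~ s, family = binomial()))$coefficients[, 2]
  expect_true(abs(rep_$intercept - b0) < 3 * se[1])
  expect_true(abs(rep_$slope - b1) < 3 * se[2])
  expect_true(rep_$converged)
  expect_gt(rep_$hl_p, 0.05)
  expect_equal(sum(rep_$bins$n), n)
  expect_equal(rep_$brier, mean((rep_$fitted - y)^2))
})

test_that("calibration flags gross miscalibration and degenerate binning", {
  set.seed(2)
  n <- 2000
  s <- runif(n, -1, 1)
  # U-shaped truth that no monotone logistic in s can calibrate
  y <- rbinom(n, 1, plogis(6 * abs(s) - 2))
  rep_ <- calibrate_and_test(s, y)
  expect_lt(rep_$hl_p, 1e-4)
  # two distinct score values collapse the decile bins
  s2 <- rep(c(0, 30), each = 50)
  y2 <- rbinom(100, 1, plogis(0.05 * s2 - 0.5))
  rep2 <- calibrate_and_test(s2, y2)
  expect_lte(nrow(rep2$bins), 2)
  expect_true(is.na(rep2$hl_p))  # df < 1 is flagged, not fabricated
  # complete separation is reported, not silently returned
  rep3 <- calibrate_and_test(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_false(rep3$converged)
})

test_that("threshold sweep conserves counts and reports empty strata as NA", {
  # stratum composition of the published training cohort at the two
  # decision thresholds: 46 of 53 below 0 have IBMFS, 136 of 136 at >= 30
  # have AA
  scores <- c(rep(-10, 53), rep(10, 23), rep(40, 136))
  labels <- c(rep(c(0, 1), c(46, 7)), rep(c(1, 0), c(19, 4)), rep(1, 136))
  sw <- threshold_sweep(scores, labels, thresholds = c(-100, 0, 30))
  expect_true(all(sw$tp + sw$fp + sw$fn + sw$tn == length(scores)))
  at0 <- sw[sw$threshold == 0, ]
  expect_equal(at0$npv_ibmfs, 46 / 53)
  at30 <- sw[sw$threshold == 30, ]
  expect_equal(at30$ppv_aa, 1)
  expect_equal(at30$tp, 136)
  # below the minimum score everything is predicted AA
  lowest <- sw[sw$threshold == -100, ]
  expect_equal(lowest$sensitivity, 1)
  expect_true(is.na(lowest$npv_ibmfs))
})

test_that("PPV rises with the threshold on a score-separated cohort", {
  coh <- generate_cohort(cohort_spec(n = 3000), seed = 1)
  s <- compute_pass(coh)
  sw <- threshold_sweep(s$total, coh$diagnosis)
  ppv <- sw$ppv_aa[!is.na(sw$ppv_aa)]
  expect_true(all(diff(ppv) >= -1e-12))
})

test_that("Fleiss' kappa matches its defining formula and limiting cases", {
  # three raters in perfect agreement across two categories
  perfect <- rbind(c(3, 0), c(0, 3), c(3, 0), c(0, 3))
  expect_equal(fleiss_kappa(perfect)$kappa, 1)
  # hand-worked 4-subject, 3-rater matrix:
  # P_i = (1, 1, 1/3, 0), Pbar = 7/12, Pe = 62/144
  m <- rbind(c(3, 0, 0), c(0, 3, 0), c(1, 2, 0), c(1, 1, 1))
  expect_equal(fleiss_kappa(m)$kappa, (7 / 12 - 62 / 144) / (1 - 62 / 144))
  # uniformly random ratings agree only by chance
  set.seed(1)
  rnd <- t(vapply(seq_len(10000),
                  function(i) as.vector(rmultinom(1, 3, c(.5, .5))),
                  numeric(2)))
  expect_lt(abs(fleiss_kappa(rnd)$kappa), 0.02)
  # single-category degeneracy is flagged
  expect_warning(k <- fleiss_kappa(rbind(c(3, 0), c(3, 0)))$kappa,
                 "undefined")
  expect_true(is.na(k))
  expect_error(fleiss_kappa(rbind(c(2, 0), c(1, 2))), "same number")
})

test_that("univariate cohort summary reproduces the published odds ratios", {
  coh <- training_margins_cohort()
  u <- univariate_cohort_summary(coh)
  expect_equal(round(u$odds_ratio[u$variable == "age_ge60"], 3), 2.256)
  expect_equal(round(u$odds_ratio[u$variable == "severe"], 3), 44.955)
  expect_equal(round(u$odds_ratio[u$variable == "acute"], 3), 39.513)
  expect_equal(round(u$odds_ratio[u$variable == "somatic"], 3), 54.091)
  expect_equal(round(u$odds_ratio[u$variable == "red_flags"], 3), 0.004)
  expect_equal(round(u$odds_ratio[u$variable == "tl_short"], 3), 0.021)
  expect_equal(round(u$ci_low[u$variable == "age_ge60"], 3), 1.077)
  expect_equal(round(u$ci_high[u$variable == "age_ge60"], 3), 4.729)
  # telomere factor restricted to evaluable patients
  expect_equal(u$aa_n[u$variable == "tl_short"], 77)
  expect_equal(u$ibmfs_n[u$variable == "tl_short"], 39)
})

test_that("identical class distributions give unit odds ratios", {
  half <- all_factor_records()
  coh <- rbind(cbind(half, diagnosis = "AA"),
               cbind(half, diagnosis = "IBMFS"))
  u <- univariate_cohort_summary(coh)
  expect_true(all(abs(u$odds_ratio - 1) < 1e-12))
})

test_that("multivariate logistic recovers known coefficients at large n", {
  set.seed(1)
  n <- 5000
  x <- matrix(rbinom(n * 7, 1, 0.4), n, 7)
  colnames(x) <- c("age_ge60", "severe", "acute", "somatic",
                   "aa_condition", "red_flags", "tl_short")
  beta <- c(0.5, 1.6, 1.0, 0.9, 0.4, -1.8, -1.1)
  y <- rbinom(n, 1, plogis(0.3 + x %*% beta))
  coh <- data.frame(
    severity = ifelse(x[, "severe"] == 1, "severe", "non_severe"),
    acuity = ifelse(x[, "acute"] == 1, "acute", "chronic"),
    age_ge60 = x[, "age_ge60"] == 1,
    red_flags = x[, "red_flags"] == 1,
    aa_condition = x[, "aa_condition"] == 1,
    somatic = ifelse(x[, "somatic"] == 1, "present", "absent"),
    tl_lt_1st = ifelse(x[, "tl_short"] == 1, "short", "not_short"),
    diagnosis = ifelse(y == 1, "AA", "IBMFS")
  )
  fit <- multivariate_logistic(coh)
  expect_false(attr(fit, "separation"))
  want <- c(age_ge60 = 0.5, severe = 1.6, acute = 1.0, somatic = 0.9,
            aa_condition = 0.4, red_flags = -1.8, tl_short = -1.1)
  for (v in names(want)) {
    row <- fit[fit$variable == v, ]
    expect_lt(abs(row$beta - want[[v]]), 3 * row$se)
  }
})

test_that("null predictors stay near OR 1 and separation raises the flag", {
  set.seed(2)
  n <- 4000
  strong <- rbinom(n, 1, 0.5)
  noise <- matrix(rbinom(n * 2, 1, 0.5), n, 2)
  y <- rbinom(n, 1, plogis(-1 + 3 * strong))
  coh <- data.frame(
    severity = ifelse(strong == 1, "severe", "non_severe"),
    acuity = ifelse(noise[, 1] == 1, "acute", "chronic"),
    age_ge60 = noise[, 2] == 1,
    red_flags = FALSE, aa_condition = FALSE,
    somatic = "unknown", tl_lt_1st = "unknown",
    diagnosis = ifelse(y == 1, "AA", "IBMFS")
  )
  fit <- suppressWarnings(multivariate_logistic(coh))
  noise_or <- fit$odds_ratio[fit$variable %in% c("acute", "age_ge60")]
  expect_true(all(abs(log(noise_or)) < 0.25))
  # constructed perfectly separable instance
  sep <- data.frame(
    severity = rep(c("severe", "non_severe"), each = 20),
    acuity = rep(c("acute", "chronic"), 20),
    age_ge60 = rep(c(TRUE, FALSE), 20),
    red_flags = FALSE, aa_condition = FALSE,
    somatic = "unknown", tl_lt_1st = "unknown",
    diagnosis = rep(c("AA", "IBMFS"), each = 20)
  )
  expect_warning(fit2 <- multivariate_logistic(sep), "separation")
  expect_true(attr(fit2, "separation"))
})
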