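#' 2x2 contingency statistics: odds ratio, Woolf CI, Fisher exact test
#'
#' The table is laid out with the factor of interest on rows of the first
#' group: `a` = group 1 exposed, `b` = group 1 unexposed, `c` = group 2
#' exposed, `d` = group 2 unexposed, so the odds ratio `(a*d)/(b*c)`
#' compares exposure odds of group 1 to group 2. The 95% confidence
#' interval uses the Woolf logit method; when any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied to the odds
#' ratio and its interval (`exp(log(OR) +/- 1.96 * SE)`). The p-value is
#' the two-sided Fisher exact test on the uncorrected counts.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List of class `contingency_stats`: the counts, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, and `corrected` (whether the +0.5
#'   correction was used).
#' @examples
#' contingency_stats(63, 99, 11, 39)   # OR 2.256, CI 1.077-4.729
#' @export
contingency_stats <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("all-zero table")
  corrected <- any(cells == 0)
  cc <- if (corrected) cells + 0.5 else cells
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  p <- stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
  structure(list(a = a, b = b, c = c, d = d,
                 odds_ratio = unname(or), ci_low = ci[1], ci_high = ci[2],
                 p_value = p, corrected = corrected),
            class = "contingency_stats")
}

#' @export
print.contingency_stats <- function(x, ...) {
  cat(sprintf("2x2 table [%d %d / %d %d]\n", x$a, x$b, x$c, x$d))
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f), Fisher p = %.3g%s\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p_value,
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

.as_binary <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("AA", "IBMFS")))
      stop("character labels must be AA / IBMFS")
    labels <- as.integer(labels == "AA")
  }
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!is.numeric(labels) || anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  as.integer(labels)
}

# DeLong structural components: V10 per positive, V01 per negative,
# computed with midranks so ties count 1/2.
.delong_components <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' ROC AUC with DeLong variance and confidence interval
#'
#' Computes the area under the ROC curve by the midrank (tie = 1/2)
#' Mann-Whitney estimator, with its nonparametric DeLong variance and a
#' Wald 95% confidence interval truncated to \[0, 1\]. Scores must be
#' oriented so that higher values indicate the positive class (AA).
#'
#' @param scores Numeric predictor (e.g. PASS totals).
#' @param labels Binary outcome: 0/1, logical, or `"AA"`/`"IBMFS"` with AA
#'   positive.
#' @param conf_level Confidence level for the Wald interval.
#' @return List of class `roc_result`: `auc`, `variance`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`.
#' @export
roc_auc_delong <- function(scores, labels, conf_level = 0.95) {
  y <- .as_binary(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  if (length(unique(y)) < 2) stop("both classes must be present")
  cmp <- .delong_components(scores, y)
  v <- stats::var(cmp$v10) / cmp$m + stats::var(cmp$v01) / cmp$n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, cmp$auc + c(-1, 1) * z * sqrt(v)))
  structure(list(auc = cmp$auc, variance = v, ci_low = ci[1], ci_high = ci[2],
                 n_pos = cmp$m, n_neg = cmp$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), DeLong variance %.3g (%d+/%d-)\n",
              x$auc, x$ci_low, x$ci_high, x$variance, x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong chi-square test for two correlated AUCs
#'
#' Tests equality of the AUCs of two scores measured on the same patients,
#' using the paired DeLong covariance of the two estimators. The statistic
#' `(AUC_a - AUC_b)^2 / var(AUC_a - AUC_b)` is referred to chi-square with
#' one degree of freedom.
#'
#' @param scores_a,scores_b Numeric scores on the same patients.
#' @param labels Shared binary labels (see [roc_auc_delong()]).
#' @return List: `chi2`, `p_value`, `auc_a`, `auc_b`, `var_diff`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  y <- .as_binary(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop("scores and labels differ in length")
  if (length(unique(y)) < 2) stop("both classes must be present")
  ca <- .delong_components(scores_a, y)
  cb <- .delong_components(scores_b, y)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / ca$m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / ca$n
  d <- ca$auc - cb$auc
  if (vd <= .Machine$double.eps^0.75) {
    if (abs(d) <= sqrt(.Machine$double.eps))
      return(list(chi2 = 0, p_value = 1, auc_a = ca$auc, auc_b = cb$auc,
                  var_diff = 0))
    stop("zero DeLong variance with unequal AUCs")
  }
  chi2 <- d^2 / vd
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       auc_a = ca$auc, auc_b = cb$auc, var_diff = vd)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; lower is better, 0.25 corresponds to a constant 0.5 forecast.
#'
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @param labels Binary outcomes (see [roc_auc_delong()]).
#' @return Numeric scalar in \[0, 1\].
#' @export
brier_score <- function(probabilities, labels) {
  y <- .as_binary(labels)
  p <- as.numeric(probabilities)
  if (length(p) != length(y)) stop("lengths differ")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]")
  mean((p - y)^2)
}

#' Logistic recalibration with Hosmer-Lemeshow test and Brier score
#'
#' Fits a univariate logistic regression of the outcome on the score
#' (maximum likelihood), derives per-patient predicted probabilities, and
#' summarizes calibration: a binned calibration table over quantile bins of
#' predicted probability, the Hosmer-Lemeshow statistic over those bins
#' (degenerate duplicate bin boundaries are merged; df = bins - 2), and the
#' Brier score of the fitted probabilities. A quasi-separated fit is
#' returned with `converged = FALSE` rather than failing.
#'
#' @param scores Numeric score per patient.
#' @param labels Binary outcomes (see [roc_auc_delong()]).
#' @param n_bins Target number of probability bins (default 10, deciles).
#' @return List of class `calibration_report`: `intercept`, `slope`, `bins`
#'   (data frame: `mean_pred`, `obs_freq`, `n`), `brier`, `hl_statistic`,
#'   `hl_df`, `hl_p`, `converged`, `fitted` (per-patient probabilities).
#' @export
calibrate_and_test <- function(scores, labels, n_bins = 10) {
  y <- .as_binary(labels)
  s <- as.numeric(scores)
  if (length(s) != length(y)) stop("lengths differ")
  if (length(unique(y)) < 2) stop("both classes must be present")

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ s, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  converged <- fit$converged && !sep_warn
  p <- stats::fitted(fit)

  qs <- stats::quantile(p, probs = seq(0, 1, length.out = n_bins + 1))
  br <- unique(qs)
  bins <- if (length(br) > 1)
    cut(p, breaks = br, include.lowest = TRUE) else factor(rep(1, length(p)))
  g <- nlevels(bins)
  n_g <- as.vector(table(bins))
  o_g <- as.vector(tapply(y, bins, sum))
  e_g <- as.vector(tapply(p, bins, sum))
  pbar <- e_g / n_g
  denom <- n_g * pbar * (1 - pbar)
  ok <- denom > 0
  hl <- sum((o_g[ok] - e_g[ok])^2 / denom[ok])
  hl_df <- g - 2L
  hl_p <- if (hl_df >= 1) stats::pchisq(hl, df = hl_df, lower.tail = FALSE)
          else NA_real_

  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    bins = data.frame(mean_pred = as.vector(tapply(p, bins, mean)),
                      obs_freq = o_g / n_g, n = n_g),
    brier = mean((p - y)^2),
    hl_statistic = hl, hl_df = hl_df, hl_p = hl_p,
    converged = converged, fitted = as.vector(p)
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Logistic recalibration: intercept %.3f, slope %.3f%s\n",
              x$intercept, x$slope,
              if (!x$converged) " [non-converged / separated]" else ""))
  cat(sprintf("Brier %.3f; Hosmer-Lemeshow chi2 %.2f on %d df, p = %s\n",
              x$brier, x$hl_statistic, x$hl_df,
              if (is.na(x$hl_p)) "NA (too few bins)" else
                sprintf("%.3g", x$hl_p)))
  invisible(x)
}

#' Diagnostic metrics across score thresholds
#'
#' At each threshold `t` a patient is predicted AA iff `score >= t`.
#' Sensitivity and PPV refer to the AA prediction; NPV is the proportion of
#' IBMFS among patients below the threshold (so at `t = 0` it is the PPV
#' for IBMFS among negative scores). Metrics with an empty stratum are
#' reported as `NA`, never coerced to 0 or 1; the stratum counts are always
#' reported.
#'
#' @param scores Numeric/integer scores.
#' @param labels Binary labels (see [roc_auc_delong()]).
#' @param thresholds Integer thresholds to evaluate.
#' @return Data frame: `threshold`, `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `ppv_aa`, `npv_ibmfs`.
#' @export
threshold_sweep <- function(scores, labels,
                            thresholds = seq(-70, 80, by = 10)) {
  y <- .as_binary(labels)
  s <- as.numeric(scores)
  if (length(s) != length(y)) stop("lengths differ")
  rows <- lapply(thresholds, function(t) {
    pred <- s >= t
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    fn <- sum(!pred & y == 1); tn <- sum(!pred & y == 0)
    data.frame(
      threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      ppv_aa = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv_ibmfs = if (tn + fn > 0) tn / (tn + fn) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for a fixed number of raters assigning
#' subjects to nominal categories, from the subjects x categories count
#' matrix.
#'
#' @param ratings Integer matrix, one row per subject, one column per
#'   category; each row sums to the (constant) number of raters.
#' @return List: `kappa`, `p_bar` (mean observed agreement), `p_e`
#'   (expected agreement), `n_raters`. `kappa` is `NA` with a warning when
#'   all ratings fall in a single category (`p_e = 1`).
#' @examples
#' m <- rbind(c(3, 0), c(0, 3), c(3, 0))  # 3 raters, perfect agreement
#' fleiss_kappa(m)$kappa                  # 1
#' @export
fleiss_kappa <- function(ratings) {
  m <- as.matrix(ratings)
  if (any(m < 0) || any(m != round(m))) stop("ratings must be counts")
  k <- unique(rowSums(m))
  if (length(k) != 1) stop("every subject must be rated by the same number of raters")
  if (k < 2) stop("need at least 2 raters")
  n <- nrow(m)
  p_j <- colSums(m) / (n * k)
  p_i <- (rowSums(m^2) - k) / (k * (k - 1))
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  kappa <- if (1 - p_e < .Machine$double.eps) {
    warning("all ratings in one category: kappa undefined")
    NA_real_
  } else (p_bar - p_e) / (1 - p_e)
  list(kappa = kappa, p_bar = p_bar, p_e = p_e, n_raters = as.integer(k))
}

.factor_indicators <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (!("age_ge60" %in% names(cohort)) && "age_years" %in% names(cohort))
    cohort$age_ge60 <- cohort$age_years >= 60
  som <- as.character(cohort$somatic)
  tl <- as.character(cohort$tl_lt_1st)
  list(
    age_ge60 = as.logical(cohort$age_ge60),
    severe = as.character(cohort$severity) == "severe",
    acute = as.character(cohort$acuity) == "acute",
    # somatic: missing testing counted as absence of abnormal findings
    somatic = !is.na(som) & som == "present",
    aa_condition = as.logical(cohort$aa_condition),
    red_flags = as.logical(cohort$red_flags),
    # telomeres: restricted to evaluable patients
    tl_short = ifelse(is.na(tl) | tl == "unknown", NA, tl == "short")
  )
}

#' Univariate group comparison of the PASS factors
#'
#' One row per PASS factor comparing AA vs IBMFS: class-wise counts, odds
#' ratio with Woolf 95% CI and two-sided Fisher exact p-value (see
#' [contingency_stats()]). The somatic factor counts untested patients as
#' negative (testing absence treated as absence of abnormal findings),
#' while the telomere factor is restricted to patients with an evaluable
#' measurement. If an `age_years` column is present a two-sided Welch t
#' test of age by diagnosis is attached as the `age_ttest` attribute.
#'
#' @param cohort Data frame of patient records with a `diagnosis` column.
#' @return Data frame: `variable`, `aa_pos`, `aa_n`, `ibmfs_pos`,
#'   `ibmfs_n`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`. Single-level
#'   factors are skipped with a warning.
#' @export
univariate_cohort_summary <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (!("diagnosis" %in% names(cohort)) || anyNA(cohort$diagnosis))
    stop("diagnosis labels are required for every record")
  aa <- cohort$diagnosis == "AA"
  ind <- .factor_indicators(cohort)
  rows <- list()
  for (v in names(ind)) {
    x <- ind[[v]]
    use <- !is.na(x)
    a <- sum(x[use] & aa[use]);    b <- sum(!x[use] & aa[use])
    cc <- sum(x[use] & !aa[use]);  d <- sum(!x[use] & !aa[use])
    if ((a + cc == 0) || (b + d == 0)) {
      warning("factor '", v, "' has a single level; skipped")
      next
    }
    cs <- contingency_stats(a, b, cc, d)
    rows[[v]] <- data.frame(variable = v, aa_pos = a, aa_n = a + b,
                            ibmfs_pos = cc, ibmfs_n = cc + d,
                            odds_ratio = cs$odds_ratio, ci_low = cs$ci_low,
                            ci_high = cs$ci_high, p_value = cs$p_value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if ("age_years" %in% names(cohort))
    attr(out, "age_ttest") <- stats::t.test(cohort$age_years[aa],
                                            cohort$age_years[!aa])
  out
}

#' Multivariate logistic regression of diagnosis on the seven PASS factors
#'
#' Maximum-likelihood logistic fit of AA (vs IBMFS) on the seven factor
#' indicators, with Wald odds ratios, 95% confidence intervals and
#' p-values. The somatic and telomere indicators treat unknown as absent so
#' every record contributes. Quasi-separation (common with near-perfect
#' predictors such as red flags) is detected and flagged via the
#' `separation` attribute instead of silently returning unstable
#' coefficients.
#'
#' @param cohort Data frame of patient records with `diagnosis`.
#' @return Data frame: `variable`, `beta`, `se`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`; attributes `separation` (logical) and `fit`.
#' @export
multivariate_logistic <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (!("diagnosis" %in% names(cohort)) || anyNA(cohort$diagnosis))
    stop("diagnosis labels are required for every record")
  y <- as.integer(cohort$diagnosis == "AA")
  ind <- .factor_indicators(cohort)
  x <- data.frame(lapply(ind, function(z) as.integer(z %in% TRUE)))
  keep <- vapply(x, function(z) length(unique(z)) > 1, logical(1))
  if (sum(keep) < 2) stop("need at least 2 non-constant predictors")
  x <- x[keep]
  dat <- cbind(y = y, x)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  vars <- names(x)
  est <- se <- p <- stats::setNames(rep(NA_real_, length(vars)), vars)
  rn <- intersect(rownames(sm), vars)  # aliased coefficients stay NA
  est[rn] <- sm[rn, 1]; se[rn] <- sm[rn, 2]; p[rn] <- sm[rn, 4]
  separation <- sep_warn || !fit$converged || any(abs(est) > 15, na.rm = TRUE)
  out <- data.frame(variable = vars, beta = unname(est), se = unname(se),
                    odds_ratio = exp(unname(est)),
                    ci_low = exp(unname(est - stats::qnorm(0.975) * se)),
                    ci_high = exp(unname(est + stats::qnorm(0.975) * se)),
                    p_value = unname(p))
  rownames(out) <- NULL
  attr(out, "separation") <- separation
  attr(out, "fit") <- fit
  if (separation)
    warning("quasi-separation detected: Wald statistics are unreliable")
  out
}

#' Full evaluation report for a scored, labeled cohort
#'
#' Convenience wrapper combining discrimination ([roc_auc_delong()]),
#' calibration ([calibrate_and_test()]) and the threshold predictive-value
#' sweep ([threshold_sweep()]), plus the per-tier positive predictive
#' values at the published thresholds (AA at score >= 30, IBMFS at
#' score < 0, AA within 0-20).
#'
#' @param scores Integer PASS totals.
#' @param labels Binary labels (see [roc_auc_delong()]).
#' @param thresholds Thresholds for the sweep.
#' @return List of class `pass_evaluation`: `roc`, `calibration`, `sweep`,
#'   `tiers` (data frame of per-tier counts and PPVs), `n`.
#' @export
evaluate_scores <- function(scores, labels,
                            thresholds = seq(-70, 80, by = 10)) {
  y <- .as_binary(labels)
  s <- as.numeric(scores)
  tier <- classify_tier(s)
  tier_tab <- data.frame(
    tier = levels(tier),
    n = as.vector(table(tier)),
    n_aa = as.vector(tapply(y, tier, sum, default = 0L))
  )
  tier_tab$ppv <- ifelse(tier_tab$n > 0,
                         ifelse(tier_tab$tier == "IBMFS_likely",
                                (tier_tab$n - tier_tab$n_aa) / tier_tab$n,
                                tier_tab$n_aa / tier_tab$n),
                         NA_real_)
  structure(list(
    roc = roc_auc_delong(s, y),
    calibration = calibrate_and_test(s, y),
    sweep = threshold_sweep(s, y, thresholds),
    tiers = tier_tab,
    n = length(y)
  ), class = "pass_evaluation")
}

#' @export
print.pass_evaluation <- function(x, ...) {
  cat("PASS evaluation,", x$n, "patients\n")
  print(x$roc)
  print(x$calibration)
  cat("Per-tier predictive values:\n")
  print(x$tiers, row.names = FALSE)
  invisible(x)
}
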