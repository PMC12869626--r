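#' Build the seven-factor indicator matrix from patient records
#'
#' Each PASS factor is coded as a single 0/1 indicator of the listed level
#' (age >= 60, severe cytopenias, acute onset, AA-associated somatic change
#' present, AA-associated condition present, IBMFS red flags present,
#' lymphocyte telomere length < 1st percentile). Unknown somatic or
#' telomere status codes to 0, matching the score's missing-data rule.
#'
#' @param cohort Data frame of patient records (see [pass_patient()]).
#' @return Numeric matrix with columns `age_ge60`, `severe`, `acute`,
#'   `somatic`, `aa_condition`, `red_flags`, `tl_short`.
#' @export
pass_features <- function(cohort) {
  ind <- .factor_indicators(cohort)
  x <- vapply(ind, function(z) as.numeric(z %in% TRUE),
              numeric(nrow(as.data.frame(cohort))))
  colnames(x) <- names(ind)
  x
}

#' L1-penalized logistic regression path
#'
#' Fits the lasso-penalized logistic regression of a binary outcome on a
#' feature matrix over a decreasing grid of penalty values, with an
#' unpenalized intercept. The grid defaults to 100 log-spaced values from
#' the smallest penalty that shrinks every slope to zero down to 1e-4 of
#' that value. Features are left on their original scale (the PASS factors
#' are comparable 0/1 indicators), so coefficients are directly
#' interpretable for point conversion.
#'
#' @param features Numeric matrix, one column per candidate factor; no
#'   constant columns.
#' @param labels Binary outcome (see [roc_auc_delong()]).
#' @param lambda Optional penalty grid (decreasing positive reals).
#' @param nlambda,lambda_min_ratio Grid size and lower endpoint ratio when
#'   `lambda` is not supplied.
#' @param standardize Standardize features internally (default `FALSE` for
#'   binary indicator features).
#' @param ... Passed to [glmnet::glmnet()].
#' @return List of class `pass_lasso_path`: `lambda`, `beta` (features x
#'   lambda matrix), `intercept` (per lambda), and the underlying `fit`.
#' @export
lasso_logistic_path <- function(features, labels, lambda = NULL,
                                nlambda = 100, lambda_min_ratio = 1e-4,
                                standardize = FALSE, ...) {
  y <- .as_binary(labels)
  x <- as.matrix(features)
  if (nrow(x) != length(y)) stop("features and labels differ in length")
  if (any(apply(x, 2, function(z) length(unique(z))) < 2))
    stop("constant feature column(s) present")
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = lambda, nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio,
                        standardize = standardize, ...)
  structure(list(lambda = fit$lambda, beta = as.matrix(fit$beta),
                 intercept = as.numeric(fit$a0), fit = fit),
            class = "pass_lasso_path")
}

#' Select the penalty by stratified k-fold cross-validation
#'
#' Partitions the cohort into `k` folds stratified by class (every fold
#' contains both outcomes), computes the mean held-out binomial deviance
#' along the penalty path, and returns the penalty minimizing it (the
#' minimum-deviance criterion).
#'
#' @param features,labels As in [lasso_logistic_path()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed fixing the fold assignment (required for
#'   reproducibility).
#' @param lambda Optional penalty grid.
#' @param standardize See [lasso_logistic_path()].
#' @return List of class `pass_lasso_cv`: `lambda_min`, `lambda`, `cvm`
#'   (mean CV deviance), `cvsd` (its SE), `foldid`, and the
#'   [glmnet::cv.glmnet()] object as `fit`.
#' @export
cv_select_lambda <- function(features, labels, k = 10, seed,
                             lambda = NULL, standardize = FALSE) {
  y <- .as_binary(labels)
  x <- as.matrix(features)
  if (missing(seed)) stop("seed is required")
  if (k > min(table(y))) stop("k exceeds the size of the smaller class")
  foldid <- integer(length(y))
  set.seed(as.integer(seed))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  cvfit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                             type.measure = "deviance", foldid = foldid,
                             lambda = lambda, standardize = standardize)
  structure(list(lambda_min = cvfit$lambda.min, lambda = cvfit$lambda,
                 cvm = cvfit$cvm, cvsd = cvfit$cvsd, foldid = foldid,
                 fit = cvfit),
            class = "pass_lasso_cv")
}

#' Convert logistic coefficients to integer score points
#'
#' Maps each nonzero coefficient to sign(beta) * 20 when its magnitude
#' reaches `magnitude_cutoff` and sign(beta) * 10 otherwise; zeroed factors
#' are dropped. Note that the published PASS additionally applies
#' severity-conditional acuity and age points that are a clinical
#' refinement, not derivable from main-effect coefficients; those are
#' configured in [compute_pass()], not produced here.
#'
#' @param coefficients Named numeric vector of fitted coefficients.
#' @param magnitude_cutoff Magnitude at which a factor earns 20 points
#'   instead of 10 (default 2).
#' @return Named integer vector of points for the retained factors.
#' @examples
#' coefficients_to_points(c(severe = 2.5, red_flags = -3.9, acute = 1.5))
#' @export
coefficients_to_points <- function(coefficients, magnitude_cutoff = 2) {
  b <- coefficients[coefficients != 0]
  pts <- as.integer(sign(b) * ifelse(abs(b) >= magnitude_cutoff, 20L, 10L))
  names(pts) <- names(b)
  pts
}

#' Re-derive a PASS-like point map from a labeled cohort
#'
#' Runs the full derivation pipeline: builds the seven-factor indicator
#' matrix, selects the lasso penalty by stratified 10-fold cross-validated
#' minimum binomial deviance, refits the path, and converts the
#' coefficients at the selected penalty into integer points.
#'
#' @param cohort Labeled patient records.
#' @param seed Integer seed for the cross-validation folds.
#' @param k Number of folds.
#' @param magnitude_cutoff See [coefficients_to_points()].
#' @return List of class `pass_derivation`: `lambda_min`, `coefficients`,
#'   `intercept`, `point_map`, `cv` and `path` objects.
#' @export
derive_score_map <- function(cohort, seed, k = 10, magnitude_cutoff = 2) {
  cohort <- as.data.frame(cohort)
  x <- pass_features(cohort)
  x <- x[, apply(x, 2, function(z) length(unique(z)) > 1), drop = FALSE]
  y <- .as_binary(cohort$diagnosis)
  cv <- cv_select_lambda(x, y, k = k, seed = seed)
  path <- lasso_logistic_path(x, y, lambda = cv$lambda)
  j <- which.min(abs(path$lambda - cv$lambda_min))
  beta <- path$beta[, j]
  structure(list(lambda_min = cv$lambda_min, coefficients = beta,
                 intercept = path$intercept[j],
                 point_map = coefficients_to_points(beta, magnitude_cutoff),
                 cv = cv, path = path),
            class = "pass_derivation")
}

#' @export
print.pass_derivation <- function(x, ...) {
  cat(sprintf("Lasso-derived point map (lambda_min = %.4g)\n", x$lambda_min))
  print(data.frame(factor = names(x$coefficients),
                   beta = round(unname(x$coefficients), 3),
                   points = ifelse(names(x$coefficients) %in%
                                     names(x$point_map),
                                   x$point_map[names(x$coefficients)], 0L)),
        row.names = FALSE)
  invisible(x)
}
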