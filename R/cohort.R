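#' Specification of a synthetic bone marrow failure cohort
#'
#' Default class-conditional prevalences and missingness rates equal those
#' of the 212-adult training cohort in which PASS was developed (162 AA, 50
#' IBMFS): e.g. 79.6% of AA patients had severe cytopenias vs 8.0% of
#' IBMFS, 88.3% vs 16.0% presented acutely, and lymphocyte telomere length
#' below the 1st percentile was found in 2.6% of evaluable AA vs 56.4% of
#' evaluable IBMFS patients. Telomere testing was unavailable for 85/162 AA
#' and 11/50 IBMFS patients; somatic missingness follows the availability
#' of PNH flow cytometry, the most widely performed somatic screen (11/162
#' AA, 34/50 IBMFS untested). The seven factors are sampled independently
#' given the diagnosis (only marginal prevalences are published).
#'
#' @param n Cohort size.
#' @param aa_prevalence Probability that a patient has AA (default
#'   162/212).
#' @param prev_aa,prev_ibmfs Named numeric vectors of factor prevalences
#'   for the AA and IBMFS classes, names `severe`, `acute`, `age_ge60`,
#'   `red_flags`, `aa_condition`, `somatic`, `tl_short`.
#' @param miss_somatic,miss_tl Named numeric vectors (`AA`, `IBMFS`) of
#'   probabilities that the somatic / telomere factor is untested
#'   (`"unknown"`).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 212,
                        aa_prevalence = 162 / 212,
                        prev_aa = c(severe = 0.796, acute = 0.883,
                                    age_ge60 = 0.389, red_flags = 0.037,
                                    aa_condition = 0.062, somatic = 0.525,
                                    tl_short = 0.026),
                        prev_ibmfs = c(severe = 0.080, acute = 0.160,
                                       age_ge60 = 0.220, red_flags = 0.900,
                                       aa_condition = 0.000, somatic = 0.020,
                                       tl_short = 0.564),
                        miss_somatic = c(AA = 11 / 162, IBMFS = 34 / 50),
                        miss_tl = c(AA = 85 / 162, IBMFS = 11 / 50)) {
  want <- c("severe", "acute", "age_ge60", "red_flags", "aa_condition",
            "somatic", "tl_short")
  stopifnot(n >= 1, setequal(names(prev_aa), want),
            setequal(names(prev_ibmfs), want))
  probs <- c(aa_prevalence, prev_aa, prev_ibmfs, miss_somatic, miss_tl)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (aa_prevalence <= 0 || aa_prevalence >= 1)
    warning("degenerate aa_prevalence: single-class cohort")
  structure(list(n = as.integer(n), aa_prevalence = aa_prevalence,
                 prev_aa = prev_aa[want], prev_ibmfs = prev_ibmfs[want],
                 miss_somatic = miss_somatic, miss_tl = miss_tl),
            class = "cohort_spec")
}

#' Generate a labeled synthetic bone marrow failure cohort
#'
#' Samples the diagnosis first, then the seven PASS factors independently
#' given the diagnosis at the class-conditional prevalences of the spec,
#' and finally masks the somatic and telomere factors to `"unknown"` at the
#' per-class missingness rates. Ages are drawn uniformly inside the age
#' band implied by the age indicator (18-60 / 60-87) so the cohort also
#' carries a continuous age column. Deterministic for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Data frame of class `pass_cohort` with one row per patient and
#'   columns `patient_id`, `severity`, `acuity`, `age_years`, `age_ge60`,
#'   `red_flags`, `aa_condition`, `somatic`, `tl_lt_1st`, `diagnosis`,
#'   `cohort`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 100), seed = 1)
#' table(coh$diagnosis)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  n <- spec$n
  aa <- stats::runif(n) < spec$aa_prevalence
  p <- function(f) ifelse(aa, spec$prev_aa[[f]], spec$prev_ibmfs[[f]])
  draw <- function(f) stats::runif(n) < p(f)

  severe <- draw("severe")
  acute <- draw("acute")
  age60 <- draw("age_ge60")
  red_flags <- draw("red_flags")
  aa_condition <- draw("aa_condition")
  somatic <- ifelse(draw("somatic"), "present", "absent")
  tl <- ifelse(draw("tl_short"), "short", "not_short")

  m_som <- ifelse(aa, spec$miss_somatic[["AA"]], spec$miss_somatic[["IBMFS"]])
  m_tl <- ifelse(aa, spec$miss_tl[["AA"]], spec$miss_tl[["IBMFS"]])
  somatic[stats::runif(n) < m_som] <- "unknown"
  tl[stats::runif(n) < m_tl] <- "unknown"

  age_years <- round(ifelse(age60, stats::runif(n, 60, 87),
                            stats::runif(n, 18, 60)), 1)
  # keep the rounded age consistent with the sampled age band
  age_years <- ifelse(age60, pmax(age_years, 60), pmin(age_years, 59.9))

  out <- data.frame(
    patient_id = sprintf("S%05d", seq_len(n)),
    severity = ifelse(severe, "severe", "non_severe"),
    acuity = ifelse(acute, "acute", "chronic"),
    age_years = age_years,
    age_ge60 = age60,
    red_flags = red_flags,
    aa_condition = aa_condition,
    somatic = somatic,
    tl_lt_1st = tl,
    diagnosis = ifelse(aa, "AA", "IBMFS"),
    cohort = "synthetic",
    stringsAsFactors = FALSE
  )
  class(out) <- c("pass_cohort", "data.frame")
  out
}

# deterministic within-class assignment: the first k patients of the class
# carry the factor, so marginal counts are exact by construction
.assign_first <- function(class_n, k) c(rep(TRUE, k), rep(FALSE, class_n - k))

#' Deterministic pseudo-cohort matching the published training-cohort margins
#'
#' Builds a 212-patient cohort (162 AA, 50 IBMFS) whose per-factor marginal
#' counts equal those reported for the PASS training cohort: e.g. 63 AA and
#' 11 IBMFS patients aged >= 60, 129/4 with severe cytopenias, 143/8 acute,
#' 85/1 with an AA-associated somatic change, 10/0 with an AA-associated
#' condition, 6/45 with IBMFS red flags, and telomere categories 2 short /
#' 75 not short / 85 untested (AA) and 22 / 17 / 11 (IBMFS). Factors are
#' assigned independently within class in a fixed order (the first k
#' patients of each class carry each factor), so the marginals are exact
#' but the joint structure is synthetic: univariate statistics reproduce
#' the published table, whereas joint quantities (score distributions, AUC)
#' do not represent the real cohort.
#'
#' @return Data frame of class `pass_cohort`, 212 rows.
#' @export
training_margins_cohort <- function() {
  counts <- list(
    AA = list(n = 162, age_ge60 = 63, severe = 129, acute = 143,
              somatic = 85, aa_condition = 10, red_flags = 6,
              tl_short = 2, tl_not_short = 75),
    IBMFS = list(n = 50, age_ge60 = 11, severe = 4, acute = 8,
                 somatic = 1, aa_condition = 0, red_flags = 45,
                 tl_short = 22, tl_not_short = 17)
  )
  blocks <- lapply(names(counts), function(dx) {
    k <- counts[[dx]]
    tl <- c(rep("short", k$tl_short), rep("not_short", k$tl_not_short),
            rep("unknown", k$n - k$tl_short - k$tl_not_short))
    data.frame(
      patient_id = sprintf("%s%03d", ifelse(dx == "AA", "T", "U"),
                           seq_len(k$n)),
      severity = ifelse(.assign_first(k$n, k$severe), "severe", "non_severe"),
      acuity = ifelse(.assign_first(k$n, k$acute), "acute", "chronic"),
      age_ge60 = .assign_first(k$n, k$age_ge60),
      red_flags = .assign_first(k$n, k$red_flags),
      aa_condition = .assign_first(k$n, k$aa_condition),
      somatic = ifelse(.assign_first(k$n, k$somatic), "present", "absent"),
      tl_lt_1st = tl,
      diagnosis = dx,
      cohort = "training_margins",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  class(out) <- c("pass_cohort", "data.frame")
  out
}
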