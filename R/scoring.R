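#' Classify cytopenia severity by modified Camitta criteria
#'
#' A patient is classified as severe (SAA/VSAA) when two or more severe
#' cytopenias are present: absolute neutrophil count < 0.5 x 10^3/uL,
#' reticulocytopenic anemia with absolute reticulocyte count < 60 x 10^3/uL,
#' and platelets < 20 x 10^3/uL. One or fewer severe cytopenias is
#' non-severe (NSAA). SAA and VSAA carry identical PASS points, so a single
#' severe class is used.
#'
#' @param anc Absolute neutrophil count, 10^3 cells/uL.
#' @param arc Absolute reticulocyte count, 10^3 cells/uL.
#' @param platelets Platelet count, 10^3 cells/uL.
#' @param anemic Optional logical: hemoglobin below normal. When supplied,
#'   the reticulocyte criterion requires both anemia and `arc < 60`; when
#'   `NULL` or `NA` the criterion is `arc < 60` alone (many cohorts report
#'   ARC without an explicit anemia flag).
#' @param strict_anemia If `TRUE`, the reticulocyte criterion is never met
#'   without an explicit `anemic = TRUE` flag.
#' @return Character vector, `"severe"` or `"non_severe"`.
#' @examples
#' classify_severity(0.3, 40, 15)  # all three criteria -> severe
#' classify_severity(0.8, 70, 15)  # one criterion -> non_severe
#' @export
classify_severity <- function(anc, arc, platelets, anemic = NULL,
                              strict_anemia = FALSE) {
  n <- max(length(anc), length(arc), length(platelets))
  anc <- rep_len(as.numeric(anc), n)
  arc <- rep_len(as.numeric(arc), n)
  platelets <- rep_len(as.numeric(platelets), n)
  if (anyNA(anc) || anyNA(arc) || anyNA(platelets))
    stop("counts must be non-missing numerics")
  if (any(anc < 0) || any(arc < 0) || any(platelets < 0))
    stop("counts must be non-negative")
  if (is.null(anemic)) anemic <- rep(NA, n) else anemic <- rep_len(anemic, n)

  retic <- arc < 60
  # anemia flag gates the reticulocyte criterion when known
  retic <- ifelse(is.na(anemic), if (strict_anemia) FALSE else retic,
                  retic & anemic)
  k <- (anc < 0.5) + retic + (platelets < 20)
  ifelse(k >= 2, "severe", "non_severe")
}

#' Derive the AA-associated somatic-change status from individual markers
#'
#' The composite somatic factor is positive when any of the four
#' AA-associated somatic markers is positive: a PNH granulocyte clone
#' (>= 0.5% by default), acquired 6p copy-neutral loss of heterozygosity,
#' del(13)(q) as an isolated cytogenetic abnormality, or a somatic
#' *BCOR*/*BCORL1* mutation. It is `"absent"` when every tested marker is
#' negative and `"unknown"` when no marker was tested.
#'
#' @param pnh_clone_pct PNH granulocyte clone size in percent; `NA` = not
#'   tested.
#' @param sixp_loh Logical, acquired 6pLOH present; `NA` = not tested.
#' @param del13q_isolated Logical, isolated del(13)(q); `NA` = not tested.
#' @param bcor_bcorl1 Logical, somatic BCOR/BCORL1 mutation; `NA` = not
#'   tested.
#' @param sensitive_pnh If `TRUE`, any detectable PNH clone (> 0%) counts as
#'   positive instead of the conservative >= 0.5% threshold.
#' @return Character vector over `"present"`, `"absent"`, `"unknown"`.
#' @examples
#' somatic_from_markers(pnh_clone_pct = 6)            # "present"
#' somatic_from_markers(0.3, FALSE, FALSE, FALSE)     # "absent"
#' somatic_from_markers(0.3, sensitive_pnh = TRUE)    # "present"
#' @export
somatic_from_markers <- function(pnh_clone_pct = NA, sixp_loh = NA,
                                 del13q_isolated = NA, bcor_bcorl1 = NA,
                                 sensitive_pnh = FALSE) {
  n <- max(length(pnh_clone_pct), length(sixp_loh), length(del13q_isolated),
           length(bcor_bcorl1))
  pnh <- rep_len(as.numeric(pnh_clone_pct), n)
  if (any(pnh < 0, na.rm = TRUE)) stop("pnh_clone_pct must be non-negative")
  loh <- rep_len(as.logical(sixp_loh), n)
  d13 <- rep_len(as.logical(del13q_isolated), n)
  bcor <- rep_len(as.logical(bcor_bcorl1), n)

  pnh_pos <- if (sensitive_pnh) pnh > 0 else pnh >= 0.5
  markers <- cbind(pnh_pos, loh, d13, bcor)
  any_pos <- apply(markers, 1L, function(z) any(z %in% TRUE))
  any_tested <- apply(markers, 1L, function(z) any(!is.na(z)))
  ifelse(any_pos, "present", ifelse(any_tested, "absent", "unknown"))
}

#' Assign the diagnostic tier for a PASS total
#'
#' Scores of 30 and above are high-confidence AA, 0 to 20 is the
#' intermediate range, and negative scores indicate likely IBMFS. Because
#' attainable totals are multiples of 10 in -70..80, the three tiers
#' partition the score range.
#'
#' @param total Integer PASS total(s).
#' @return Factor with levels `IBMFS_likely`, `intermediate`,
#'   `AA_high_confidence`.
#' @examples
#' classify_tier(c(30, 10, -10))
#' @export
classify_tier <- function(total) {
  total <- as.numeric(total)
  out <- ifelse(total >= 30, "AA_high_confidence",
                ifelse(total >= 0, "intermediate", "IBMFS_likely"))
  factor(out, levels = c("IBMFS_likely", "intermediate", "AA_high_confidence"))
}

#' Build a one-patient PASS record
#'
#' Convenience constructor for the record data frame consumed by
#' [compute_pass()]. Factors 1-5 (severity, acuity, age, IBMFS red flags,
#' AA-associated conditions) are required at scoring time; the somatic and
#' telomere factors may be `"unknown"`.
#'
#' @param severity `"severe"` (SAA/VSAA) or `"non_severe"` (NSAA).
#' @param acuity `"acute"` (cytopenia duration <= 1 year) or `"chronic"`
#'   (> 1 year).
#' @param age_years Age in years (>= 18); age 60 and above earns the older-age
#'   points. Exactly one of `age_years`/`age_ge60` must be given.
#' @param age_ge60 Logical alternative to `age_years`.
#' @param red_flags Logical: any IBMFS red-flag condition present.
#' @param aa_condition Logical: any AA-associated condition present.
#' @param somatic `"present"`, `"absent"` or `"unknown"`: AA-associated
#'   somatic change (see [somatic_from_markers()]).
#' @param tl_lt_1st `"short"` (lymphocyte telomere length < 1st percentile),
#'   `"not_short"` (>= 1st percentile) or `"unknown"`.
#' @param patient_id Optional identifier.
#' @param diagnosis Optional ground-truth label, `"AA"` or `"IBMFS"`.
#' @return One-row data frame of class `pass_cohort`.
#' @examples
#' p <- pass_patient("non_severe", "acute", age_years = 45, red_flags = FALSE,
#'                   aa_condition = FALSE, somatic = "present")
#' compute_pass(p)
#' @export
pass_patient <- function(severity, acuity, age_years = NULL, age_ge60 = NULL,
                         red_flags, aa_condition, somatic = "unknown",
                         tl_lt_1st = "unknown", patient_id = "patient",
                         diagnosis = NA_character_) {
  if (is.null(age_years) == is.null(age_ge60))
    stop("supply exactly one of age_years or age_ge60")
  if (is.null(age_ge60)) age_ge60 <- age_years >= 60
  rec <- data.frame(
    patient_id = patient_id,
    severity = severity,
    acuity = acuity,
    age_ge60 = age_ge60,
    red_flags = red_flags,
    aa_condition = aa_condition,
    somatic = somatic,
    tl_lt_1st = tl_lt_1st,
    diagnosis = diagnosis,
    stringsAsFactors = FALSE
  )
  if (!is.null(age_years)) rec$age_years <- age_years
  class(rec) <- c("pass_cohort", "data.frame")
  rec
}

.chk_levels <- function(x, allowed, what) {
  bad <- !is.na(x) & !(x %in% allowed)
  if (any(bad))
    stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(allowed, collapse = "/")))
  x
}

#' Compute the PASS score for a cohort of records
#'
#' Adds the seven component contributions of the Predictive Aplastic Score
#' System: (1) severity, +20 for SAA/VSAA and 0 for NSAA; (2) acuity, +10
#' for acute presentation, -10 for chronic presentation with severe
#' cytopenias and -20 for chronic non-severe; (3) age, +10 at 60 years and
#' older, otherwise 0 if severe and -10 if non-severe; (4) IBMFS red flags,
#' -20 if present and +10 if absent; (5) AA-associated conditions, +10 if
#' present and 0 if absent; (6) AA-associated somatic change, +20 if present
#' and 0 if absent or unknown; (7) lymphocyte telomere length, -20 if below
#' the 1st percentile for age and 0 otherwise or if unknown. Factors 1-5 are
#' required; the somatic and telomere factors are optional and score 0 when
#' unknown or excluded.
#'
#' @param records Data frame with columns `severity`, `acuity`, `age_ge60`
#'   (or `age_years`), `red_flags`, `aa_condition`, and optionally
#'   `somatic`, `tl_lt_1st`, `patient_id`, `diagnosis`. See [pass_patient()].
#' @param include_somatic If `FALSE`, the somatic component is excluded
#'   (scored 0), emulating a setting where somatic testing is unavailable.
#' @param include_tl If `FALSE`, the telomere component is excluded.
#' @param missing `"strict"` (default) errors when a required factor is
#'   missing; `"lenient"` scores missing required factors as absence of
#'   abnormal findings (no severe cytopenias, acute onset, no red flags, no
#'   AA-associated condition) with a warning, the policy used when scoring
#'   retrospective cohorts with incomplete documentation. Age must always be
#'   present.
#' @return Data frame of class `pass_scores` with the seven component point
#'   columns, `total` and `tier`, one row per record.
#' @examples
#' p <- pass_patient("non_severe", "acute", age_years = 45, red_flags = FALSE,
#'                   aa_condition = FALSE, somatic = "present",
#'                   tl_lt_1st = "unknown")
#' compute_pass(p)$total                    # 30
#' p$tl_lt_1st <- "short"
#' compute_pass(p)$total                    # 10
#' @export
compute_pass <- function(records, include_somatic = TRUE, include_tl = TRUE,
                         missing = c("strict", "lenient")) {
  missing <- match.arg(missing)
  records <- as.data.frame(records)
  n <- nrow(records)
  if (n == 0L) stop("no records to score")

  need <- c("severity", "acuity", "red_flags", "aa_condition")
  if (!("age_ge60" %in% names(records))) {
    if (!("age_years" %in% names(records)))
      stop("records must contain age_ge60 or age_years")
    records$age_ge60 <- records$age_years >= 60
  }
  absent_cols <- setdiff(need, names(records))
  if (length(absent_cols) > 0)
    stop("missing required column(s): ", paste(absent_cols, collapse = ", "))
  if (!("somatic" %in% names(records))) records$somatic <- "unknown"
  if (!("tl_lt_1st" %in% names(records))) records$tl_lt_1st <- "unknown"

  sev <- .chk_levels(as.character(records$severity),
                     c("severe", "non_severe"), "severity")
  acu <- .chk_levels(as.character(records$acuity),
                     c("acute", "chronic"), "acuity")
  age60 <- as.logical(records$age_ge60)
  rf <- as.logical(records$red_flags)
  aac <- as.logical(records$aa_condition)
  som <- .chk_levels(as.character(records$somatic),
                     c("present", "absent", "unknown"), "somatic")
  som[is.na(som)] <- "unknown"
  tl <- .chk_levels(as.character(records$tl_lt_1st),
                    c("short", "not_short", "unknown"), "tl_lt_1st")
  tl[is.na(tl)] <- "unknown"

  miss_req <- is.na(sev) | is.na(acu) | is.na(rf) | is.na(aac)
  if (any(is.na(age60)))
    stop("age is required for every record (rows: ",
         paste(which(is.na(age60)), collapse = ", "), ")")
  if (any(miss_req)) {
    if (missing == "strict")
      stop("required factors missing in rows: ",
           paste(which(miss_req), collapse = ", "),
           " (use missing = \"lenient\" to score them as absence of",
           " abnormal findings)")
    warning(sum(miss_req), " record(s) with missing required factors scored",
            " as absence of abnormal findings")
    sev[is.na(sev)] <- "non_severe"
    acu[is.na(acu)] <- "acute"
    rf[is.na(rf)] <- FALSE
    aac[is.na(aac)] <- FALSE
  }

  severe <- sev == "severe"
  severity_pts <- ifelse(severe, 20L, 0L)
  acuity_pts <- ifelse(acu == "acute", 10L, ifelse(severe, -10L, -20L))
  age_pts <- ifelse(age60, 10L, ifelse(severe, 0L, -10L))
  red_flag_pts <- ifelse(rf, -20L, 10L)
  aa_condition_pts <- ifelse(aac, 10L, 0L)
  somatic_pts <- if (include_somatic) ifelse(som == "present", 20L, 0L)
                 else rep(0L, n)
  tl_pts <- if (include_tl) ifelse(tl == "short", -20L, 0L) else rep(0L, n)

  total <- severity_pts + acuity_pts + age_pts + red_flag_pts +
    aa_condition_pts + somatic_pts + tl_pts
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(records))
      as.character(records$patient_id) else sprintf("P%04d", seq_len(n)),
    severity_pts = severity_pts, acuity_pts = acuity_pts, age_pts = age_pts,
    red_flag_pts = red_flag_pts, aa_condition_pts = aa_condition_pts,
    somatic_pts = somatic_pts, tl_pts = tl_pts,
    total = as.integer(total), tier = classify_tier(total),
    stringsAsFactors = FALSE
  )
  if ("diagnosis" %in% names(records))
    out$diagnosis <- as.character(records$diagnosis)
  class(out) <- c("pass_scores", "data.frame")
  out
}

#' @export
print.pass_scores <- function(x, ...) {
  cat("PASS scores for", nrow(x), "patient(s)\n")
  cat("Tiers:", paste(sprintf("%s=%d", levels(x$tier), table(x$tier)),
                      collapse = ", "), "\n")
  NextMethod()
}

#' Tier interpretation text
#'
#' Short management-oriented interpretation for each diagnostic tier, used
#' by the interactive calculator.
#'
#' @param tier A tier value as returned by [classify_tier()].
#' @return Character vector of interpretation strings.
#' @export
tier_interpretation <- function(tier) {
  txt <- c(
    AA_high_confidence = paste(
      "High-confidence acquired aplastic anemia (PASS >= 30):",
      "AA-directed therapy can proceed without delay; recalculate the score",
      "if new findings emerge."),
    intermediate = paste(
      "Intermediate (PASS 0-20): AA is likely but not certain; individualize",
      "management and consider further IBMFS testing, particularly before",
      "transplant."),
    IBMFS_likely = paste(
      "Likely IBMFS (PASS < 0): comprehensive IBMFS evaluation including",
      "genetic testing is recommended before AA-directed therapy.")
  )
  unname(txt[as.character(tier)])
}
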