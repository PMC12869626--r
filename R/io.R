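.cohort_schema <- c(
  "patient_id", "severity", "anc", "arc", "platelets", "anemic",
  "acuity", "duration_years", "age_years", "age_ge60",
  "red_flags", "aa_condition",
  "somatic", "pnh_clone_pct", "sixp_loh", "del13q_isolated", "bcor_bcorl1",
  "tl_lt_1st", "diagnosis", "cohort"
)

.parse_bool <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a patient cohort from CSV
#'
#' Reads and validates a cohort file (comma-separated, UTF-8, header
#' required; booleans as `true`/`false`; tri-states as
#' `present`/`absent`/`unknown`, telomere category as
#' `short`/`not_short`/`unknown`). Severity may be given directly or
#' derived from raw counts (`anc`, `arc`, `platelets`, optional `anemic`);
#' acuity may be given directly or derived from `duration_years` with the
#' <= 1 year rule (an explicit `acuity` column wins, with a warning when
#' both are present and inconsistent). The composite somatic status may be
#' given directly or derived from the marker columns via
#' [somatic_from_markers()]. Rows that cannot be validated are dropped,
#' reported in the `rejects` attribute with their line numbers and
#' reasons, and summarized in a warning.
#'
#' @param path Path to the CSV file.
#' @param sensitive_pnh Clone-threshold policy passed to
#'   [somatic_from_markers()] when deriving somatic status from markers.
#' @return Data frame of class `pass_cohort`; attribute `rejects` is a
#'   data frame with `line` and `reason` columns (zero rows when all rows
#'   parse).
#' @export
read_cohort_csv <- function(path, sensitive_pnh = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  unknown <- setdiff(names(raw), .cohort_schema)
  if (length(unknown) > 0)
    stop("unknown column(s): ", paste(unknown, collapse = ", "))

  n <- nrow(raw)
  has <- function(col) col %in% names(raw)
  get_num <- function(col) if (has(col))
    suppressWarnings(as.numeric(raw[[col]])) else rep(NA_real_, n)
  get_chr <- function(col) if (has(col)) {
    z <- trimws(raw[[col]]); z[z == ""] <- NA; z
  } else rep(NA_character_, n)
  get_bool <- function(col) if (has(col)) .parse_bool(raw[[col]])
    else rep(NA, n)

  reasons <- vector("list", n)
  flag <- function(i, msg) reasons[[i]] <<- c(reasons[[i]], msg)

  severity <- get_chr("severity")
  anc <- get_num("anc"); arc <- get_num("arc"); plt <- get_num("platelets")
  anemic <- get_bool("anemic")
  counts_ok <- !is.na(anc) & !is.na(arc) & !is.na(plt) &
    anc >= 0 & arc >= 0 & plt >= 0
  derived_sev <- rep(NA_character_, n)
  derived_sev[counts_ok] <- classify_severity(anc[counts_ok], arc[counts_ok],
                                              plt[counts_ok],
                                              anemic[counts_ok])
  severity[is.na(severity)] <- derived_sev[is.na(severity)]
  for (i in which(!is.na(severity) & !(severity %in% c("severe", "non_severe"))))
    flag(i, paste0("invalid severity '", severity[i], "'"))
  for (i in which(is.na(severity))) flag(i, "severity missing (no counts)")

  acuity <- get_chr("acuity")
  dur <- get_num("duration_years")
  derived_acu <- ifelse(is.na(dur), NA_character_,
                        ifelse(dur <= 1, "acute", "chronic"))
  both <- !is.na(acuity) & !is.na(derived_acu) & acuity != derived_acu
  if (any(both))
    warning("acuity column inconsistent with duration_years in ",
            sum(both), " row(s); explicit acuity used")
  acuity[is.na(acuity)] <- derived_acu[is.na(acuity)]
  for (i in which(!is.na(acuity) & !(acuity %in% c("acute", "chronic"))))
    flag(i, paste0("invalid acuity '", acuity[i], "'"))
  for (i in which(is.na(acuity))) flag(i, "acuity missing")

  age_years <- get_num("age_years")
  age_ge60 <- get_bool("age_ge60")
  age_ge60[is.na(age_ge60)] <- (age_years >= 60)[is.na(age_ge60)]
  for (i in which(is.na(age_ge60))) flag(i, "age missing")

  red_flags <- get_bool("red_flags")
  for (i in which(is.na(red_flags))) flag(i, "red_flags missing")
  aa_condition <- get_bool("aa_condition")
  for (i in which(is.na(aa_condition))) flag(i, "aa_condition missing")

  somatic <- get_chr("somatic")
  pnh <- get_num("pnh_clone_pct")
  if (any(pnh < 0, na.rm = TRUE)) stop("negative pnh_clone_pct")
  marker_cols <- has("pnh_clone_pct") || has("sixp_loh") ||
    has("del13q_isolated") || has("bcor_bcorl1")
  if (marker_cols) {
    derived_som <- somatic_from_markers(pnh, get_bool("sixp_loh"),
                                        get_bool("del13q_isolated"),
                                        get_bool("bcor_bcorl1"),
                                        sensitive_pnh = sensitive_pnh)
    somatic[is.na(somatic)] <- derived_som[is.na(somatic)]
  }
  somatic[is.na(somatic)] <- "unknown"
  for (i in which(!(somatic %in% c("present", "absent", "unknown"))))
    flag(i, paste0("invalid somatic '", somatic[i], "'"))

  tl <- get_chr("tl_lt_1st")
  tl[is.na(tl)] <- "unknown"
  for (i in which(!(tl %in% c("short", "not_short", "unknown"))))
    flag(i, paste0("invalid tl_lt_1st '", tl[i], "'"))

  diagnosis <- get_chr("diagnosis")
  for (i in which(!is.na(diagnosis) & !(diagnosis %in% c("AA", "IBMFS"))))
    flag(i, paste0("invalid diagnosis '", diagnosis[i], "'"))

  out <- data.frame(
    patient_id = if (has("patient_id")) raw$patient_id
      else sprintf("P%04d", seq_len(n)),
    severity = severity, acuity = acuity,
    age_years = age_years, age_ge60 = age_ge60,
    red_flags = red_flags, aa_condition = aa_condition,
    somatic = somatic, tl_lt_1st = tl,
    diagnosis = diagnosis,
    cohort = if (has("cohort")) raw$cohort else NA_character_,
    stringsAsFactors = FALSE
  )
  if (!has("age_years")) out$age_years <- NULL
  if (anyDuplicated(out$patient_id))
    stop("duplicate patient_id values")

  bad <- which(vapply(reasons, length, integer(1)) > 0)
  rejects <- data.frame(
    line = bad + 1L,  # +1 for the header line
    reason = vapply(reasons[bad], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE
  )
  if (length(bad) > 0) {
    warning(length(bad), " row(s) rejected; see attr(, 'rejects')")
    out <- out[-bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("pass_cohort", "data.frame")
  attr(out, "rejects") <- rejects
  attr(out, "source") <- normalizePath(path)
  out
}

#' Write a cohort (or scored cohort) to CSV
#'
#' Writes the data frame with the package's CSV dialect (booleans as
#' `true`/`false`), so that [read_cohort_csv()] round-trips the records.
#'
#' @param x Cohort or score data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(x, path) {
  x <- as.data.frame(x)
  for (col in names(x))
    if (is.logical(x[[col]]))
      x[[col]] <- ifelse(is.na(x[[col]]), "", tolower(as.character(x[[col]])))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
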