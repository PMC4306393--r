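# Cohort records: CSV schema, validation, and the study's exclusion filters.

.cohort_numeric_cols <- c(
  "age_years", "sbp_mmhg", "dbp_mmhg", "pulse_bpm", "sodium_mmol_l",
  "potassium_mmol_l", "glucose_mmol_l", "hb_g_l", "wbc_1e9_l",
  "platelets_1e9_l", "onset_to_ct_h", "icv_cm3", "total_vol_cm3",
  "parenchymal_vol_cm3", "ivh_vol_cm3", "fu_total_vol_cm3", "fu_icv_cm3")

.cohort_bool_cols <- c("smoker", "alcohol_excess", "ivh_present",
                       "fu_ivh_present", "death30")

.cohort_schema <- c("patient_id", "age_years", "sex", "smoker",
                    "alcohol_excess", "sbp_mmhg", "dbp_mmhg", "pulse_bpm",
                    "sodium_mmol_l", "potassium_mmol_l", "glucose_mmol_l",
                    "hb_g_l", "wbc_1e9_l", "platelets_1e9_l", "onset_to_ct_h",
                    "icv_cm3", "total_vol_cm3", "parenchymal_vol_cm3",
                    "ivh_vol_cm3", "ivh_present", "fu_total_vol_cm3",
                    "fu_icv_cm3", "fu_ivh_present", "death30",
                    "exclusion_codes")

#' Exclusion reason codes
#'
#' The closed set of reasons a record may be excluded from analysis:
#' alternative diagnoses (traumatic ICH, subarachnoid haemorrhage, vascular
#' malformation, tumour, haemorrhagic transformation of ischaemic stroke,
#' post-thrombolytic haemorrhage), locations outside scope (infratentorial,
#' primary intraventricular), surgical evacuation, arrival beyond 24 h,
#' missing follow-up CT, a brain unsuitable for post-mortem volumetry
#' (fragmented or multilobar haematoma, damage on removal), and insufficient
#' medical records.
#'
#' @return Character vector of valid codes.
#' @export
exclusion_codes <- function() {
  c("traumatic", "sah", "vascular_malformation", "tumour",
    "haemorrhagic_transformation", "postthrombolytic", "infratentorial",
    "primary_ivh", "surgical", "late_arrival", "no_second_ct",
    "brain_unsuitable", "records_insufficient")
}

#' Cohort CSV schema
#'
#' Column names, in order, of the cohort interchange format: one row per
#' admission, comma-separated, UTF-8, dot decimal separator, booleans coded
#' 0/1, missing values as empty cells, and `exclusion_codes` a
#' semicolon-separated list drawn from [exclusion_codes()].
#'
#' @return Character vector of the 25 column names.
#' @export
cohort_schema <- function() .cohort_schema

#' Read a patient cohort from CSV
#'
#' Parses and validates a cohort file against [cohort_schema()]. Missing
#' cells become `NA` (never silent zeros); numeric columns must parse under
#' the dot-decimal dialect and booleans must be 0/1. Validation enforces the
#' record invariants: age >= 18, strictly positive potassium, glucose and
#' systolic blood pressure where present, exclusion codes drawn from the
#' closed set, and `death30` present on every non-excluded record.
#'
#' @param path CSV file path.
#' @param validate run invariant checks (default `TRUE`).
#' @return A data.frame (one row per patient) with typed columns; the
#'   `exclusion_codes` column is a character vector of semicolon-separated
#'   codes (`""` = none).
#' @export
read_cohort <- function(path, validate = TRUE) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  extra <- setdiff(names(raw), .cohort_schema)
  missing <- setdiff(.cohort_schema, names(raw))
  if (length(missing))
    .stopf("schema error: missing column(s) %s", paste(missing, collapse = ", "))
  if (length(extra))
    .stopf("schema error: unknown column(s) %s", paste(extra, collapse = ", "))
  out <- raw[, .cohort_schema]
  blank <- function(v) is.na(v) | !nzchar(trimws(v))
  for (col in .cohort_numeric_cols) {
    v <- trimws(out[[col]])
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!blank(v) & is.na(num))
    if (length(bad))
      .stopf("parse error in column '%s', row %d: cannot read \"%s\" as a number (dot-decimal dialect)",
             col, bad[1], v[bad[1]])
    num[blank(v)] <- NA_real_
    out[[col]] <- num
  }
  for (col in .cohort_bool_cols) {
    v <- trimws(out[[col]])
    bad <- which(!blank(v) & !v %in% c("0", "1"))
    if (length(bad))
      .stopf("parse error in column '%s', row %d: booleans must be 0 or 1, got \"%s\"",
             col, bad[1], v[bad[1]])
    out[[col]] <- ifelse(blank(v), NA_integer_, as.integer(v))
  }
  out$exclusion_codes <- trimws(out$exclusion_codes)
  out$exclusion_codes[blank(out$exclusion_codes)] <- ""
  if (validate) validate_cohort(out)
  out
}

#' @rdname read_cohort
#' @param records cohort data frame in the schema of [cohort_schema()].
#' @export
write_cohort <- function(records, path) {
  miss <- setdiff(.cohort_schema, names(records))
  if (length(miss)) .stopf("records are missing column(s): %s", paste(miss, collapse = ", "))
  utils::write.csv(records[, .cohort_schema], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate cohort invariants
#'
#' @param records cohort data frame.
#' @return `records`, invisibly; errors on the first violated invariant.
#' @export
validate_cohort <- function(records) {
  chk <- function(bad, msg) {
    i <- which(bad)
    if (length(i)) .stopf("invariant violation (row %d): %s", i[1], msg)
  }
  chk(!is.na(records$age_years) & records$age_years < 18, "age must be >= 18 years")
  for (col in c("potassium_mmol_l", "glucose_mmol_l", "sbp_mmhg"))
    chk(!is.na(records[[col]]) & records[[col]] <= 0,
        sprintf("%s must be strictly positive when present", col))
  chk(!records$sex %in% c("male", "female", NA_character_, ""),
      "sex must be 'male' or 'female'")
  codes <- .parse_codes(records$exclusion_codes)
  bad_codes <- vapply(codes, function(cc) any(!cc %in% exclusion_codes()), logical(1))
  chk(bad_codes, sprintf("unknown exclusion code (valid: %s)",
                         paste(exclusion_codes(), collapse = ", ")))
  not_excluded <- lengths(codes) == 0
  chk(not_excluded & is.na(records$death30),
      "death30 must be recorded for every non-excluded record")
  invisible(records)
}

.parse_codes <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(cc) trimws(cc[nzchar(trimws(cc))]))
}

#' Exclusion policy
#'
#' Which exclusion codes are active, and whether survivors without a
#' follow-up CT are excluded (they lack the second volumetry needed for the
#' growth analysis; nonsurvivors get theirs at autopsy).
#'
#' @param active character vector of active codes (default: all of
#'   [exclusion_codes()]).
#' @param require_second_ct exclude survivors with no follow-up total volume
#'   (derived code `no_second_ct`); default `TRUE`.
#' @return A list of class `exclusion_policy`.
#' @export
exclusion_policy <- function(active = exclusion_codes(),
                             require_second_ct = TRUE) {
  bad <- setdiff(active, exclusion_codes())
  if (length(bad)) .stopf("unknown exclusion code(s): %s", paste(bad, collapse = ", "))
  structure(list(active = active, require_second_ct = require_second_ct),
            class = "exclusion_policy")
}

#' Apply the exclusion filters
#'
#' Removes records whose exclusion flags are active under the policy, plus
#' (optionally) survivors lacking a second CT, and returns both the kept
#' records and a per-removal audit listing every applicable reason. The
#' filter partitions its input (every record is either kept or audited) and
#' is idempotent.
#'
#' @param records cohort data frame.
#' @param policy an [exclusion_policy()].
#' @return A list with `kept` (data.frame) and `audit` (data.frame with
#'   columns `patient_id`, `code`, `source` — `"flag"` for supplied codes,
#'   `"derived"` for the second-CT rule).
#' @export
apply_exclusions <- function(records, policy = exclusion_policy()) {
  stopifnot(inherits(policy, "exclusion_policy"))
  codes <- .parse_codes(records$exclusion_codes)
  audit <- data.frame(patient_id = character(), code = character(),
                      source = character(), stringsAsFactors = FALSE)
  drop <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    hit <- intersect(codes[[i]], policy$active)
    src <- rep("flag", length(hit))
    if (policy$require_second_ct &&
        isTRUE(records$death30[i] == 0) && is.na(records$fu_total_vol_cm3[i]) &&
        !"no_second_ct" %in% hit) {
      hit <- c(hit, "no_second_ct")
      src <- c(src, "derived")
    }
    if (length(hit)) {
      drop[i] <- TRUE
      audit <- rbind(audit, data.frame(patient_id = records$patient_id[i],
                                       code = hit, source = src,
                                       stringsAsFactors = FALSE))
    }
  }
  list(kept = records[!drop, , drop = FALSE], audit = audit)
}
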