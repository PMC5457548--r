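#' @importFrom rlang abort warn .data
#' @importFrom stats rbinom rpois rgamma rnorm runif rgeom setNames sd
#' @importFrom utils read.csv write.csv
NULL

# Enumerations used throughout the claims data model. Agent classes are
# two-level: `agent_code` identifies a specific product (used for "same agent"
# rules), `agent_class` the analysis grouping.

#' Agent classes counted as antipsychotics
#'
#' The long-acting injectable index agent (`pp1m`), the nine oral atypical
#' agents identified by generic name, plus typical oral, typical long-acting
#' injectable and other atypical long-acting injectable groupings.
#'
#' @return Character vector of antipsychotic agent classes.
#' @export
ap_classes <- function() {
  c("pp1m", oaa_classes(), "typical_oral_ap", "typical_lai", "other_atypical_lai")
}

#' Oral atypical antipsychotic agent classes
#' @return Character vector of the nine oral atypical agent classes.
#' @export
oaa_classes <- function() {
  c("aripiprazole", "asenapine", "iloperidone", "lurasidone", "olanzapine",
    "paliperidone", "quetiapine", "risperidone", "ziprasidone")
}

#' Supporting psychiatric medication classes
#' @return Classes that pair with an antipsychotic for psychiatric polypharmacy.
#' @export
psych_support_classes <- function() {
  c("anxiolytic", "antidepressant", "mood_stabilizer")
}

agent_class_levels <- function() {
  c(ap_classes(), psych_support_classes(), "other")
}

service_category_levels <- function() {
  c("inpatient", "outpatient", "emergency_room", "long_term_care",
    "mhi_admission", "mhi_1day", "home_care", "other")
}

sex_levels <- function() c("female", "male")
region_levels <- function() c("urban", "suburban", "rural")

#' Default agent-code to agent-class map
#'
#' An editable configuration table standing in for product-level drug
#' dictionaries: one row per agent code with its analysis class and a branded
#' flag (used by the brand-discount sensitivity scenario).
#'
#' @param path Optional path to a CSV with columns `agent_code`, `agent_class`,
#'   `branded`; defaults to the table shipped with the package.
#' @return A tibble with columns `agent_code`, `agent_class`, `branded`.
#' @export
default_agent_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "agent_map.csv", package = "claimsce")
  }
  map <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  bad <- setdiff(map$agent_class, agent_class_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown agent_class in map: ", paste(bad, collapse = ", ")),
          class = "claimsce_value_error")
  }
  map$branded <- as.logical(map$branded)
  map
}

parse_date_col <- function(x, file, col) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(d))
  if (length(bad) > 0) {
    abort(sprintf("%s: column '%s' has unparseable date at row %d", file, col, bad[1]),
          class = "claimsce_value_error")
  }
  d
}

check_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s): %s", file, paste(missing, collapse = ", ")),
          class = "claimsce_schema_error")
  }
}

check_enum <- function(x, levels, file, col) {
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad) > 0) {
    abort(sprintf("%s: column '%s' has value '%s' outside its enumeration at row %d",
                  file, col, x[bad[1]], bad[1]),
          class = "claimsce_value_error")
  }
  x
}

#' Construct and validate a claims bundle
#'
#' A claims bundle holds the four tables every pipeline stage consumes:
#' patients, enrollment spans, pharmacy claims and medical claims. Validation
#' checks the column schema, enumerations, per-table invariants (positive days
#' supply, non-negative paid amounts, ordered and non-overlapping enrollment
#' spans) and referential integrity. In strict mode a claim dated outside all
#' of its patient's enrollment spans is an error; in non-strict mode it is
#' tolerated with a warning (useful for generating deliberately excluded
#' patients).
#'
#' @param patients,enrollment,pharmacy,medical Data frames conforming to the
#'   documented schema.
#' @param strict Logical; enforce claims-within-enrollment (default `TRUE`).
#' @return An object of class `claims_bundle` (a named list of tibbles plus the
#'   strict flag).
#' @export
claims_bundle <- function(patients, enrollment, pharmacy, medical, strict = TRUE) {
  patients <- tibble::as_tibble(patients)
  enrollment <- tibble::as_tibble(enrollment)
  pharmacy <- tibble::as_tibble(pharmacy)
  medical <- tibble::as_tibble(medical)

  check_columns(patients, c("patient_id", "birth_date", "sex", "race", "region", "state"),
                "patients")
  check_columns(enrollment, c("patient_id", "start_date", "end_date", "capitated",
                              "dual_coverage"), "enrollment")
  check_columns(pharmacy, c("patient_id", "dispense_date", "agent_code", "agent_class",
                            "days_supply", "paid_amount", "branded", "service_year"),
                "pharmacy")
  check_columns(medical, c("patient_id", "start_date", "end_date", "service_category",
                           "dx_codes", "paid_amount", "agent_code", "branded",
                           "service_year"), "medical")

  patients$patient_id <- as.character(patients$patient_id)
  patients$birth_date <- parse_date_col(patients$birth_date, "patients", "birth_date")
  check_enum(patients$sex, sex_levels(), "patients", "sex")
  check_enum(patients$region, region_levels(), "patients", "region")
  if (anyDuplicated(patients$patient_id)) {
    abort("patients: duplicated patient_id", class = "claimsce_integrity_error")
  }

  enrollment$patient_id <- as.character(enrollment$patient_id)
  enrollment$start_date <- parse_date_col(enrollment$start_date, "enrollment", "start_date")
  enrollment$end_date <- parse_date_col(enrollment$end_date, "enrollment", "end_date")
  enrollment$capitated <- as.logical(enrollment$capitated)
  enrollment$dual_coverage <- as.logical(enrollment$dual_coverage)
  bad <- which(enrollment$start_date > enrollment$end_date)
  if (length(bad) > 0) {
    abort(sprintf("enrollment: start_date after end_date at row %d", bad[1]),
          class = "claimsce_value_error")
  }
  if (nrow(enrollment) > 1) {
    e <- enrollment[order(enrollment$patient_id, enrollment$start_date), ]
    same <- e$patient_id[-1] == e$patient_id[-nrow(e)]
    overl <- same & (e$start_date[-1] <= e$end_date[-nrow(e)])
    if (any(overl)) {
      abort(sprintf("enrollment: overlapping spans for patient %s",
                    e$patient_id[-1][which(overl)[1]]),
            class = "claimsce_value_error")
    }
  }

  pharmacy$patient_id <- as.character(pharmacy$patient_id)
  pharmacy$dispense_date <- parse_date_col(pharmacy$dispense_date, "pharmacy", "dispense_date")
  pharmacy$agent_code <- as.character(pharmacy$agent_code)
  pharmacy$days_supply <- as.integer(pharmacy$days_supply)
  pharmacy$paid_amount <- as.numeric(pharmacy$paid_amount)
  pharmacy$branded <- as.logical(pharmacy$branded)
  pharmacy$service_year <- as.integer(pharmacy$service_year)
  check_enum(pharmacy$agent_class, agent_class_levels(), "pharmacy", "agent_class")
  bad <- which(is.na(pharmacy$days_supply) | pharmacy$days_supply < 1L)
  if (length(bad) > 0) {
    abort(sprintf("pharmacy: days_supply < 1 at row %d", bad[1]),
          class = "claimsce_value_error")
  }
  bad <- which(pharmacy$paid_amount < 0)
  if (length(bad) > 0) {
    abort(sprintf("pharmacy: negative paid_amount at row %d", bad[1]),
          class = "claimsce_value_error")
  }

  medical$patient_id <- as.character(medical$patient_id)
  medical$start_date <- parse_date_col(medical$start_date, "medical", "start_date")
  medical$end_date <- parse_date_col(medical$end_date, "medical", "end_date")
  medical$dx_codes <- as.character(medical$dx_codes)
  medical$paid_amount <- as.numeric(medical$paid_amount)
  medical$agent_code <- as.character(medical$agent_code)
  medical$branded <- as.logical(medical$branded)
  medical$service_year <- as.integer(medical$service_year)
  check_enum(medical$service_category, service_category_levels(), "medical",
             "service_category")
  bad <- which(medical$start_date > medical$end_date)
  if (length(bad) > 0) {
    abort(sprintf("medical: start_date after end_date at row %d", bad[1]),
          class = "claimsce_value_error")
  }
  bad <- which(medical$service_category == "mhi_1day" &
                 medical$start_date != medical$end_date)
  if (length(bad) > 0) {
    abort(sprintf("medical: mhi_1day claim spanning more than one day at row %d", bad[1]),
          class = "claimsce_value_error")
  }
  bad <- which(medical$paid_amount < 0)
  if (length(bad) > 0) {
    abort(sprintf("medical: negative paid_amount at row %d", bad[1]),
          class = "claimsce_value_error")
  }

  ids <- patients$patient_id
  for (nm in c("enrollment", "pharmacy", "medical")) {
    tab <- get(nm)
    unknown <- setdiff(unique(tab$patient_id), ids)
    if (length(unknown) > 0) {
      abort(sprintf("%s: patient_id %s not present in patients table", nm, unknown[1]),
            class = "claimsce_integrity_error")
    }
  }

  # birth date precedes all claim dates
  first_claim <- c(
    split(pharmacy$dispense_date, pharmacy$patient_id),
    split(medical$start_date, medical$patient_id)
  )
  if (length(first_claim) > 0) {
    mins <- vapply(split(unlist(first_claim, use.names = FALSE),
                         rep(names(first_claim), lengths(first_claim))),
                   min, numeric(1))
    bd <- setNames(as.numeric(patients$birth_date), patients$patient_id)
    off <- names(mins)[bd[names(mins)] >= mins]
    if (length(off) > 0) {
      abort(sprintf("patient %s has a claim on or before birth_date", off[1]),
            class = "claimsce_integrity_error")
    }
  }

  # claims inside enrollment
  claim_dates <- rbind(
    data.frame(patient_id = pharmacy$patient_id, date = pharmacy$dispense_date),
    data.frame(patient_id = medical$patient_id, date = medical$start_date)
  )
  if (nrow(claim_dates) > 0 && nrow(enrollment) >= 0) {
    covered <- covered_by_enrollment(claim_dates$patient_id, claim_dates$date, enrollment)
    if (!all(covered)) {
      msg <- sprintf("%d claim(s) dated outside enrollment (first: patient %s)",
                     sum(!covered), claim_dates$patient_id[which(!covered)[1]])
      if (strict) abort(msg, class = "claimsce_integrity_error") else warn(msg)
    }
  }

  structure(list(patients = patients, enrollment = enrollment,
                 pharmacy = pharmacy, medical = medical, strict = strict),
            class = "claims_bundle")
}

# TRUE where date falls inside some enrollment span of that patient
covered_by_enrollment <- function(patient_id, date, enrollment) {
  spans <- split(enrollment[c("start_date", "end_date")], enrollment$patient_id)
  mapply(function(pid, d) {
    s <- spans[[pid]]
    !is.null(s) && any(s$start_date <= d & d <= s$end_date)
  }, patient_id, as.list(date), USE.NAMES = FALSE)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle> ", nrow(x$patients), " patients, ",
      nrow(x$enrollment), " enrollment spans, ",
      nrow(x$pharmacy), " pharmacy claims, ",
      nrow(x$medical), " medical claims",
      if (!x$strict) " (non-strict)", "\n", sep = "")
  invisible(x)
}

bundle_files <- function(dir) {
  stats::setNames(file.path(dir, c("patients.csv", "enrollment.csv",
                                   "pharmacy.csv", "medical.csv")),
                  c("patients", "enrollment", "pharmacy", "medical"))
}

#' Read a claims bundle from delimited text files
#'
#' Reads `patients.csv`, `enrollment.csv`, `pharmacy.csv` and `medical.csv`
#' from a directory (UTF-8, comma-separated, header row; dates ISO-8601;
#' `dx_codes` a semicolon-separated list) and validates the result.
#'
#' @param dir Directory containing the four files.
#' @param strict Enforce claims-within-enrollment (default `TRUE`).
#' @return A validated [claims_bundle()].
#' @export
read_bundle <- function(dir, strict = TRUE) {
  paths <- bundle_files(dir)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("missing bundle file(s): ", paste(missing, collapse = ", ")),
          class = "claimsce_schema_error")
  }
  tabs <- lapply(paths, function(p) {
    # read everything as character; claims_bundle() performs typed coercion
    # (protects code-like fields such as dx_codes from numeric conversion)
    read.csv(p, stringsAsFactors = FALSE, colClasses = "character")
  })
  names(tabs) <- names(paths)
  claims_bundle(tabs$patients, tabs$enrollment, tabs$pharmacy, tabs$medical,
                strict = strict)
}

#' Write a claims bundle to delimited text files
#'
#' Inverse of [read_bundle()]: writing then reading reproduces the bundle
#' exactly on every field of every table.
#'
#' @param bundle A `claims_bundle`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the four file paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- bundle_files(dir)
  fmt <- function(df) {
    for (col in names(df)) if (inherits(df[[col]], "Date")) {
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    df
  }
  write.csv(fmt(bundle$patients), paths[["patients"]], row.names = FALSE)
  write.csv(fmt(bundle$enrollment), paths[["enrollment"]], row.names = FALSE)
  write.csv(fmt(bundle$pharmacy), paths[["pharmacy"]], row.names = FALSE)
  write.csv(fmt(bundle$medical), paths[["medical"]], row.names = FALSE)
  invisible(paths)
}

#' Match ICD-9-CM codes against a prefix pattern
#'
#' Dot-insensitive prefix matching: `"295.30"` and `"29530"` both match the
#' pattern `"295.xx"`. Trailing `x` characters in the pattern are wildcards.
#'
#' @param code Character vector of ICD-9-CM codes.
#' @param pattern A prefix pattern such as `"295.xx"` or `"070.7x"`.
#' @return Logical vector, `TRUE` where the code matches.
#' @export
match_dx <- function(code, pattern) {
  stopifnot(length(pattern) == 1, nzchar(pattern))
  strip <- function(x) gsub("[xX]+$", "", gsub(".", "", x, fixed = TRUE))
  startsWith(strip(code), strip(pattern))
}

# Vectorized: does each code match any of the (already dot-stripped) prefixes?
match_any_prefix <- function(codes, prefixes) {
  stripped <- gsub(".", "", codes, fixed = TRUE)
  out <- rep(FALSE, length(stripped))
  for (p in prefixes) out <- out | startsWith(stripped, p)
  out
}

# Split semicolon-separated dx lists into a long table (claim row id, code).
expand_dx <- function(medical) {
  codes <- strsplit(medical$dx_codes, ";", fixed = TRUE)
  n <- lengths(codes)
  out <- tibble::tibble(
    row = rep(seq_len(nrow(medical)), n),
    patient_id = rep(medical$patient_id, n),
    date = rep(medical$start_date, n),
    code = trimws(unlist(codes, use.names = FALSE))
  )
  out[nzchar(out$code) & !is.na(out$code), ]
}
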