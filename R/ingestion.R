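#' @importFrom data.table := .N .SD as.data.table data.table fread setnames setorder copy
NULL

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [read_claims()],
#' [map_attributes()] and the phenotyping predicates. Input column names and
#' the delimiter are configuration because claims extracts differ between
#' insurers; the defaults match the schema written by
#' [generate_cohort()].
#'
#' @param ... named overrides merged over the defaults (one level deep).
#' @return A named list with components `delim`, `columns` (logical name ->
#'   file column name), `gender_values`, `qualifying_specialties`,
#'   `gynecology_specialty`, `missing_rule` (`"or"` removes a patient when
#'   either demographic is ever missing; `"and"` only when a record lacks
#'   both), and `syringe_codes` (national drug codes of insulin
#'   syringes/devices excluded from the antidiabetic drug-class predicates).
#' @seealso [read_config()] to load the same structure from a YAML file.
#' @export
claims_config <- function(...) {
  cfg <- list(
    delim = ",",
    columns = list(
      insurance_id       = "Insurance_ID",
      insurance_serial   = "Insurance_Serial",
      prescription_id    = "Prescription_ID",
      age                = "Age",
      gender             = "Gender",
      prescriber_code    = "Prescriber_Code",
      national_drug_code = "National_Drug_Code"
    ),
    gender_values = list(
      male   = c("male", "m", "1"),
      female = c("female", "f", "2")
    ),
    qualifying_specialties = c("General Practitioner", "Internist", "Endocrinologist"),
    gynecology_specialty   = "Gynecology",
    missing_rule  = "or",
    syringe_codes = character(0)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path path to a YAML file; keys present in the file override the
#'   [claims_config()] defaults.
#' @return a configuration list as from [claims_config()].
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  do.call(claims_config, yaml::read_yaml(path))
}

#' Read a pharmacy-claims table
#'
#' Reads a delimited claims extract (one row per dispensed drug) into the
#' canonical column layout. Unparseable or out-of-range ages and unrecognised
#' gender strings become missing values rather than errors; a missing
#' mandatory column is a configuration error.
#'
#' @param path path to a delimited text file with a header row.
#' @param config configuration list from [claims_config()]/[read_config()].
#' @return a `data.table` with columns `insurance_id`, `insurance_serial`,
#'   `prescription_id`, `age` (integer, NA when missing), `gender`
#'   (`"male"`/`"female"`/NA), `prescriber_code`, `national_drug_code`.
#' @export
read_claims <- function(path, config = claims_config()) {
  stopifnot(file.exists(path))
  raw <- fread(path, sep = config$delim, colClasses = "character",
               header = TRUE, na.strings = NULL)
  cols <- config$columns
  missing_cols <- setdiff(unlist(cols), names(raw))
  if (length(missing_cols)) {
    stop("claims file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dt <- raw[, unlist(cols), with = FALSE]
  setnames(dt, names(cols))
  dt[, age := parse_age(age)]
  dt[, gender := parse_gender(gender, config$gender_values)]
  for (ch in c("insurance_id", "insurance_serial", "prescription_id",
               "prescriber_code", "national_drug_code")) {
    dt[[ch]] <- trimws(dt[[ch]])
  }
  dt[]
}

parse_age <- function(x) {
  a <- suppressWarnings(as.integer(trimws(x)))
  a[!is.na(a) & (a < 0L | a > 120L)] <- NA_integer_
  a
}

parse_gender <- function(x, gender_values) {
  x <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x %in% tolower(gender_values$male)]   <- "male"
  out[x %in% tolower(gender_values$female)] <- "female"
  out
}

#' Construct a unique patient identifier
#'
#' Insurance IDs are shared within families; the serial distinguishes
#' members. The two parts are joined with `"|"`, a character that occurs in
#' neither field, so the map is injective (a bare concatenation would
#' collide, e.g. `("0012","03")` vs `("00120","3")`).
#'
#' @param insurance_id,insurance_serial character vectors, non-empty.
#' @return character vector of patient IDs.
#' @export
construct_patient_id <- function(insurance_id, insurance_serial) {
  bad <- is.na(insurance_id) | is.na(insurance_serial) |
    insurance_id == "" | insurance_serial == ""
  if (any(bad)) {
    stop("empty insurance_id or insurance_serial in ", sum(bad), " record(s)",
         call. = FALSE)
  }
  paste(insurance_id, insurance_serial, sep = "|")
}

#' Remove patients with missing demographics
#'
#' Listwise deletion of whole patients: every record of any patient whose
#' history contains a missing age or gender is removed (missingness is
#' treated as completely at random, so deletion is unbiased). With
#' `missing_rule = "and"` a patient is only removed when some record lacks
#' both fields.
#'
#' @param claims claims `data.table` as from [read_claims()].
#' @param config configuration list; only `missing_rule` is used.
#' @return the surviving claims; attributes `n_dropped_records` and
#'   `n_dropped_patients` carry the deletion log.
#' @export
drop_missing_demographics <- function(claims, config = claims_config()) {
  claims <- as.data.table(claims)
  if (nrow(claims) == 0L) {
    out <- copy(claims)
    setattr(out, "n_dropped_records", 0L)
    setattr(out, "n_dropped_patients", 0L)
    return(out)
  }
  rec_bad <- switch(match.arg(config$missing_rule, c("or", "and")),
    "or"  = is.na(claims$age) | is.na(claims$gender),
    "and" = is.na(claims$age) & is.na(claims$gender)
  )
  key <- paste(claims$insurance_id, claims$insurance_serial, sep = "\r")
  bad_patients <- unique(key[rec_bad])
  keep <- !(key %in% bad_patients)
  out <- claims[keep]
  setattr(out, "n_dropped_records", sum(!keep))
  setattr(out, "n_dropped_patients", length(bad_patients))
  out[]
}

#' Map an age in years to its analysis category
#'
#' Three half-open intervals partition the non-negative integers:
#' `age < 30` is Young, `30 <= age < 45` Middle-Aged, `age >= 45` Old.
#'
#' @param age integer vector of ages in years; NA passes through.
#' @return character vector in `c("Young", "Middle-Aged", "Old")`.
#' @export
age_to_category <- function(age) {
  if (any(!is.na(age) & age < 0)) stop("negative age", call. = FALSE)
  out <- rep(NA_character_, length(age))
  out[!is.na(age) & age < 30] <- "Young"
  out[!is.na(age) & age >= 30 & age < 45] <- "Middle-Aged"
  out[!is.na(age) & age >= 45] <- "Old"
  out
}

#' Read the national-drug-code to ATC mapping table
#'
#' Expects a CSV with columns `national_drug_id`, `generic_name`, `atc_l5`,
#' `atc_l4`, `atc_l3`, `atc_l2`, `atc_l1`. The five ATC columns must form a
#' prefix-consistent truncation chain (lengths 7, 5, 4, 3, 1).
#'
#' @param path path to the mapping CSV.
#' @return a keyed `data.table`.
#' @export
read_drug_mapping <- function(path) {
  dm <- fread(path, colClasses = "character")
  need <- c("national_drug_id", "generic_name",
            "atc_l5", "atc_l4", "atc_l3", "atc_l2", "atc_l1")
  missing_cols <- setdiff(need, names(dm))
  if (length(missing_cols)) {
    stop("drug mapping is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_drug_mapping(dm)
  data.table::setkeyv(dm, "national_drug_id")
  dm[]
}

validate_drug_mapping <- function(dm) {
  lens <- c(atc_l1 = 1L, atc_l2 = 3L, atc_l3 = 4L, atc_l4 = 5L, atc_l5 = 7L)
  ok <- rep(TRUE, nrow(dm))
  for (k in names(lens)) ok <- ok & nchar(dm[[k]]) == lens[[k]]
  for (k in 1:4) {
    lo <- dm[[paste0("atc_l", k)]]
    hi <- dm[[paste0("atc_l", k + 1L)]]
    ok <- ok & startsWith(hi, lo)
  }
  if (!all(ok)) {
    stop("ATC chain violates prefix/length invariants for national code(s): ",
         paste(utils::head(dm$national_drug_id[!ok], 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(dm)
}

#' Read the prescriber-code to specialty mapping table
#'
#' @param path CSV with columns `prescriber_code`, `specialty`.
#' @return a keyed `data.table`.
#' @export
read_specialty_mapping <- function(path) {
  sm <- fread(path, colClasses = "character")
  missing_cols <- setdiff(c("prescriber_code", "specialty"), names(sm))
  if (length(missing_cols)) {
    stop("specialty mapping is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data.table::setkeyv(sm, "prescriber_code")
  sm[]
}

#' Attach ATC levels, specialty, age category and patient IDs to claims
#'
#' Joins the drug and specialty mapping tables onto the claims, derives the
#' age category and the unique patient ID, and resolves conflicting ages
#' within a patient to the minimum (the earliest plausible record; claims
#' carry no dates here). Records whose national drug code has no ATC mapping
#' are dropped and counted, never the whole patient; records whose prescriber
#' code has no specialty entry are kept with `prescriber_specialty = NA` and
#' counted as flagged.
#'
#' @param claims output of [drop_missing_demographics()].
#' @param drug_map table from [read_drug_mapping()].
#' @param spec_map table from [read_specialty_mapping()].
#' @return a `data.table` of mapped claims with columns `patient_id`,
#'   `prescription_id`, `age`, `gender`, `age_category`,
#'   `prescriber_specialty`, `national_drug_code`, `generic_name`,
#'   `atc_l1`..`atc_l5`; attributes `n_unmapped_drug_records` and
#'   `n_unmapped_prescriber_records` carry the log counts.
#' @export
map_attributes <- function(claims, drug_map, spec_map) {
  claims <- as.data.table(claims)
  if (nrow(claims) == 0L) {
    out <- data.table(
      patient_id = character(), prescription_id = character(),
      age = integer(), gender = character(), age_category = character(),
      prescriber_specialty = character(), national_drug_code = character(),
      generic_name = character(), atc_l1 = character(), atc_l2 = character(),
      atc_l3 = character(), atc_l4 = character(), atc_l5 = character()
    )
    setattr(out, "n_unmapped_drug_records", 0L)
    setattr(out, "n_unmapped_prescriber_records", 0L)
    return(out)
  }
  dt <- copy(claims)
  dt[, patient_id := construct_patient_id(insurance_id, insurance_serial)]
  dt <- merge(dt, drug_map, by.x = "national_drug_code",
              by.y = "national_drug_id", all.x = TRUE, sort = FALSE)
  n_unmapped_drug <- sum(is.na(dt$atc_l5))
  dt <- dt[!is.na(atc_l5)]
  dt <- merge(dt, spec_map, by = "prescriber_code", all.x = TRUE, sort = FALSE)
  setnames(dt, "specialty", "prescriber_specialty")
  n_unmapped_spec <- sum(is.na(dt$prescriber_specialty))
  # one age per patient: minimum across records, then categorise
  dt[, age := min(age), by = patient_id]
  dt[, age_category := age_to_category(age)]
  out <- dt[, .(patient_id, prescription_id, age, gender, age_category,
                prescriber_specialty, national_drug_code, generic_name,
                atc_l1, atc_l2, atc_l3, atc_l4, atc_l5)]
  setattr(out, "n_unmapped_drug_records", n_unmapped_drug)
  setattr(out, "n_unmapped_prescriber_records", n_unmapped_spec)
  out[]
}

#' Run the full ingestion stage
#'
#' Convenience wrapper: read claims, delete patients with missing
#' demographics, and map attributes, returning the mapped claims together
#' with a record-conservation log
#' (`n_input = n_retained + n_dropped_missing + n_dropped_unmapped`).
#'
#' @param claims_path,drug_map_path,spec_map_path file paths.
#' @param config configuration list.
#' @return `list(claims = mapped claims, log = list of counts)`.
#' @export
ingest_claims <- function(claims_path, drug_map_path, spec_map_path,
                          config = claims_config()) {
  raw <- read_claims(claims_path, config)
  kept <- drop_missing_demographics(raw, config)
  mapped <- map_attributes(kept, read_drug_mapping(drug_map_path),
                           read_specialty_mapping(spec_map_path))
  log <- list(
    n_input = nrow(raw),
    n_retained = nrow(mapped),
    n_dropped_missing = attr(kept, "n_dropped_records"),
    n_dropped_missing_patients = attr(kept, "n_dropped_patients"),
    n_dropped_unmapped = attr(mapped, "n_unmapped_drug_records"),
    n_flagged_prescriber = attr(mapped, "n_unmapped_prescriber_records")
  )
  list(claims = mapped, log = log)
}

# data.table's setattr without importing it at top level everywhere
setattr <- data.table::setattr
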