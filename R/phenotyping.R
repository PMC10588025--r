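#' Drug-class predicates for phenotyping
#'
#' Builds the configurable code sets used by the T2DM labelling rules. All
#' sets respect the ATC hierarchy: antidiabetic drugs are level-2 prefix
#' `A10`, insulins `A10A`, oral antidiabetics (OADs) `A10B`, metformin
#' `A10BA02`. Insulin (Human) is identified by generic-name match by default
#' (that is how formularies list it) with an optional explicit ATC list.
#' National codes in `syringe_codes` (insulin syringes/devices that the
#' national coding files under A10) are excluded from every predicate so a
#' device can neither qualify a prescription nor trigger an insulin-based
#' exclusion.
#'
#' @param config configuration list from [claims_config()]; supplies
#'   `syringe_codes`, `qualifying_specialties` and `gynecology_specialty`.
#' @param insulin_human_atc optional character vector of ATC level-5 codes
#'   treated as Insulin (Human) in addition to the name match.
#' @return an object of class `drug_predicates`: a list of vectorised
#'   record-level predicate functions over a mapped-claims table.
#' @export
drug_predicates <- function(config = claims_config(),
                            insulin_human_atc = character(0)) {
  syringe <- config$syringe_codes
  not_device <- function(claims) !(claims$national_drug_code %in% syringe)
  is_human_name <- function(claims) {
    nm <- tolower(claims$generic_name)
    grepl("insulin", nm, fixed = TRUE) & grepl("human", nm, fixed = TRUE) |
      claims$atc_l5 %in% insulin_human_atc
  }
  preds <- list(
    a10_all     = function(claims) claims$atc_l2 == "A10" & not_device(claims),
    insulin_any = function(claims) startsWith(claims$atc_l5, "A10A") & not_device(claims),
    oad         = function(claims) startsWith(claims$atc_l5, "A10B") & not_device(claims),
    insulin_human = function(claims) {
      startsWith(claims$atc_l5, "A10A") & not_device(claims) & is_human_name(claims)
    },
    metformin = function(claims) {
      (claims$atc_l5 == "A10BA02" |
         grepl("metformin", tolower(claims$generic_name), fixed = TRUE)) &
        not_device(claims)
    },
    qualifying_specialties = config$qualifying_specialties,
    gynecology_specialty   = config$gynecology_specialty
  )
  class(preds) <- "drug_predicates"
  preds
}

# Per-record predicate flags used by all phenotyping rules.
record_flags <- function(claims, preds) {
  data.table(
    patient_id      = claims$patient_id,
    prescription_id = claims$prescription_id,
    specialty       = claims$prescriber_specialty,
    is_a10          = preds$a10_all(claims),
    is_insulin      = preds$insulin_any(claims),
    is_oad          = preds$oad(claims),
    is_human        = preds$insulin_human(claims),
    is_metformin    = preds$metformin(claims)
  )
}

#' Flag qualifying prescriptions
#'
#' A prescription qualifies for the T2DM case definition when it contains at
#' least one antidiabetic (A10) drug that is not an excluded syringe/device
#' code AND its prescriber's specialty is one of the qualifying set (general
#' practitioner, internist, endocrinologist). Both conditions are evaluated
#' on the same prescription.
#'
#' @param claims mapped claims (from [map_attributes()]).
#' @param preds predicates from [drug_predicates()].
#' @return `data.table` with one row per (patient_id, prescription_id) and a
#'   logical `qualifying` column.
#' @export
qualifying_prescriptions <- function(claims, preds = drug_predicates()) {
  rf <- record_flags(claims, preds)
  rf[, .(
    qualifying = any(is_a10) &
      (specialty[1L] %in% preds$qualifying_specialties)
  ), by = .(patient_id, prescription_id)]
}

#' Detect patient-level exclusion conditions
#'
#' Evaluates the four exclusion rules that separate other indications for
#' antidiabetic drugs from T2DM. All four require age < 30:
#' \describe{
#'   \item{t1dm_male}{male on any insulin;}
#'   \item{t1dm_female}{female on any insulin other than Insulin (Human);}
#'   \item{pcos}{female with metformin prescribed by a gynecologist;}
#'   \item{pregnancy}{female on Insulin (Human) who is not among the
#'     patients with at least one OAD in a non-PCOS prescription (a
#'     prescription is "PCOS" when it itself contains gynecologist-prescribed
#'     metformin).}
#' }
#' Exclusions are patient-level and permanent for the study window.
#'
#' @inheritParams qualifying_prescriptions
#' @param age_cutoff strict upper age bound (years) below which the
#'   exclusion rules apply; 30 matches the Young category boundary.
#' @return `data.table` with one row per patient: `patient_id`, `age`,
#'   `gender`, logical columns `t1dm_male`, `t1dm_female`, `pcos`,
#'   `pregnancy`, and `excluded` (any of the four).
#' @export
detect_exclusions <- function(claims, preds = drug_predicates(),
                              age_cutoff = 30L) {
  rf <- record_flags(claims, preds)
  demo <- as.data.table(claims)[, .(age = age[1L], gender = gender[1L]),
                                by = patient_id]
  rx <- rf[, .(
    has_insulin    = any(is_insulin),
    has_nonhuman   = any(is_insulin & !is_human),
    has_human      = any(is_human),
    pcos_rx        = any(is_metformin) &
                       (specialty[1L] %in% preds$gynecology_specialty),
    has_oad        = any(is_oad)
  ), by = .(patient_id, prescription_id)]
  pat <- rx[, .(
    any_insulin     = any(has_insulin),
    any_nonhuman    = any(has_nonhuman),
    any_human       = any(has_human),
    any_pcos_rx     = any(pcos_rx),
    oad_non_pcos    = any(has_oad & !pcos_rx)
  ), by = patient_id]
  out <- merge(demo, pat, by = "patient_id", sort = FALSE)
  young  <- !is.na(out$age) & out$age < age_cutoff
  male   <- out$gender %in% "male"
  female <- out$gender %in% "female"
  out[, t1dm_male   := young & male & any_insulin]
  out[, t1dm_female := young & female & any_nonhuman]
  out[, pcos        := young & female & any_pcos_rx]
  out[, pregnancy   := young & female & any_human & !oad_non_pcos]
  out[, excluded := t1dm_male | t1dm_female | pcos | pregnancy]
  out[, .(patient_id, age, gender, t1dm_male, t1dm_female, pcos, pregnancy,
          excluded)]
}

#' Label patients as T2DM or not
#'
#' A patient is labelled T2DM when they have at least one qualifying
#' prescription ([qualifying_prescriptions()]) and none of the four
#' exclusion conditions ([detect_exclusions()]) applies.
#'
#' @inheritParams detect_exclusions
#' @return `data.table` with one row per patient: `patient_id`, `age`,
#'   `gender`, `age_category`, the four exclusion flags, `excluded`,
#'   `qualifies` and `is_t2dm`.
#' @export
label_t2dm <- function(claims, preds = drug_predicates(),
                       age_cutoff = 30L) {
  claims <- as.data.table(claims)
  qp <- qualifying_prescriptions(claims, preds)
  qual <- qp[, .(qualifies = any(qualifying)), by = patient_id]
  excl <- detect_exclusions(claims, preds, age_cutoff = age_cutoff)
  cat_ <- claims[, .(age_category = age_category[1L]), by = patient_id]
  out <- Reduce(function(a, b) merge(a, b, by = "patient_id", sort = FALSE),
                list(excl, qual, cat_))
  out[, is_t2dm := qualifies & !excluded]
  setorder(out, patient_id)
  out[]
}

#' Censor antidiabetic drugs from non-T2DM patients
#'
#' Removes every A10-coded record (level-2 ATC prefix `A10`, devices
#' included) belonging to a patient not labelled T2DM; all other records are
#' preserved. After censoring, any patient still holding an A10 code is by
#' construction a labelled T2DM patient.
#'
#' @param claims mapped claims.
#' @param labels patient labels from [label_t2dm()].
#' @return the censored claims; attribute `n_censored_records` logs the
#'   number of removed records.
#' @export
censor_a10 <- function(claims, labels) {
  claims <- as.data.table(claims)
  t2dm_ids <- labels$patient_id[labels$is_t2dm]
  drop <- claims$atc_l2 == "A10" & !(claims$patient_id %in% t2dm_ids)
  out <- claims[!drop]
  setattr(out, "n_censored_records", sum(drop))
  out[]
}
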