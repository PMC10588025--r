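#' Synthetic drug formulary
#'
#' A small ATC-coded formulary covering the drug classes that matter for the
#' analysis: oral antidiabetics, insulins (plus an insulin-syringe device
#' code that the national coding files under A10), statins, renin-angiotensin
#' agents, diuretics, antithrombotics, beta blockers, nitrates, thiamine,
#' gabapentin, levothyroxine, contraceptives and background drugs. The five
#' ATC levels are prefix-consistent truncations of the level-5 code.
#'
#' @return a `data.table` in the layout of [read_drug_mapping()].
#' @export
synthetic_formulary <- function() {
  fm <- data.table(
    national_drug_id = c(
      "50101", "50102", "50103", "50104",
      "50201", "50202", "50203", "50299",
      "60101", "60201", "60202", "60301", "60302",
      "02023", "60501", "60601",
      "70101", "70201", "70301",
      "80101", "80102", "80201", "80301", "90101", "90102"
    ),
    generic_name = c(
      "Metformin", "Glibenclamide", "Gliclazide", "Pioglitazone",
      "Insulin (Human)", "Insulin Aspart", "Insulin Glargine",
      "Insulin Syringe",
      "Atorvastatin", "Losartan", "Enalapril", "Hydrochlorothiazide",
      "Furosemide",
      "Acetylsalicylic Acid", "Metoprolol", "Isosorbide Dinitrate",
      "Thiamine (Vit B1)", "Gabapentin", "Levothyroxine",
      "Paracetamol", "Amoxicillin", "Folic Acid",
      "Levonorgestrel/Ethinylestradiol",
      "Omeprazole", "Cetirizine"
    ),
    atc_l5 = c(
      "A10BA02", "A10BB01", "A10BB09", "A10BG03",
      "A10AB01", "A10AB05", "A10AE04", "A10XA01",
      "C10AA05", "C09CA01", "C09AA02", "C03AA03", "C03CA01",
      "B01AC06", "C07AB02", "C01DA08",
      "A11DA01", "N03AX12", "H03AA01",
      "N02BE01", "J01CA04", "B03BB01",
      "G03AA07", "A02BC01", "R06AE07"
    )
  )
  fm[, atc_l4 := substr(atc_l5, 1L, 5L)]
  fm[, atc_l3 := substr(atc_l5, 1L, 4L)]
  fm[, atc_l2 := substr(atc_l5, 1L, 3L)]
  fm[, atc_l1 := substr(atc_l5, 1L, 1L)]
  data.table::setcolorder(fm, c("national_drug_id", "generic_name",
                                "atc_l5", "atc_l4", "atc_l3", "atc_l2",
                                "atc_l1"))
  fm[]
}

#' Synthetic prescriber-specialty mapping
#'
#' Deterministic code pools per specialty (code 1787 is an
#' endocrinologist, as in published mapping examples of this kind of table).
#'
#' @return a `data.table` in the layout of [read_specialty_mapping()].
#' @export
synthetic_specialty_mapping <- function() {
  pools <- list(
    "General Practitioner" = sprintf("%04d", 1001:1015),
    "Internist"            = sprintf("%04d", 1101:1110),
    "Endocrinologist"      = c("1787", sprintf("%04d", 1201:1204)),
    "Gynecology"           = sprintf("%04d", 1301:1310),
    "Cardiologist"         = sprintf("%04d", 1401:1405),
    "Other"                = sprintf("%04d", 1501:1510)
  )
  data.table::rbindlist(lapply(names(pools), function(sp) {
    data.table(prescriber_code = pools[[sp]], specialty = sp)
  }))
}

# Latent-condition prevalences P(condition | T2DM status, age, gender).
# Values are plausible claims-cohort figures; comorbidity enrichment in
# diabetics is the planted signal the miner is expected to recover.
default_condition_probs <- function() {
  grid <- data.table::CJ(condition = c("hypertension", "dyslipidemia", "cvd",
                                       "hypothyroidism", "neuropathy"),
                         t2dm = c(TRUE, FALSE),
                         age_category = c("Young", "Middle-Aged", "Old"),
                         gender = c("male", "female"))
  by_age <- function(young, mid, old, age) {
    c(Young = young, "Middle-Aged" = mid, Old = old)[age]
  }
  grid[, p := 0]
  grid[condition == "hypertension" & t2dm == FALSE,
       p := by_age(0.04, 0.15, 0.30, age_category)]
  grid[condition == "hypertension" & t2dm == TRUE,
       p := by_age(0.35, 0.50, 0.65, age_category)]
  grid[condition == "dyslipidemia" & t2dm == FALSE,
       p := by_age(0.04, 0.12, 0.22, age_category)]
  grid[condition == "dyslipidemia" & t2dm == TRUE,
       p := by_age(0.60, 0.68, 0.75, age_category)]
  grid[condition == "cvd" & t2dm == FALSE,
       p := by_age(0.01, 0.04, 0.15, age_category)]
  grid[condition == "cvd" & t2dm == TRUE,
       p := by_age(0.08, 0.22, 0.42, age_category)]
  grid[condition == "hypothyroidism",
       p := data.table::fifelse(gender == "female",
                                data.table::fifelse(t2dm, 0.15, 0.10),
                                data.table::fifelse(t2dm, 0.05, 0.03))]
  grid[condition == "neuropathy" & t2dm == FALSE, p := 0.01]
  grid[condition == "neuropathy" & t2dm == TRUE,
       p := by_age(0.06, 0.18, 0.32, age_category)]
  grid[]
}

# Per-prescription drug probabilities: p_rx when the indication condition is
# active, p_bg otherwise. Condition "t2dm" drugs are never drawn for
# non-diabetics; "background" drugs are condition-free (p_rx == p_bg).
# Scripted drugs (device, confounder-only) are added outside this model.
default_drug_model <- function() {
  data.table(
    national_drug_id = c("50101", "50102", "50103", "50104",
                         "50201", "50202", "50203",
                         "60101", "60201", "60202", "60301",
                         "60302", "02023", "60501", "60601",
                         "70101", "70201", "70301",
                         "80101", "80102", "80201"),
    condition = c(rep("t2dm", 7L),
                  "dyslipidemia", "hypertension", "hypertension",
                  "hypertension", "cvd", "cvd", "cvd", "cvd",
                  "neuropathy", "neuropathy", "hypothyroidism",
                  "background", "background", "background"),
    p_rx = c(0.70, 0.30, 0.15, 0.10,
             0.25, 0.08, 0.08,
             0.50, 0.30, 0.20, 0.15,
             0.20, 0.55, 0.40, 0.15,
             0.35, 0.30, 0.60,
             0.15, 0.08, 0.02),
    p_bg = c(rep(0, 7L),
             0.005, 0.003, 0.003, 0.002,
             0.002, 0.010, 0.005, 0.001,
             0.010, 0.005, 0.002,
             0.15, 0.08, 0.02)
  )
}

insulin_codes <- c("50201", "50202", "50203")
syringe_code <- "50299"
anchor_codes <- c("90101", "90102") # routine drugs guaranteeing >=1 dispensing
# device, folic, contraceptive, anchors: outside the factorized drug model
scripted_codes <- c(syringe_code, "80201", "80301", anchor_codes)

#' Specification of a synthetic claims cohort
#'
#' Collects every parameter of the generative model: cohort size and seed,
#' diabetic prevalence (10%, with diabetics predominantly old and female, as
#' in provincial claims cohorts), latent comorbidity prevalences, the
#' per-prescription drug model, confounder subpopulation rates (young type 1
#' diabetics, PCOS metformin from gynecologists, pregnant patients on human
#' insulin), prescriber-specialty assignment, and the demographic
#' missingness rate. Every patient receives a fixed number of prescriptions
#' (`n_prescriptions`) so that patient-level item probabilities aggregate
#' per-prescription Bernoulli draws as `1 - (1 - p)^m` and
#' [expected_rule_metrics()] is exact.
#'
#' @param n_patients cohort size.
#' @param seed RNG seed; fully determines the generated cohort.
#' @param ... overrides for any other component (see the returned list).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20000L, seed = 1L, ...) {
  spec <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    p_t2dm = 0.10,
    age_dist = list(
      t2dm = c("Young" = 0.074, "Middle-Aged" = 0.154, "Old" = 0.772),
      non  = c("Young" = 0.424, "Middle-Aged" = 0.230, "Old" = 0.346)
    ),
    gender_dist = list(
      t2dm = c(female = 0.634, male = 0.366),
      non  = c(female = 0.550, male = 0.450)
    ),
    age_bands = list("Young" = c(5L, 29L), "Middle-Aged" = c(30L, 44L),
                     "Old" = c(45L, 90L)),
    n_prescriptions = 3L,
    p_missing = 0.02,
    p_t1dm = 0.015,
    p_pcos = 0.03,
    p_pregnancy = 0.03,
    p_syringe_given_insulin = 0.6,
    specialty_probs = list(
      t2dm  = c("General Practitioner" = 0.55, "Internist" = 0.30,
                "Endocrinologist" = 0.15),
      other = c("General Practitioner" = 0.70, "Internist" = 0.20,
                "Cardiologist" = 0.05, "Other" = 0.05)
    ),
    condition_probs = default_condition_probs(),
    drug_model = default_drug_model(),
    formulary = synthetic_formulary()
  )
  dots <- list(...)
  for (nm in names(dots)) spec[[nm]] <- dots[[nm]]
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  probs <- c(spec$p_t2dm, spec$p_missing, spec$p_t1dm, spec$p_pcos,
             spec$p_pregnancy, spec$p_syringe_given_insulin,
             spec$condition_probs$p, spec$drug_model$p_rx,
             spec$drug_model$p_bg,
             unlist(spec$specialty_probs))
  if (any(probs < 0 | probs > 1)) {
    stop("cohort_spec contains probabilities outside [0, 1]", call. = FALSE)
  }
  for (d in c(spec$age_dist, spec$gender_dist)) {
    if (abs(sum(d) - 1) > 1e-8) {
      stop("age/gender distributions must sum to 1", call. = FALSE)
    }
  }
  stopifnot(spec$n_patients >= 1L, spec$n_prescriptions >= 1L)
  invisible(spec)
}

#' Generate a synthetic claims cohort
#'
#' Draws a cohort from the generative model in a [cohort_spec()]: latent
#' T2DM status, demographics, comorbid conditions, confounder
#' subpopulations, per-prescription drug draws, prescriber specialties, and
#' demographic missingness. The output claims table uses the exact CSV
#' schema the ingestion stage expects; the ground-truth table records every
#' latent variable and flags patients whose generated history cannot support
#' their latent label (`ambiguous`: diabetics for whom no antidiabetic drug
#' was ever drawn) plus those with blanked demographics (`missing_demo`).
#'
#' @param spec a [cohort_spec()].
#' @return `list(claims = data.table, truth = data.table)`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_patients
  m <- spec$n_prescriptions

  # -- patients: family-structured insurance IDs ---------------------------
  fam <- sample.int(max(1L, ceiling(n / 1.6)), n, replace = TRUE)
  pat <- data.table(idx = seq_len(n), insurance_id = sprintf("%07d", fam))
  pat[, insurance_serial := sprintf("%02d", seq_len(.N)), by = insurance_id]

  # -- latent status and demographics --------------------------------------
  pat[, t2dm := stats::runif(n) < spec$p_t2dm]
  pat[, age_category := NA_character_]
  pat[, gender := NA_character_]
  for (grp in c(TRUE, FALSE)) {
    key <- if (grp) "t2dm" else "non"
    sel <- which(pat$t2dm == grp)
    ad <- spec$age_dist[[key]]
    gd <- spec$gender_dist[[key]]
    pat$age_category[sel] <- sample(names(ad), length(sel), replace = TRUE,
                                    prob = ad)
    pat$gender[sel] <- sample(names(gd), length(sel), replace = TRUE,
                              prob = gd)
  }
  pat[, age := {
    lo <- vapply(spec$age_bands[age_category], `[`, integer(1), 1L)
    hi <- vapply(spec$age_bands[age_category], `[`, integer(1), 2L)
    lo + as.integer(floor(stats::runif(.N) * (hi - lo + 1L)))
  }]

  # -- confounder subpopulations (young, non-diabetic) ---------------------
  young <- pat$age_category == "Young"
  pat[, t1dm := !t2dm & young & stats::runif(n) < spec$p_t1dm]
  pat[, pcos := !t2dm & young & gender == "female" & !t1dm &
        stats::runif(n) < spec$p_pcos]
  pat[, pregnancy := !t2dm & young & gender == "female" & !t1dm & !pcos &
        stats::runif(n) < spec$p_pregnancy]

  # -- chronic comorbid conditions -----------------------------------------
  cp <- spec$condition_probs
  for (cond in unique(cp$condition)) {
    lut <- cp[cp$condition == cond, ]
    mg <- merge(pat[, .(idx, t2dm, age_category, gender)], lut,
                by = c("t2dm", "age_category", "gender"), sort = FALSE)
    data.table::setorder(mg, idx)
    data.table::set(pat, j = cond, value = stats::runif(n) < mg$p)
  }

  # -- prescriptions --------------------------------------------------------
  rx <- data.table(idx = rep(pat$idx, each = m),
                   rx_no = rep(seq_len(m), times = n))
  rx <- merge(rx, pat, by = "idx", sort = FALSE)
  rx[, prescription_id := sprintf("RX%07d-%d", idx, rx_no)]
  sp <- character(nrow(rx))
  draw_specialty <- function(sel, probs) {
    if (any(sel)) sp[sel] <<- sample(names(probs), sum(sel),
                                     replace = TRUE, prob = probs)
  }
  draw_specialty(rx$t2dm, spec$specialty_probs$t2dm)
  draw_specialty(!rx$t2dm & !rx$t1dm & !rx$pcos & !rx$pregnancy,
                 spec$specialty_probs$other)
  draw_specialty(rx$t1dm, c("Endocrinologist" = 0.6, "Internist" = 0.4))
  sp[rx$pcos] <- "Gynecology"
  draw_specialty(rx$pregnancy,
                 c("General Practitioner" = 0.5, "Gynecology" = 0.5))
  rx[, specialty := sp]

  # -- drug draws (general model) ------------------------------------------
  dm <- spec$drug_model
  drawn <- vector("list", nrow(dm) + 4L)
  for (i in seq_len(nrow(dm))) {
    cond <- dm$condition[i]
    active <- if (cond == "t2dm") rx$t2dm
              else if (cond == "background") rep(TRUE, nrow(rx))
              else rx[[cond]]
    p <- data.table::fifelse(active, dm$p_rx[i], dm$p_bg[i])
    if (dm$national_drug_id[i] %in% insulin_codes) {
      p[rx$age_category == "Young"] <- 0 # early T2DM is managed on OADs
    }
    hit <- stats::runif(nrow(rx)) < p
    if (any(hit)) {
      drawn[[i]] <- data.table(row = which(hit),
                               national_drug_code = dm$national_drug_id[i])
    }
  }

  # -- anchor dispensing: every patient's first prescription has a routine
  #    drug, so every patient appears in the claims file -------------------
  first_rx <- which(rx$rx_no == 1L)
  drawn[[length(drawn)]] <- data.table(
    row = first_rx,
    national_drug_code = sample(anchor_codes, length(first_rx),
                                replace = TRUE))

  # -- scripted confounder prescriptions -----------------------------------
  sc <- length(drawn) - 3L
  t1 <- which(rx$t1dm)
  if (length(t1)) {
    male <- rx$gender[t1] == "male"
    code <- character(length(t1))
    code[male] <- sample(insulin_codes, sum(male), replace = TRUE,
                         prob = c(0.4, 0.3, 0.3))
    code[!male] <- sample(insulin_codes[2:3], sum(!male), replace = TRUE)
    drawn[[sc]] <- data.table(row = t1, national_drug_code = code)
  }
  pc <- which(rx$pcos)
  if (length(pc)) {
    extra <- pc[stats::runif(length(pc)) < 0.5]
    drawn[[sc + 1L]] <- data.table(
      row = c(pc, extra),
      national_drug_code = c(rep("50101", length(pc)),
                             rep("80301", length(extra))))
  }
  pg <- which(rx$pregnancy)
  if (length(pg)) {
    extra <- pg[stats::runif(length(pg)) < 0.8]
    drawn[[sc + 2L]] <- data.table(
      row = c(pg, extra),
      national_drug_code = c(rep("50201", length(pg)),
                             rep("80201", length(extra))))
  }

  claims <- data.table::rbindlist(drawn[!vapply(drawn, is.null, logical(1))])
  claims <- unique(claims)

  # -- syringe accompanies insulin -----------------------------------------
  ins_rows <- unique(claims$row[claims$national_drug_code %in% insulin_codes])
  if (length(ins_rows)) {
    sy <- ins_rows[stats::runif(length(ins_rows)) <
                     spec$p_syringe_given_insulin]
    if (length(sy)) {
      claims <- rbind(claims, data.table(row = sy,
                                         national_drug_code = syringe_code))
    }
  }

  # -- assemble claim records ----------------------------------------------
  claims <- cbind(rx[claims$row,
                     .(insurance_id, insurance_serial, prescription_id,
                       age, gender, specialty, idx)],
                  claims[, .(national_drug_code)])
  sm <- synthetic_specialty_mapping()
  pools <- split(sm$prescriber_code, sm$specialty)
  claims[, prescriber_code := {
    out <- character(.N)
    for (sp in unique(specialty)) {
      sel <- specialty == sp
      out[sel] <- sample(pools[[sp]], sum(sel), replace = TRUE)
    }
    out
  }]

  # -- demographic missingness ---------------------------------------------
  miss <- which(stats::runif(n) < spec$p_missing)
  age_chr <- as.character(claims$age)
  gender_chr <- claims$gender
  if (length(miss)) {
    what <- sample(c("age", "gender", "both"), length(miss), replace = TRUE,
                   prob = c(0.45, 0.45, 0.10))
    blank_age <- miss[what != "gender"]
    blank_gen <- miss[what != "age"]
    age_chr[claims$idx %in% blank_age] <- ""
    gender_chr[claims$idx %in% blank_gen] <- ""
  }

  out_claims <- data.table(
    Insurance_ID = claims$insurance_id,
    Insurance_Serial = claims$insurance_serial,
    Prescription_ID = claims$prescription_id,
    Age = age_chr,
    Gender = gender_chr,
    Prescriber_Code = claims$prescriber_code,
    National_Drug_Code = claims$national_drug_code
  )
  setorder(out_claims, Insurance_ID, Insurance_Serial, Prescription_ID,
           National_Drug_Code)

  a10_pat <- unique(claims$idx[
    claims$national_drug_code %in%
      spec$drug_model$national_drug_id[spec$drug_model$condition == "t2dm"]])
  truth <- pat[, .(idx, insurance_id, insurance_serial, t2dm, age, gender,
                   age_category, t1dm, pcos, pregnancy, hypertension,
                   dyslipidemia, cvd, hypothyroidism, neuropathy)]
  truth[, patient_id := construct_patient_id(insurance_id, insurance_serial)]
  truth[, ambiguous := t2dm & !(idx %in% a10_pat)]
  truth[, missing_demo := idx %in% miss]
  truth[, c("idx", "insurance_id", "insurance_serial") := NULL]
  data.table::setcolorder(truth, "patient_id")

  list(claims = out_claims, truth = truth[])
}

#' Closed-form expected rule metrics under the generative model
#'
#' Computes the exact patient-level probabilities P(has A), P(has B),
#' P(has A and B) for ATC-level items by marginalizing the per-prescription
#' drug model over the latent condition distribution (per-prescription
#' Bernoulli draws aggregate to `1 - (1 - p)^m` at the patient level), then
#' derives support, confidence and lift. Probabilities refer to the
#' post-censoring transactions the miner sees: antidiabetic items occur only
#' in diabetic patients. Items whose formulary group consists of scripted
#' drugs (devices, confounder-only drugs) are not expressible in closed form
#' and raise an error.
#'
#' @param spec a [cohort_spec()].
#' @param antecedent character vector of ATC codes at `level`.
#' @param consequent single ATC code at `level`.
#' @param level ATC level 1–5.
#' @return `list(support, confidence, lift, p_antecedent, p_consequent)`.
#' @export
expected_rule_metrics <- function(spec, antecedent, consequent, level) {
  stopifnot(level %in% 1:5, length(consequent) == 1L,
            !(consequent %in% antecedent), length(antecedent) >= 1L)
  width <- atc_level_width[level]
  items <- c(antecedent, consequent)
  if (any(nchar(items) != width)) {
    stop("items must be ATC codes of level ", level, " (width ", width, ")",
         call. = FALSE)
  }
  fm <- copy(spec$formulary)
  fm[, item := substr(atc_l5, 1L, width)]
  dm <- merge(spec$drug_model, fm[, .(national_drug_id, item)],
              by = "national_drug_id", sort = FALSE)

  groups <- lapply(items, function(it) {
    codes_all <- fm$national_drug_id[fm$item == it]
    if (!length(codes_all)) stop("unsupported item: ", it, call. = FALSE)
    codes <- setdiff(codes_all, syringe_code) # device accompanies insulin
    if (!length(codes) || any(codes %in% scripted_codes)) {
      stop("unsupported item (scripted drugs): ", it, call. = FALSE)
    }
    dm[dm$national_drug_id %in% codes, ]
  })
  names(groups) <- items

  m <- spec$n_prescriptions
  cp <- spec$condition_probs
  cells <- data.table::CJ(t2dm = c(TRUE, FALSE),
                          age_category = c("Young", "Middle-Aged", "Old"),
                          gender = c("male", "female"))
  cells[, p_cell := {
    grp <- data.table::fifelse(t2dm, "t2dm", "non")
    mapply(function(g, a, s) {
      (if (g == "t2dm") spec$p_t2dm else 1 - spec$p_t2dm) *
        spec$age_dist[[g]][[a]] * spec$gender_dist[[g]][[s]]
    }, grp, age_category, gender)
  }]

  # per-prescription prob of drug d in a given cell and condition state
  q_drug <- function(row, cell, state) {
    if (row$condition == "t2dm") {
      if (!cell$t2dm) return(0)
      if (row$national_drug_id %in% insulin_codes &&
          cell$age_category == "Young") return(0)
      return(row$p_rx)
    }
    if (row$condition == "background") return(row$p_rx)
    if (isTRUE(state[[row$condition]])) row$p_rx else row$p_bg
  }

  prob_items <- function(which_items) {
    gs <- groups[which_items]
    conds <- setdiff(unique(unlist(lapply(gs, function(g) g$condition))),
                     c("t2dm", "background"))
    total <- 0
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci]
      states <- if (length(conds)) {
        do.call(data.table::CJ, stats::setNames(
          rep(list(c(TRUE, FALSE)), length(conds)), conds))
      } else data.table(.dummy = TRUE)
      cell_p <- 0
      for (si in seq_len(nrow(states))) {
        state <- as.list(states[si])
        p_state <- 1
        for (cond in conds) {
          pc <- cp$p[cp$condition == cond & cp$t2dm == cell$t2dm &
                       cp$age_category == cell$age_category &
                       cp$gender == cell$gender]
          p_state <- p_state * if (isTRUE(state[[cond]])) pc else 1 - pc
        }
        p_joint <- 1
        for (g in gs) {
          r <- 1
          for (k in seq_len(nrow(g))) r <- r * (1 - q_drug(g[k], cell, state))
          p_joint <- p_joint * (1 - r^m)
        }
        cell_p <- cell_p + p_state * p_joint
      }
      total <- total + cell$p_cell * cell_p
    }
    total
  }

  p_ab <- prob_items(items)
  p_a <- prob_items(antecedent)
  p_b <- prob_items(consequent)
  list(support = p_ab, confidence = p_ab / p_a,
       lift = (p_ab / p_a) / p_b, p_antecedent = p_a, p_consequent = p_b)
}

#' Observed lift and its Monte-Carlo standard error
#'
#' Estimates the lift of a rule directly from the per-patient item
#' indicators of a transaction set and its delta-method standard error (the
#' sampling noise of a cohort of `n_patients` i.i.d. patients).
#'
#' @param ts a `transaction_set`.
#' @param antecedent character vector of items.
#' @param consequent single item.
#' @return `list(lift, se, p_a, p_b, p_ab)`.
#' @export
observed_lift <- function(ts, antecedent, consequent) {
  stopifnot(inherits(ts, "transaction_set"))
  baskets <- transaction_items(ts)
  n <- ts$n_patients
  has_items <- function(b, its) all(its %in% b)
  xa <- xb <- xab <- logical(n)
  present <- names(baskets)
  pos <- match(present, ts$patient_ids)
  xa[pos] <- vapply(baskets, has_items, logical(1), its = antecedent)
  xb[pos] <- vapply(baskets, has_items, logical(1), its = consequent)
  xab <- xa & xb
  p_a <- mean(xa); p_b <- mean(xb); p_ab <- mean(xab)
  lift <- p_ab / (p_a * p_b)
  # influence function of f(p_ab, p_a, p_b) = p_ab / (p_a p_b)
  psi <- xab / (p_a * p_b) -
    p_ab * xa / (p_a^2 * p_b) -
    p_ab * xb / (p_a * p_b^2)
  list(lift = lift, se = stats::sd(psi) / sqrt(n),
       p_a = p_a, p_b = p_b, p_ab = p_ab)
}

#' Pipeline configuration matching the synthetic formulary
#'
#' The [claims_config()] defaults with the synthetic insulin-syringe device
#' code registered for exclusion from the antidiabetic predicates.
#'
#' @return a configuration list.
#' @export
synthetic_claims_config <- function() {
  claims_config(syringe_codes = syringe_code)
}

#' Hand-specified fixture patients covering every phenotyping branch
#'
#' Ten deterministic patients: one per exclusion rule (type 1 diabetes in a
#' young male and in a young female, PCOS, pregnancy), the
#' pregnancy-override case (human insulin but an OAD in a non-PCOS
#' prescription), the no-antidiabetic case, the wrong-specialty case, the
#' age-blocked gynecology-metformin case, the syringe-only case, and clean
#' T2DM cases (old female on metformin from a GP; young male on an OAD
#' only).
#'
#' @return `list(claims = data.table in the raw claims schema,
#'   expected = data.table(patient_id, is_t2dm, t1dm_male, t1dm_female,
#'   pcos, pregnancy))`.
#' @export
fixture_patients <- function() {
  row <- function(id, serial, rx, age, gender, prescriber, drug) {
    data.table(Insurance_ID = id, Insurance_Serial = serial,
               Prescription_ID = rx, Age = as.character(age),
               Gender = gender, Prescriber_Code = prescriber,
               National_Drug_Code = drug)
  }
  # prescriber codes: 1001 GP, 1101 Internist, 1787 Endocrinologist,
  # 1301 Gynecology (from synthetic_specialty_mapping())
  claims <- data.table::rbindlist(list(
    row("F001", "01", "P01", 25, "male",   "1787", "50203"), # t1dm male
    row("F002", "01", "P02", 27, "female", "1101", "50202"), # t1dm female
    row("F003", "01", "P03", 26, "female", "1301", "50101"), # pcos
    row("F004", "01", "P04", 24, "female", "1001", "50201"), # pregnancy
    row("F004", "01", "P04", 24, "female", "1001", "80201"),
    row("F005", "01", "P05", 24, "female", "1001", "50201"), # human insulin...
    row("F005", "01", "P06", 24, "female", "1101", "50101"), # ...but OAD -> T2DM
    row("F006", "01", "P07", 40, "male",   "1101", "60101"), # no A10 drug
    row("F007", "01", "P08", 50, "female", "1301", "50101"), # wrong specialty
    row("F008", "01", "P09", 55, "male",   "1001", "50299"), # syringe only
    row("F009", "01", "P10", 55, "female", "1001", "50101"), # clean T2DM
    row("F010", "01", "P11", 25, "male",   "1101", "50101")  # young OAD T2DM
  ))
  expected <- data.table(
    patient_id = paste(sprintf("F%03d", 1:10), "01", sep = "|"),
    is_t2dm     = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                    FALSE, FALSE, FALSE, TRUE, TRUE),
    t1dm_male   = c(TRUE, rep(FALSE, 9L)),
    t1dm_female = c(FALSE, TRUE, rep(FALSE, 8L)),
    pcos        = c(FALSE, FALSE, TRUE, rep(FALSE, 7L)),
    pregnancy   = c(FALSE, FALSE, FALSE, TRUE, rep(FALSE, 6L))
  )
  list(claims = claims, expected = expected)
}
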