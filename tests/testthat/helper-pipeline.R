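# Shared fixtures: mapping tables on disk, and a memoised synthetic-cohort
# pipeline run so several test files can reuse the same cohort.

write_mapping_files <- local({
  paths <- NULL
  function() {
    if (is.null(paths)) {
      fm <- file.path(tempdir(), "formulary.csv")
      sm <- file.path(tempdir(), "specialties.csv")
      data.table::fwrite(synthetic_formulary(), fm)
      data.table::fwrite(synthetic_specialty_mapping(), sm)
      paths <<- list(drug_map = fm, spec_map = sm)
    }
    paths
  }
})

# Run ingestion + phenotyping + censoring for a cohort spec.
run_pipeline <- function(spec) {
  maps <- write_mapping_files()
  cfg <- synthetic_claims_config()
  co <- generate_cohort(spec)
  claims_path <- tempfile(fileext = ".csv")
  data.table::fwrite(co$claims, claims_path)
  ing <- ingest_claims(claims_path, maps$drug_map, maps$spec_map, cfg)
  unlink(claims_path)
  preds <- drug_predicates(cfg)
  labels <- label_t2dm(ing$claims, preds)
  censored <- censor_a10(ing$claims, labels)
  list(spec = spec, truth = co$truth, raw = co$claims, log = ing$log,
       claims = ing$claims, preds = preds, labels = labels,
       censored = censored)
}

# One moderate cohort shared across test files.
test_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_pipeline(cohort_spec(n_patients = 6000L, seed = 7L))
    }
    cache
  }
})

# Mapped-claims rows built directly (bypassing file IO) for rule-level tests.
mapped_claim <- function(patient_id, prescription_id, age, gender,
                         specialty, drug) {
  fm <- synthetic_formulary()
  d <- fm[fm$national_drug_id == drug, ]
  stopifnot(nrow(d) == 1L)
  data.table::data.table(
    patient_id = patient_id, prescription_id = prescription_id,
    age = as.integer(age), gender = gender,
    age_category = age_to_category(age),
    prescriber_specialty = specialty,
    national_drug_code = drug, generic_name = d$generic_name,
    atc_l1 = d$atc_l1, atc_l2 = d$atc_l2, atc_l3 = d$atc_l3,
    atc_l4 = d$atc_l4, atc_l5 = d$atc_l5)
}

# Random small transaction databases for miner-vs-oracle checks.
random_transactions <- function(n_txn, n_items, density) {
  items <- letters[seq_len(n_items)]
  txns <- lapply(seq_len(n_txn), function(i) {
    items[stats::runif(n_items) < density]
  })
  txns[lengths(txns) > 0L]
}

itemset_key_table <- function(itemsets) {
  x <- data.table::as.data.table(itemsets)[, .(itemset, support_count)]
  data.table::setorder(x, itemset)
  x
}
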