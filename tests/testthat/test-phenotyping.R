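preds <- drug_predicates(synthetic_claims_config())

test_that("a prescription qualifies only with an A10 drug and a listed specialty", {
  met_endo <- mapped_claim("p1", "r1", 55, "female", "Endocrinologist", "50101")
  met_gyn  <- mapped_claim("p2", "r2", 55, "female", "Gynecology", "50101")
  statin   <- mapped_claim("p3", "r3", 55, "male", "Internist", "60101")
  qp <- qualifying_prescriptions(rbind(met_endo, met_gyn, statin), preds)
  expect_identical(qp$qualifying[match(c("r1", "r2", "r3"),
                                       qp$prescription_id)],
                   c(TRUE, FALSE, FALSE))
})

test_that("exclusion rules fire on the right demographics and drugs", {
  claims <- rbind(
    mapped_claim("m25", "r1", 25, "male", "Endocrinologist", "50203"),
    mapped_claim("f27", "r2", 27, "female", "General Practitioner", "50201"),
    mapped_claim("f50", "r3", 50, "female", "Gynecology", "50101")
  )
  ex <- detect_exclusions(claims, preds)
  m25 <- ex[ex$patient_id == "m25", ]
  expect_true(m25$t1dm_male)
  expect_false(any(m25$t1dm_female, m25$pcos, m25$pregnancy))
  f27 <- ex[ex$patient_id == "f27", ]
  expect_true(f27$pregnancy)  # human insulin, no OAD anywhere
  expect_false(f27$t1dm_female)  # human insulin does not count
  f50 <- ex[ex$patient_id == "f50", ]
  expect_false(f50$excluded)  # age >= 30 blocks every branch
})

test_that("fixture patients are labelled exactly as hand-derived", {
  fx <- fixture_patients()
  maps <- write_mapping_files()
  path <- tempfile(fileext = ".csv")
  data.table::fwrite(fx$claims, path)
  ing <- ingest_claims(path, maps$drug_map, maps$spec_map,
                       synthetic_claims_config())
  labels <- label_t2dm(ing$claims, preds)
  got <- merge(fx$expected, labels, by = "patient_id",
               suffixes = c(".exp", ""))
  expect_identical(nrow(got), nrow(fx$expected))
  expect_identical(got$is_t2dm, got$is_t2dm.exp)
  expect_identical(got$t1dm_male, got$t1dm_male.exp)
  expect_identical(got$t1dm_female, got$t1dm_female.exp)
  expect_identical(got$pcos, got$pcos.exp)
  expect_identical(got$pregnancy, got$pregnancy.exp)
})

test_that("an exclusion overrides a qualifying prescription", {
  # young male, insulin from an endocrinologist: qualifies but is excluded
  claims <- mapped_claim("p", "r", 25, "male", "Endocrinologist", "50201")
  lab <- label_t2dm(claims, preds)
  expect_true(lab$qualifies)
  expect_true(lab$excluded)
  expect_false(lab$is_t2dm)
})

test_that("labelling is invariant to record order within a patient", {
  pl <- test_cohort()
  shuffled <- pl$claims[sample(nrow(pl$claims))]
  lab2 <- label_t2dm(shuffled, pl$preds)
  ref <- pl$labels[order(patient_id)]
  cmp <- lab2[order(patient_id)]
  expect_identical(cmp$is_t2dm, ref$is_t2dm)
  expect_identical(cmp$excluded, ref$excluded)
})

test_that("exclusion flags are monotone in the age cutoff", {
  pl <- test_cohort()
  e30 <- detect_exclusions(pl$claims, pl$preds, age_cutoff = 30L)
  e45 <- detect_exclusions(pl$claims, pl$preds, age_cutoff = 45L)
  both <- merge(e30, e45, by = "patient_id", suffixes = c(".30", ".45"))
  expect_true(all(!both$excluded.30 | both$excluded.45))
})

test_that("censoring removes A10 drugs from non-T2DM patients only", {
  claims <- rbind(
    mapped_claim("preg", "r1", 24, "female", "General Practitioner", "50201"),
    mapped_claim("preg", "r1", 24, "female", "General Practitioner", "80201"),
    mapped_claim("t2dm", "r2", 60, "male", "Internist", "50101")
  )
  labels <- label_t2dm(claims, preds)
  cen <- censor_a10(claims, labels)
  expect_identical(cen[cen$patient_id == "preg", ]$generic_name, "Folic Acid")
  expect_identical(nrow(cen[cen$patient_id == "t2dm", ]), 1L)
  expect_identical(attr(cen, "n_censored_records"), 1L)
  # no-op when nothing to censor
  cen2 <- censor_a10(cen, labels)
  expect_equal(cen2, cen, ignore_attr = TRUE)
})

test_that("after censoring, every remaining A10 holder is labelled T2DM", {
  pl <- test_cohort()
  holders <- unique(pl$censored[pl$censored$atc_l2 == "A10", ]$patient_id)
  t2dm_ids <- pl$labels$patient_id[pl$labels$is_t2dm]
  expect_true(all(holders %in% t2dm_ids))
})

test_that("phenotyping recovers the latent labels on synthetic truth", {
  pl <- test_cohort()
  truth <- pl$truth[pl$truth$missing_demo == FALSE, ]
  m <- merge(truth, pl$labels[, c("patient_id", "is_t2dm")],
             by = "patient_id")
  expect_identical(nrow(m), nrow(truth))
  expect_gte(mean(m$is_t2dm == m$t2dm), 0.99)
  unambiguous <- m[m$ambiguous == FALSE, ]
  expect_identical(unambiguous$is_t2dm, unambiguous$t2dm)
})
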