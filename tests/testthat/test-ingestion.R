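test_that("age categories partition 0..120 with the documented boundaries", {
  ages <- 0:120
  cats <- age_to_category(ages)
  expect_false(anyNA(cats))
  expect_true(all(cats %in% c("Young", "Middle-Aged", "Old")))
  expect_identical(age_to_category(c(29, 30, 44, 45)),
                   c("Young", "Middle-Aged", "Middle-Aged", "Old"))
  expect_identical(age_to_category(38), "Middle-Aged")
  # each age falls in exactly one interval
  in_young <- ages < 30
  in_mid <- ages >= 30 & ages < 45
  in_old <- ages >= 45
  expect_true(all(in_young + in_mid + in_old == 1L))
  expect_error(age_to_category(-1), "negative")
})

test_that("claims parsing tolerates bad values and flags missing columns", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "Insurance_ID,Insurance_Serial,Prescription_ID,Age,Gender,Prescriber_Code,National_Drug_Code",
    "A1,01,P1,38,female,1001,50101",
    "A1,01,P2,,male,1001,50101",
    "A2,02,P3,abc,,1002,02023",
    "A3,03,P4,130,F,1002,02023"
  ), path)
  claims <- read_claims(path)
  expect_identical(claims$age, c(38L, NA, NA, NA))
  expect_identical(claims$gender, c("female", "male", NA, "female"))

  empty <- tempfile(fileext = ".csv")
  writeLines("Insurance_ID,Insurance_Serial,Prescription_ID,Age,Gender,Prescriber_Code,National_Drug_Code",
             empty)
  expect_identical(nrow(read_claims(empty)), 0L)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("Insurance_ID,Age", "A,1"), bad)
  expect_error(read_claims(bad), "National_Drug_Code")
})

test_that("patient IDs are deterministic and injective", {
  expect_identical(construct_patient_id("0012", "03"), "0012|03")
  expect_false(construct_patient_id("0012", "03") ==
                 construct_patient_id("00120", "3"))
  expect_identical(construct_patient_id("0012", "03"),
                   construct_patient_id("0012", "03"))
  expect_error(construct_patient_id("", "03"), "empty")
})

test_that("patients with any missing demographic are removed wholesale", {
  claims <- data.table::data.table(
    insurance_id = c("A", "A", "A", "B", "C", "C"),
    insurance_serial = c("1", "1", "1", "1", "1", "1"),
    prescription_id = paste0("P", 1:6),
    age = c(40L, NA, 41L, 50L, 30L, 30L),
    gender = c("male", "male", "male", "female", NA, "female"),
    prescriber_code = "1001",
    national_drug_code = "50101"
  )
  out <- drop_missing_demographics(claims)
  expect_identical(sort(unique(out$insurance_id)), "B")
  expect_identical(attr(out, "n_dropped_records"), 5L)
  expect_identical(attr(out, "n_dropped_patients"), 2L)
  # idempotence
  again <- drop_missing_demographics(out)
  expect_equal(again, out, ignore_attr = TRUE)
  # total removal
  all_bad <- claims[is.na(age) | is.na(gender)]
  expect_identical(nrow(drop_missing_demographics(all_bad)), 0L)
  # strict-AND variant keeps patients missing only one field
  and_cfg <- claims_config(missing_rule = "and")
  expect_identical(sort(unique(drop_missing_demographics(claims, and_cfg)$insurance_id)),
                   c("A", "B", "C"))
})

test_that("attribute mapping attaches ATC chain, specialty and age category", {
  claims <- data.table::data.table(
    insurance_id = c("A", "A", "B"),
    insurance_serial = "1",
    prescription_id = c("P1", "P1", "P2"),
    age = c(38L, 38L, 62L),
    gender = c("male", "male", "female"),
    prescriber_code = c("1787", "1787", "9999"),
    national_drug_code = c("02023", "XXXXX", "50101")
  )
  fm <- synthetic_formulary()
  sm <- synthetic_specialty_mapping()
  mapped <- map_attributes(claims, fm, sm)
  asa <- mapped[mapped$national_drug_code == "02023", ]
  expect_identical(
    unlist(asa[, c("atc_l5", "atc_l4", "atc_l3", "atc_l2", "atc_l1")],
           use.names = FALSE),
    c("B01AC06", "B01AC", "B01A", "B01", "B"))
  expect_identical(asa$prescriber_specialty, "Endocrinologist")
  expect_identical(asa$age_category, "Middle-Aged")
  # unmapped drug dropped and counted; unmapped prescriber kept but flagged
  expect_identical(attr(mapped, "n_unmapped_drug_records"), 1L)
  expect_identical(attr(mapped, "n_unmapped_prescriber_records"), 1L)
  expect_true(is.na(mapped[mapped$patient_id == "B|1", ]$prescriber_specialty))
})

test_that("ATC chains in the formulary are prefix-consistent", {
  fm <- synthetic_formulary()
  for (k in 1:4) {
    expect_true(all(startsWith(fm[[paste0("atc_l", k + 1L)]],
                               fm[[paste0("atc_l", k)]])))
  }
  expect_identical(unique(nchar(fm$atc_l5)), 7L)
})

test_that("ingestion conserves records across the three dispositions", {
  pl <- test_cohort()
  log <- pl$log
  expect_identical(log$n_input,
                   log$n_retained + log$n_dropped_missing +
                     log$n_dropped_unmapped)
  expect_identical(log$n_dropped_unmapped, 0L)
  # conflicting ages collapse to one age per patient
  expect_true(all(pl$claims[, data.table::uniqueN(age),
                            by = patient_id]$V1 == 1L))
})

test_that("YAML configs override the defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("missing_rule: and", "syringe_codes:", "  - '50299'"), path)
  cfg <- read_config(path)
  expect_identical(cfg$missing_rule, "and")
  expect_identical(cfg$syringe_codes, "50299")
  expect_identical(cfg$columns, claims_config()$columns)
})
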