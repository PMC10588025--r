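fake_ts <- function(n_patients, n_diabetic) {
  structure(list(level = 2L, stratum = c(gender = "all", age_category = "all"),
                 items = data.table::data.table(patient_id = character(0),
                                                item = character(0)),
                 patient_ids = character(0),
                 n_patients = n_patients, n_diabetic = n_diabetic),
            class = "transaction_set")
}

test_that("frequent items are thresholded with ceil and ordered by count then name", {
  txns <- list(c("a", "b"), "a", c("a", "b", "c"))
  fi <- find_frequent_items(txns, mining_config(min_support = 0.5))
  expect_identical(fi$item, c("a", "b"))    # c: 1/3 < 0.5
  expect_identical(fi$count, c(3L, 2L))
  # unanimity at min_support = 1
  all_x <- list(c("x", "y"), "x", c("x", "z"))
  expect_identical(find_frequent_items(all_x, mining_config(min_support = 1))$item,
                   "x")
  expect_identical(nrow(find_frequent_items(list(), mining_config())), 0L)
  # lexicographic tie-break
  tie <- find_frequent_items(list(c("b", "a")), mining_config())
  expect_identical(tie$item, c("a", "b"))
})

test_that("the FP-tree shares paths and links nodes through the header", {
  txns <- list(c("a", "b"), c("a", "b"))
  tree <- build_fp_tree(txns, find_frequent_items(txns, mining_config()))
  a <- tree$root$children[["a"]]
  expect_identical(a$count, 2)
  expect_identical(a$children[["b"]]$count, 2)
  expect_null(a$children[["b"]]$children[["anything"]])

  txns2 <- list(c("a", "b"), c("a", "c"))
  tree2 <- build_fp_tree(txns2, find_frequent_items(txns2, mining_config()))
  a2 <- tree2$root$children[["a"]]
  expect_identical(a2$count, 2)
  expect_identical(a2$children[["b"]]$count, 1)
  expect_identical(a2$children[["c"]]$count, 1)
  # header chain counts sum to the item's support
  expect_identical(sum(vapply(tree2$header[["a"]], function(n) n$count,
                              numeric(1))), 2)
  # transactions with no frequent item contribute no path
  txns3 <- list(rep("a", 1), "b")
  tree3 <- build_fp_tree(txns3, data.table::data.table(item = "a", count = 1L))
  expect_identical(length(ls(tree3$root$children)), 1L)
})

test_that("FP-Growth recovers hand-computed itemsets", {
  got <- mine_frequent_itemsets(list(c("a", "b"), c("a", "b"), "a"),
                                mining_config(min_support = 0.5))
  expect_identical(itemset_key_table(got),
                   data.table::data.table(itemset = c("a", "a,b", "b"),
                                          support_count = c(3L, 2L, 2L)))
  # threshold above every frequency
  none <- mine_frequent_itemsets(list("a", "b"), mining_config(min_support = 0.9))
  expect_identical(nrow(none), 0L)
  # power set of a single transaction
  ps <- mine_frequent_itemsets(list(c("a", "b", "c")),
                               mining_config(min_support = 0.5))
  expect_identical(nrow(ps), 7L)
  expect_true(all(ps$support_count == 1L))
})

test_that("rule metrics match the worked eight-transaction example", {
  txns <- c(rep(list(c("A10", "C10")), 4), rep(list("A10"), 2),
            list("C10"), list("C07"))
  res <- mine_rules(txns, mining_config(min_support = 0.125,
                                        min_confidence = 0.1))
  r <- res$rules[res$rules$antecedent == "A10" & res$rules$consequent == "C10", ]
  expect_identical(r$joint_count, 4L)
  expect_equal(r$support, 0.5, tolerance = 1e-12)
  expect_equal(r$confidence, 4 / 6, tolerance = 1e-12)
  expect_equal(r$lift, (4 / 6) / (5 / 8), tolerance = 1e-12)
})

test_that("a perfectly co-occurring pair has confidence 1 and lift 1/Supp(B)", {
  txns <- c(rep(list(c("x", "y")), 2), rep(list("z"), 2))
  rules <- mine_rules(txns, mining_config(min_support = 0.25,
                                          min_confidence = 0.5))$rules
  xy <- rules[rules$antecedent == "x", ]
  expect_equal(xy$confidence, 1)
  expect_equal(xy$lift, 2)
})

test_that("prevalence is the joint count over diabetic patients", {
  rules <- data.table::data.table(antecedent = "A10", consequent = "C10",
                                  joint_count = 4L, support = 0.5,
                                  confidence = 0.5, lift = 1,
                                  prevalence = NA_real_)
  expect_equal(compute_prevalence(rules, fake_ts(8L, 6L))$prevalence, 4 / 6)
  expect_equal(compute_prevalence(rules, fake_ts(8L, 4L))$prevalence, 1)
  # sigma recovered from support x N
  r2 <- data.table::data.table(antecedent = "a", consequent = "b",
                               joint_count = as.integer(0.001 * 10000),
                               support = 0.001, confidence = 0.1, lift = 1,
                               prevalence = NA_real_)
  expect_equal(compute_prevalence(r2, fake_ts(10000L, 1000L))$prevalence, 0.01)
  expect_error(compute_prevalence(rules, fake_ts(8L, 0L)), "prevalence")
})

test_that("brute-force enumeration refuses oversized item sets", {
  txns <- list(paste0("i", 1:21))
  expect_error(brute_force_itemsets(txns, mining_config(min_support = 0.5)),
               "21")
})

test_that("FP-Growth equals exhaustive enumeration on random instances", {
  set.seed(20240917)
  for (i in 1:30) {
    txns <- random_transactions(sample(10:60, 1), sample(3:8, 1),
                                stats::runif(1, 0.2, 0.7))
    if (!length(txns)) next
    cfg <- mining_config(min_support = stats::runif(1, 0.05, 0.5))
    expect_identical(itemset_key_table(mine_frequent_itemsets(txns, cfg)),
                     itemset_key_table(brute_force_itemsets(txns, cfg)))
  }
})

test_that("itemsets obey downward closure and threshold anti-monotonicity", {
  set.seed(11)
  txns <- random_transactions(80, 7, 0.4)
  its <- mine_frequent_itemsets(txns, mining_config(min_support = 0.1))
  lookup <- stats::setNames(its$support_count, its$itemset)
  for (i in which(its$size > 1L)) {
    items <- its$items[[i]]
    for (j in seq_along(items)) {
      sub <- paste(items[-j], collapse = ",")
      expect_true(sub %in% names(lookup))
      expect_gte(lookup[[sub]], its$support_count[i])
    }
  }
  looser <- mine_frequent_itemsets(txns, mining_config(min_support = 0.05))
  expect_true(all(its$itemset %in% looser$itemset))
  rules_strict <- mine_rules(txns, mining_config(0.1, 0.5))$rules
  rules_loose <- mine_rules(txns, mining_config(0.1, 0.2))$rules
  key <- function(r) paste(r$antecedent, r$consequent, sep = "=>")
  expect_true(all(key(rules_strict) %in% key(rules_loose)))
})

test_that("the itemset-size cap truncates with a warning but keeps exact counts", {
  txns <- rep(list(c("a", "b", "c", "d")), 3)
  expect_warning(
    capped <- mine_frequent_itemsets(txns, mining_config(min_support = 0.5,
                                                         max_itemset_size = 2)),
    "truncated")
  expect_identical(max(capped$size), 2L)
  full <- mine_frequent_itemsets(txns, mining_config(min_support = 0.5))
  small <- full[full$size <= 2L, ]
  expect_identical(itemset_key_table(capped), itemset_key_table(small))
})
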