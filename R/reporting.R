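#' Keep diabetes-anchored rules
#'
#' Retains rules whose antecedent is non-empty and consists entirely of
#' antidiabetic codes (level-2 ATC prefix `A10`) and whose consequent is not
#' an antidiabetic code — the co-prescriptions of interest: what else is
#' dispensed to patients on diabetes drugs.
#'
#' @param rules rule table from [generate_rules()].
#' @return the filtered rule table.
#' @export
filter_diabetes_rules <- function(rules) {
  rules <- as.data.table(rules)
  if (nrow(rules) == 0L) return(rules)
  ante_items <- strsplit(rules$antecedent, ",", fixed = TRUE)
  # only codes of length >= 3 with prefix A10 count as antidiabetic
  keep <- vapply(ante_items, function(x) {
    length(x) > 0L && all(nchar(x) >= 3L & startsWith(x, "A10"))
  }, logical(1))
  keep <- keep & !startsWith(rules$consequent, "A10")
  rules[keep]
}

#' Rank, filter and truncate rules for reporting
#'
#' Applies the reporting conventions: drop rules with lift at or below the
#' floor (strictly greater than 2.0 survives by default), sort descending by
#' the level's key — prevalence at ATC level 2 (the most-prescribed drug
#' classes), lift at levels 3–5 — with ties broken by descending confidence
#' then antecedent order, and truncate to the top `k`.
#'
#' @param rules rule table (normally [filter_diabetes_rules()] output).
#' @param level ATC level the rules were mined at (selects the sort key).
#' @param k maximum number of reported rules (default 30).
#' @param lift_floor strict lower bound on lift (default 2.0).
#' @param sort_key override the per-level default; one of `"prevalence"`,
#'   `"lift"`.
#' @return an object of class `rule_report`: the truncated rule table plus
#'   attributes `level`, `sort_key`, `k`, `lift_floor`.
#' @export
rank_and_truncate <- function(rules, level, k = 30L, lift_floor = 2.0,
                              sort_key = NULL) {
  rules <- as.data.table(rules)
  if (is.null(sort_key)) sort_key <- if (level == 2L) "prevalence" else "lift"
  sort_key <- match.arg(sort_key, c("prevalence", "lift"))
  out <- rules[rules$lift > lift_floor]
  if (nrow(out) > 0L) {
    ord <- order(-out[[sort_key]], -out$confidence, out$antecedent,
                 out$consequent)
    out <- out[ord]
    out <- out[seq_len(min(k, nrow(out)))]
  }
  structure(out, class = c("rule_report", class(out)),
            level = level, sort_key = sort_key, k = k,
            lift_floor = lift_floor)
}

#' Grid search over mining thresholds
#'
#' Re-mines the transaction set at every combination of minimum support and
#' minimum confidence and tabulates how many frequent itemsets, rules and
#' diabetes-anchored rules survive — the evidence on which a working point
#' is chosen. Counts are monotone non-increasing along both axes.
#'
#' @param ts a `transaction_set`.
#' @param support_grid,confidence_grid numeric vectors of thresholds.
#' @return `data.table(min_support, min_confidence, n_itemsets, n_rules,
#'   n_diabetes_rules)`, one row per grid cell.
#' @export
threshold_sweep <- function(ts, support_grid, confidence_grid) {
  stopifnot(length(support_grid) > 0L, length(confidence_grid) > 0L)
  rows <- list()
  for (s in sort(support_grid)) {
    itemsets <- mine_frequent_itemsets(ts, mining_config(min_support = s))
    for (conf in sort(confidence_grid)) {
      cfg <- mining_config(min_support = s, min_confidence = conf)
      rules <- generate_rules(itemsets, ts, cfg)
      rows[[length(rows) + 1L]] <- data.table(
        min_support = s, min_confidence = conf,
        n_itemsets = nrow(itemsets), n_rules = nrow(rules),
        n_diabetes_rules = nrow(filter_diabetes_rules(rules))
      )
    }
  }
  data.table::rbindlist(rows)
}
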