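atc_level_width <- c(1L, 3L, 4L, 5L, 7L)

#' Build per-patient drug transactions at one ATC level
#'
#' Aggregates censored, mapped claims into one deduplicated set of ATC codes
#' per patient, truncated to the chosen hierarchy level. The denominator
#' `n_patients` is the number of cohort patients in the stratum — including
#' patients whose entire record set was censored away and who therefore
#' contribute an empty basket — so support is computed against the full
#' cohort. `n_diabetic` counts the T2DM-labelled patients in the stratum.
#'
#' @param claims mapped (and normally censored) claims.
#' @param level ATC level, integer 1–5 (code widths 1, 3, 4, 5, 7).
#' @param cohort patient table from [label_t2dm()] (or any table with
#'   `patient_id`, `gender`, `age_category`, `is_t2dm`) defining the cohort.
#' @param stratum length-2 character vector `(gender, age_category)`; either
#'   component may be `"all"`.
#' @return an object of class `transaction_set`: a list with `level`,
#'   `stratum`, `items` (a `data.table(patient_id, item)` of distinct pairs),
#'   `patient_ids`, `n_patients`, `n_diabetic`.
#' @export
build_transactions <- function(claims, level, cohort,
                               stratum = c("all", "all")) {
  if (!(is.numeric(level) && length(level) == 1L && level %in% 1:5)) {
    stop("level must be an integer between 1 and 5", call. = FALSE)
  }
  level <- as.integer(level)
  claims <- as.data.table(claims)
  cohort <- as.data.table(cohort)
  sel <- rep(TRUE, nrow(cohort))
  if (stratum[1] != "all") sel <- sel & cohort$gender == stratum[1]
  if (stratum[2] != "all") sel <- sel & cohort$age_category == stratum[2]
  cohort <- cohort[sel]
  col <- paste0("atc_l", level)
  items <- claims[patient_id %in% cohort$patient_id,
                  .(patient_id, item = get(col))]
  items <- unique(items)
  setorder(items, patient_id, item)
  structure(list(
    level = level,
    stratum = c(gender = stratum[1], age_category = stratum[2]),
    items = items,
    patient_ids = cohort$patient_id,
    n_patients = nrow(cohort),
    n_diabetic = sum(cohort$is_t2dm)
  ), class = "transaction_set")
}

#' Extract transactions as a list of item vectors
#'
#' Only non-empty baskets appear in the list; the set's `n_patients` remains
#' the support denominator.
#'
#' @param ts a `transaction_set`.
#' @return named list of character vectors, one per contributing patient.
#' @export
transaction_items <- function(ts) {
  stopifnot(inherits(ts, "transaction_set"))
  if (nrow(ts$items) == 0L) return(list())
  split(ts$items$item, ts$items$patient_id)
}

#' @export
print.transaction_set <- function(x, ...) {
  cat(sprintf(
    "<transaction_set> ATC level %d, stratum (%s, %s): %d patients (%d diabetic), %d item rows\n",
    x$level, x$stratum[1], x$stratum[2], x$n_patients, x$n_diabetic,
    nrow(x$items)))
  invisible(x)
}

#' Stratified transaction sets
#'
#' Builds transaction sets for every combination of gender in
#' `{male, female, all}` and age category in
#' `{Young, Middle-Aged, Old, all}` (12 strata), dropping empty ones. Each
#' patient belongs to exactly four strata: their own cell, the two margins,
#' and the grand total.
#'
#' @inheritParams build_transactions
#' @return a named list of `transaction_set` objects, names like
#'   `"male|Old"` or `"all|all"`.
#' @export
stratify <- function(claims, level, cohort) {
  out <- list()
  for (g in c("male", "female", "all")) {
    for (a in c("Young", "Middle-Aged", "Old", "all")) {
      ts <- build_transactions(claims, level, cohort, stratum = c(g, a))
      if (ts$n_patients > 0L) out[[paste(g, a, sep = "|")]] <- ts
    }
  }
  out
}

#' Write transactions in basket format
#'
#' One line per patient, tab-separated ATC codes; patients with an empty
#' basket produce an empty line so the support denominator is recoverable.
#'
#' @param ts a `transaction_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_basket <- function(ts, path) {
  stopifnot(inherits(ts, "transaction_set"))
  baskets <- transaction_items(ts)
  lines <- vapply(ts$patient_ids, function(pid) {
    b <- baskets[[pid]]
    if (is.null(b)) "" else paste(b, collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a basket file as a list of transactions
#'
#' @param path basket file path (one line per patient, tab-separated items;
#'   empty lines are empty baskets).
#' @return list of character vectors (empty vectors for empty lines).
#' @export
read_basket <- function(path) {
  lines <- readLines(path)
  lapply(strsplit(lines, "\t", fixed = TRUE),
         function(x) x[nzchar(x)])
}
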