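#' Mining configuration
#'
#' @param min_support minimum rule/itemset support as a fraction of the
#'   number of patients, in (0, 1]. The support-count threshold is
#'   `ceiling(min_support * N)` and the comparison is non-strict
#'   (`count >= threshold`). Default 0.0001.
#' @param min_confidence minimum rule confidence in (0, 1]. Default 0.1.
#' @param max_itemset_size cap on mined itemset size (`Inf` = unbounded);
#'   exceeding it truncates the search with a warning.
#' @return a list of class `mining_config`.
#' @export
mining_config <- function(min_support = 0.0001, min_confidence = 0.1,
                          max_itemset_size = Inf) {
  stopifnot(min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1,
            max_itemset_size >= 1)
  structure(list(min_support = min_support, min_confidence = min_confidence,
                 max_itemset_size = max_itemset_size),
            class = "mining_config")
}

# Normalise a transaction_set / plain list of character vectors to a common
# shape: list of item vectors, N (denominator), n_diabetic (NA if unknown).
as_txn_list <- function(ts) {
  if (inherits(ts, "transaction_set")) {
    list(txns = transaction_items(ts), n = ts$n_patients,
         n_diabetic = ts$n_diabetic)
  } else if (is.list(ts)) {
    list(txns = lapply(ts, function(x) unique(as.character(x))),
         n = length(ts), n_diabetic = NA_integer_)
  } else {
    stop("ts must be a transaction_set or a list of item vectors",
         call. = FALSE)
  }
}

support_count_threshold <- function(min_support, n) {
  max(1L, as.integer(ceiling(min_support * n - 1e-9)))
}

#' Frequent single items
#'
#' Counts item frequencies over the transactions and keeps items whose
#' support count reaches `ceiling(min_support * N)`, ordered by descending
#' count with lexicographic tie-break — the insertion order of the FP-tree.
#'
#' @param ts a [build_transactions()] result or a list of character vectors.
#' @param cfg a [mining_config()].
#' @return `data.table(item, count)` in FP-tree insertion order.
#' @export
find_frequent_items <- function(ts, cfg = mining_config()) {
  tl <- as_txn_list(ts)
  if (tl$n == 0L || length(tl$txns) == 0L) {
    return(data.table(item = character(0), count = integer(0)))
  }
  counts <- table(unlist(tl$txns, use.names = FALSE))
  minct <- support_count_threshold(cfg$min_support, tl$n)
  counts <- counts[counts >= minct]
  dt <- data.table(item = names(counts), count = as.integer(counts))
  setorder(dt, -count, item)
  dt[]
}

# --- FP-tree ---------------------------------------------------------------

new_fp_node <- function(item, parent) {
  node <- new.env(parent = emptyenv())
  node$item <- item
  node$count <- 0
  node$parent <- parent
  node$children <- new.env(parent = emptyenv())
  node
}

#' Build an FP-tree
#'
#' Each transaction is filtered to the frequent items, sorted by the global
#' insertion order, and inserted as a root-to-leaf path with counts
#' incremented along the way; identical filtered transactions are collapsed
#' first and inserted with their multiplicity. A header table links every
#' node of each item so its support count equals the sum over its node
#' chain.
#'
#' @param ts transactions (as in [find_frequent_items()]).
#' @param freq_items `data.table(item, count)` from [find_frequent_items()];
#'   its row order is the insertion order.
#' @return an object of class `fp_tree` with components `root`, `header`
#'   (item -> list of nodes) and `items` (the insertion-order table).
#' @export
build_fp_tree <- function(ts, freq_items) {
  tl <- as_txn_list(ts)
  rank <- stats::setNames(seq_len(nrow(freq_items)), freq_items$item)
  root <- new_fp_node(NA_character_, NULL)
  header <- new.env(parent = emptyenv())
  # collapse identical filtered transactions
  keys <- vapply(tl$txns, function(items) {
    r <- rank[items[items %in% names(rank)]]
    if (length(r) == 0L) return("")
    paste(names(sort(r)), collapse = "\x1f")
  }, character(1))
  keys <- keys[keys != ""]
  if (length(keys)) {
    tab <- table(keys)
    for (i in seq_along(tab)) {
      path <- strsplit(names(tab)[i], "\x1f", fixed = TRUE)[[1]]
      insert_path(root, header, path, as.numeric(tab[i]))
    }
  }
  structure(list(root = root, header = header, items = freq_items),
            class = "fp_tree")
}

insert_path <- function(root, header, path, weight) {
  node <- root
  for (it in path) {
    child <- node$children[[it]]
    if (is.null(child)) {
      child <- new_fp_node(it, node)
      node$children[[it]] <- child
      header[[it]] <- c(header[[it]], child)
    }
    child$count <- child$count + weight
    node <- child
  }
  invisible(root)
}

# prefix path from a node's parent up to (excluding) the root
node_prefix <- function(node) {
  path <- character(0)
  p <- node$parent
  while (!is.null(p) && !is.na(p$item)) {
    path <- c(p$item, path)
    p <- p$parent
  }
  path
}

#' Mine frequent itemsets with FP-Growth
#'
#' Finds frequent items, builds the FP-tree, and recursively mines
#' conditional pattern bases / conditional FP-trees. The output is the
#' complete set of itemsets with support count at or above
#' `ceiling(min_support * N)`, without duplicates.
#'
#' @inheritParams find_frequent_items
#' @return `data.table(itemset, items, size, support_count, support)` where
#'   `itemset` is the comma-joined lexicographically sorted key and `items` a
#'   list-column of character vectors.
#' @export
mine_frequent_itemsets <- function(ts, cfg = mining_config()) {
  tl <- as_txn_list(ts)
  freq <- find_frequent_items(ts, cfg)
  acc <- new.env(parent = emptyenv())
  acc$items <- vector("list", 256L)
  acc$n <- 0L
  acc$truncated <- FALSE
  if (nrow(freq) > 0L) {
    minct <- support_count_threshold(cfg$min_support, tl$n)
    tree <- build_fp_tree(ts, freq)
    mine_tree(tree, minct, cfg$max_itemset_size, character(0), acc)
  }
  if (acc$truncated) {
    warning("itemset search truncated at max_itemset_size = ",
            cfg$max_itemset_size, call. = FALSE)
  }
  finalize_itemsets(acc, tl$n)
}

emit_itemset <- function(acc, items, count) {
  if (acc$n == length(acc$items)) {
    acc$items <- c(acc$items, vector("list", length(acc$items)))
  }
  acc$n <- acc$n + 1L
  acc$items[[acc$n]] <- list(items = items, count = count)
}

mine_tree <- function(tree, minct, max_size, suffix, acc) {
  freq <- tree$items
  if (nrow(freq) == 0L) return(invisible(NULL))
  # least-frequent first (bottom of the insertion order)
  for (i in rev(seq_len(nrow(freq)))) {
    it <- freq$item[i]
    nodes <- tree$header[[it]]
    support <- sum(vapply(nodes, function(nd) nd$count, numeric(1)))
    itemset <- c(it, suffix)
    emit_itemset(acc, itemset, support)
    if (length(itemset) >= max_size) {
      if (nrow(freq) > 1L) acc$truncated <- TRUE
      next
    }
    # conditional pattern base for `it`
    base_paths <- list()
    base_wts <- numeric(0)
    for (nd in nodes) {
      pre <- node_prefix(nd)
      if (length(pre)) {
        base_paths[[length(base_paths) + 1L]] <- pre
        base_wts <- c(base_wts, nd$count)
      }
    }
    if (!length(base_paths)) next
    cond <- conditional_tree(base_paths, base_wts, minct)
    if (!is.null(cond)) mine_tree(cond, minct, max_size, itemset, acc)
  }
  invisible(NULL)
}

# build a conditional FP-tree from a weighted pattern base
conditional_tree <- function(paths, weights, minct) {
  cnt <- new.env(parent = emptyenv())
  for (i in seq_along(paths)) {
    for (it in paths[[i]]) {
      cnt[[it]] <- (if (is.null(cnt[[it]])) 0 else cnt[[it]]) + weights[i]
    }
  }
  items <- ls(cnt)
  counts <- vapply(items, function(it) cnt[[it]], numeric(1))
  keep <- counts >= minct
  if (!any(keep)) return(NULL)
  freq <- data.table(item = items[keep], count = as.integer(counts[keep]))
  setorder(freq, -count, item)
  rank <- stats::setNames(seq_len(nrow(freq)), freq$item)
  root <- new_fp_node(NA_character_, NULL)
  header <- new.env(parent = emptyenv())
  for (i in seq_along(paths)) {
    p <- paths[[i]][paths[[i]] %in% freq$item]
    if (length(p)) insert_path(root, header, p[order(rank[p])], weights[i])
  }
  structure(list(root = root, header = header, items = freq),
            class = "fp_tree")
}

finalize_itemsets <- function(acc, n) {
  if (acc$n == 0L) {
    return(data.table(itemset = character(0), items = list(), size = integer(0),
                      support_count = integer(0), support = numeric(0)))
  }
  lst <- acc$items[seq_len(acc$n)]
  items <- lapply(lst, function(x) sort(x$items))
  dt <- data.table(
    itemset = vapply(items, paste, character(1), collapse = ","),
    items = items,
    size = lengths(items),
    support_count = as.integer(vapply(lst, function(x) x$count, numeric(1)))
  )
  dt[, support := support_count / n]
  setorder(dt, size, itemset)
  dt[]
}

#' Exhaustive frequent-itemset enumeration (test oracle)
#'
#' Counts the support of every subset of the frequent single items by a
#' direct scan of the transactions. Downward closure guarantees this
#' candidate space contains all frequent itemsets. Used as the independent
#' reference answer for the FP-Growth miner; the item count is capped to
#' guard the exponential cost.
#'
#' @inheritParams find_frequent_items
#' @param max_items refuse to enumerate more than this many frequent items.
#' @return same layout as [mine_frequent_itemsets()].
#' @export
brute_force_itemsets <- function(ts, cfg = mining_config(), max_items = 20L) {
  tl <- as_txn_list(ts)
  freq <- find_frequent_items(ts, cfg)
  k <- nrow(freq)
  if (k > max_items) {
    stop("brute-force enumeration refused: ", k, " frequent items > ",
         max_items, call. = FALSE)
  }
  acc <- new.env(parent = emptyenv())
  acc$items <- vector("list", 256L)
  acc$n <- 0L
  if (k > 0L) {
    minct <- support_count_threshold(cfg$min_support, tl$n)
    items <- sort(freq$item)
    M <- vapply(items, function(it) {
      vapply(tl$txns, function(tx) it %in% tx, logical(1))
    }, logical(length(tl$txns)))
    M <- matrix(M, nrow = length(tl$txns), ncol = k)
    for (size in seq_len(min(k, cfg$max_itemset_size))) {
      idx <- utils::combn(k, size)
      for (j in seq_len(ncol(idx))) {
        sel <- idx[, j]
        count <- sum(rowSums(M[, sel, drop = FALSE]) == size)
        if (count >= minct) emit_itemset(acc, items[sel], count)
      }
    }
  }
  finalize_itemsets(acc, tl$n)
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset of size two or more and every item `b` in it,
#' emits the single-consequent rule `S \ {b} -> b` when its confidence
#' reaches `min_confidence`. All metrics derive from the exact integer
#' support counts: `support = count(S)/N`,
#' `confidence = count(S)/count(S \ {b})`,
#' `lift = confidence / (count({b})/N)`. When the transaction set carries a
#' diabetic count, the prevalence indicator `count(S)/n_diabetic` is
#' attached (see [compute_prevalence()]).
#'
#' @param itemsets output of [mine_frequent_itemsets()].
#' @param ts the transaction set the itemsets were mined from.
#' @param cfg a [mining_config()].
#' @return `data.table(antecedent, consequent, joint_count, support,
#'   confidence, lift, prevalence)`; `antecedent` is the comma-joined sorted
#'   key of the left-hand-side items.
#' @export
generate_rules <- function(itemsets, ts, cfg = mining_config()) {
  tl <- as_txn_list(ts)
  empty <- data.table(antecedent = character(0), consequent = character(0),
                      joint_count = integer(0), support = numeric(0),
                      confidence = numeric(0), lift = numeric(0),
                      prevalence = numeric(0))
  multi <- itemsets[itemsets$size >= 2L, ]
  if (nrow(multi) == 0L) return(empty)
  lookup <- stats::setNames(itemsets$support_count, itemsets$itemset)
  idx <- rep(seq_len(nrow(multi)), multi$size)
  consequent <- unlist(multi$items, use.names = FALSE)
  ante_key <- unlist(lapply(multi$items, function(it) {
    vapply(seq_along(it), function(j) paste(it[-j], collapse = ","),
           character(1))
  }), use.names = FALSE)
  cnt <- multi$support_count[idx]
  conf <- cnt / unname(lookup[ante_key])
  keep <- conf >= cfg$min_confidence
  if (!any(keep)) return(empty)
  out <- data.table(
    antecedent = ante_key[keep],
    consequent = consequent[keep],
    joint_count = cnt[keep],
    support = cnt[keep] / tl$n,
    confidence = conf[keep],
    lift = conf[keep] / (unname(lookup[consequent[keep]]) / tl$n)
  )
  out[, prevalence := if (!is.na(tl$n_diabetic) && tl$n_diabetic > 0L) {
    joint_count / tl$n_diabetic
  } else NA_real_]
  setorder(out, antecedent, consequent)
  out[]
}

#' Diabetic prevalence of a rule's co-prescription
#'
#' The prevalence indicator is the joint rule count divided by the number of
#' diabetic patients in the transaction set: the fraction of diabetics who
#' were co-prescribed the rule's drugs. It is recoverable from the support as
#' `support * n_patients / n_diabetic`.
#'
#' @param rules rule table from [generate_rules()].
#' @param ts the transaction set, carrying `n_diabetic > 0`.
#' @return the rule table with its `prevalence` column (re)computed.
#' @export
compute_prevalence <- function(rules, ts) {
  if (!inherits(ts, "transaction_set") || is.na(ts$n_diabetic) ||
      ts$n_diabetic <= 0L) {
    stop("prevalence undefined: transaction set has no diabetic patients",
         call. = FALSE)
  }
  rules <- copy(as.data.table(rules))
  rules[, prevalence := joint_count / ts$n_diabetic]
  rules[]
}

#' Mine association rules end to end
#'
#' Convenience wrapper chaining [find_frequent_items()], [build_fp_tree()],
#' [mine_frequent_itemsets()] and [generate_rules()].
#'
#' @inheritParams find_frequent_items
#' @return `list(itemsets = ..., rules = ...)`.
#' @export
mine_rules <- function(ts, cfg = mining_config()) {
  itemsets <- mine_frequent_itemsets(ts, cfg)
  list(itemsets = itemsets, rules = generate_rules(itemsets, ts, cfg))
}
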