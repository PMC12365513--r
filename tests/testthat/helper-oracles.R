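# Independent oracles used across the suite. Each one re-derives its
# answer from first principles (ordered predicate lists, exhaustive subset
# enumeration, full linear scans) without touching the indexed/levelwise
# code paths it checks.

# ordered predicate semantics of the seven relations; first match wins
oracle_allen <- function(a1, a2, b1, b2, eps = 0, gap = Inf) {
  eq <- function(x, y) abs(x - y) <= eps
  lt <- function(x, y) !eq(x, y) && x < y
  if (eq(a1, b1) && eq(a2, b2)) return("e")
  if (eq(a1, b1) && lt(a2, b2)) return("s")
  if (eq(a2, b2) && lt(a1, b1)) return("f")
  if (lt(a1, b1) && lt(b2, a2)) return("c")
  if (eq(a2, b1)) return("m")
  if (lt(a1, b1) && lt(b1, a2) && lt(a2, b2)) return("o")
  if (lt(a2, b1)) {
    if (b1 - a2 <= gap) return("b") else return("unrelated")
  }
  NA_character_
}

# exhaustive subset-enumeration miner: every lexicographic STI subset of
# every transaction, thresholded on distinct-transaction counts.
# Returns a tibble keyed by (pattern, relations) with vs, mhs and the
# per-transaction HS table.
oracle_mine <- function(stis, min_count, max_gap, epsilon = 0, max_size = 4) {
  stis <- dplyr::arrange(stis, entity_id, start, end, symbol)
  txns <- split(stis, factor(stis$entity_id, levels = unique(stis$entity_id)))
  acc <- new.env(parent = emptyenv())
  for (tid in names(txns)) {
    txn <- txns[[tid]]
    n <- nrow(txn)
    for (k in seq_len(min(max_size, n))) {
      subsets <- utils::combn(n, k, simplify = FALSE)
      for (ix in subsets) {
        rel <- tirpscope:::relations_from_stis(txn$start[ix], txn$end[ix],
                                               epsilon, max_gap)
        if (any(rel == "unrelated")) next
        key <- paste(paste(txn$symbol[ix], collapse = " "),
                     paste(rel, collapse = ""), sep = "|")
        cur <- if (is.null(acc[[key]])) list() else acc[[key]]
        cur[[tid]] <- (if (is.null(cur[[tid]])) 0L else cur[[tid]]) + 1L
        acc[[key]] <- cur
      }
    }
  }
  keys <- ls(acc)
  rows <- lapply(keys, function(key) {
    hs <- unlist(acc[[key]])
    if (length(hs) < min_count) return(NULL)
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    tibble::tibble(pattern = parts[1],
                   relations = if (length(parts) > 1) parts[2] else "",
                   vs = length(hs), mhs = mean(hs),
                   hs_table = list(sort(paste0(names(hs), ":", hs))))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) out else dplyr::arrange(out, pattern, relations)
}

# the same summary table from a mined tirp_tree, for comparison
tree_pattern_table <- function(tree) {
  nodes <- tree$nodes
  hs_tables <- lapply(nodes$instances, function(inst) {
    hs <- inst |>
      dplyr::summarise(n = dplyr::n_distinct(instance), .by = "entity_id")
    sort(paste0(hs$entity_id, ":", hs$n))
  })
  tibble::tibble(
    pattern = vapply(nodes$symbols, paste, character(1), collapse = " "),
    relations = vapply(nodes$relations, paste, character(1), collapse = ""),
    vs = nodes$vs, mhs = nodes$mhs, hs_table = hs_tables
  ) |>
    dplyr::arrange(pattern, relations)
}

# "node@position" keys for a lookup result (empty-safe: paste0 would
# recycle zero-length vectors against the literal)
row_keys <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(unique(paste0(df$node, "@", df$position)))
}

# index-free lookup: full linear scan of every node
scan_lookup <- function(tree, seq, direction) {
  m <- length(seq$symbols)
  out <- character(0)
  for (r in seq_len(nrow(tree$nodes))) {
    sym <- tree$nodes$symbols[[r]]
    rel <- tree$nodes$relations[[r]]
    ps <- matches_consecutively(sym, rel, seq)
    ps <- if (direction == "later") ps[ps + m - 1L < length(sym)]
          else ps[ps > 1L]
    for (p in ps) {
      q <- if (direction == "later") p + m else p - 1L
      out <- c(out, paste0(tree$nodes$id[r], "@", q))
    }
  }
  sort(unique(out))
}

# every distinct size-1..3 consecutive (symbols, relations) window
# occurring in a tree's nodes
all_windows <- function(tree, max_len = 3L) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (r in seq_len(nrow(tree$nodes))) {
    sym <- tree$nodes$symbols[[r]]
    rel <- tree$nodes$relations[[r]]
    k <- length(sym)
    for (m in seq_len(min(max_len, k))) {
      for (p in seq_len(k - m + 1L)) {
        pos <- p:(p + m - 1L)
        sub <- if (m > 1L) tirpscope:::rel_submatrix(rel, pos) else character(0)
        key <- paste(paste(sym[pos], collapse = "\x1f"),
                     paste(sub, collapse = ""), sep = "|")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out[[length(out) + 1L]] <- fixed_sequence(sym[pos], sub)
        }
      }
    }
  }
  out
}

# random STI database for miner-oracle comparisons; occasional
# zero-duration point events and gaps beyond max_gap included on purpose
random_sti_db <- function(n_txn = 5, max_stis = 10, n_symbols = 5,
                          horizon = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alphabet <- LETTERS[seq_len(n_symbols)]
  rows <- lapply(seq_len(n_txn), function(i) {
    k <- sample(3:max_stis, 1)
    st <- round(runif(k, 0, horizon), 1)
    du <- ifelse(runif(k) < 0.2, 0, round(runif(k, 0.5, 8), 1))
    tibble::tibble(entity_id = sprintf("t%02d", i),
                   symbol = sample(alphabet, k, replace = TRUE),
                   start = st, end = st + du)
  })
  dplyr::bind_rows(rows)
}
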