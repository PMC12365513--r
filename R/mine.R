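# Correctness-first, instance-driven levelwise TIRP miner. Candidate
# relations are read off actual supporting STIs rather than derived from a
# transitivity table, so every extension is realised by construction.

check_sti_frame <- function(data) {
  need <- c("entity_id", "symbol", "start", "end")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    rlang::abort(paste("STI data lacks column(s):", paste(miss, collapse = ", ")),
                 class = "tirpscope_format_error")
  }
  if (any(data$start > data$end)) {
    rlang::abort("STI rows with start > end", class = "tirpscope_format_error")
  }
  invisible(data)
}

# split an STI tibble into per-transaction lists of parallel vectors
split_transactions <- function(data) {
  data <- arrange_stis(check_sti_frame(data))
  ids <- as.character(data$entity_id)
  lapply(split(seq_len(nrow(data)), factor(ids, levels = unique(ids))),
         function(ix) list(symbol = as.character(data$symbol[ix]),
                           start = as.numeric(data$start[ix]),
                           end = as.numeric(data$end[ix])))
}

#' Find all instances of a TIRP in one transaction
#'
#' Enumerates every lexicographically ordered selection of the
#' transaction's STIs that realises the TIRP — matching symbols
#' positionally and every pairwise Allen relation exactly. The number of
#' instances returned is the TIRP's horizontal support (HS) in the
#' transaction.
#'
#' @param stis A data frame of one transaction's STIs with columns
#'   `symbol`, `start`, `end` (any order; sorted internally).
#' @param symbols The TIRP's symbol sequence.
#' @param relations Flat upper-triangular relation vector (column order).
#' @inheritParams allen_relation
#' @return A tibble with columns `instance`, `position`, `symbol`,
#'   `start`, `end`; `dplyr::n_distinct(instance)` is the HS.
#' @export
#' @examples
#' txn <- tibble::tibble(symbol = c("A", "A", "B", "B"),
#'                       start = c(1, 10, 3, 12), end = c(2, 11, 4, 13))
#' find_instances(txn, c("A", "B"), "b", max_gap = 20)
find_instances <- function(stis, symbols, relations, epsilon = 0,
                           max_gap = Inf) {
  ord <- order(stis$start, stis$end, stis$symbol)
  txn <- list(symbol = as.character(stis$symbol[ord]),
              start = as.numeric(stis$start[ord]),
              end = as.numeric(stis$end[ord]))
  hits <- match_positions(txn, symbols, relations, epsilon, max_gap)
  k <- length(symbols)
  if (!length(hits)) {
    return(tibble::tibble(instance = integer(0), position = integer(0),
                          symbol = character(0), start = numeric(0),
                          end = numeric(0)))
  }
  pos <- unlist(hits)
  tibble::tibble(
    instance = rep(seq_along(hits), each = k),
    position = rep(seq_len(k), times = length(hits)),
    symbol = txn$symbol[pos],
    start = txn$start[pos],
    end = txn$end[pos]
  )
}

# depth-first enumeration of all position vectors realising (symbols,
# relations) in one transaction; returns list of integer vectors
match_positions <- function(txn, symbols, relations, epsilon, max_gap) {
  k <- length(symbols)
  n <- length(txn$symbol)
  out <- list()
  recurse <- function(pos) {
    d <- length(pos)
    if (d == k) {
      out[[length(out) + 1L]] <<- pos
      return(invisible(NULL))
    }
    from <- if (d == 0L) 1L else pos[d] + 1L
    if (from > n) return(invisible(NULL))
    for (e in from:n) {
      if (txn$symbol[e] != symbols[d + 1L]) next
      ok <- TRUE
      for (i in seq_len(d)) {
        r <- allen_relation(txn$start[pos[i]], txn$end[pos[i]],
                            txn$start[e], txn$end[e],
                            epsilon = epsilon, max_gap = max_gap)
        if (r != relations[[rel_index(i, d + 1L)]]) { ok <- FALSE; break }
      }
      if (ok) recurse(c(pos, e))
    }
    invisible(NULL)
  }
  recurse(integer(0))
  out
}

# VS / MHS / MMD from a per-node instance table
#' Pattern metrics from an instance table
#'
#' Computes the support metrics attached to every pattern: vertical
#' support (VS, the number of distinct supporting transactions), relative
#' VS, mean horizontal support (MHS, the mean over supporting transactions
#' of the per-transaction instance count) and mean mean duration (MMD, the
#' mean over supporting transactions of the per-transaction mean instance
#' duration, an instance's duration being its latest STI end minus its
#' earliest STI start). Both means weight transactions equally.
#'
#' @param instances A tibble with columns `entity_id`, `instance`,
#'   `start`, `end` (one row per STI of each instance), e.g. several
#'   [find_instances()] results bound together with an `entity_id` column.
#' @param n_transactions Total number of transactions in the database, for
#'   relative support.
#' @return A one-row tibble: `vs`, `relative_vs`, `mhs`, `mmd`.
#' @export
tirp_metrics <- function(instances, n_transactions) {
  if (nrow(instances) == 0L) {
    rlang::abort("metrics are undefined for an unsupported pattern",
                 class = "tirpscope_metrics_error")
  }
  per_txn <- instances |>
    dplyr::summarise(duration = max(.data$end) - min(.data$start),
                     .by = c("entity_id", "instance")) |>
    dplyr::summarise(hs = dplyr::n(), md = mean(.data$duration),
                     .by = "entity_id")
  tibble::tibble(
    vs = nrow(per_txn),
    relative_vs = nrow(per_txn) / n_transactions,
    mhs = mean(per_txn$hs),
    mmd = mean(per_txn$md)
  )
}

#' Mine the enumeration tree of frequent TIRPs
#'
#' Levelwise discovery of every frequent time-interval-related pattern in
#' an STI database. Level 1 holds every symbol supported by at least
#' `min_vs` transactions; a size-`k` node is extended by appending, for
#' every supporting instance, each STI lexicographically after the
#' instance's last STI, reading the new Allen-relation column off the
#' actual intervals. Candidates whose new column contains a pair further
#' apart than `max_gap` are discarded; the surviving candidates are
#' grouped by (symbol, relation column) and kept when their distinct
#' supporting-transaction count reaches `min_vs`. Every frequent pattern
#' appears exactly once, under its unique size-`k-1` prefix.
#'
#' @param data STI database: a data frame with columns `entity_id`,
#'   `symbol`, `start`, `end`.
#' @param min_vs Minimal vertical support: values below 1 are read as a
#'   fraction of the transaction count (converted once with ceiling),
#'   values of 1 or more as an absolute transaction count.
#' @param max_gap Maximal gap for the before relation (time units).
#' @param epsilon Endpoint equality tolerance. Default 0.
#' @param max_size Optional cap on pattern size. Default `Inf`.
#' @param keep_instances Keep each node's instance table (needed for
#'   timeline layouts; drop to save memory). Supporting transaction ids
#'   are always retained.
#' @return A `tirp_tree`.
#' @export
#' @examples
#' db <- tibble::tibble(
#'   entity_id = rep(c("p1", "p2", "p3"), each = 2),
#'   symbol = rep(c("A", "B"), 3),
#'   start = rep(c(1, 5), 3), end = rep(c(3, 7), 3)
#' )
#' mine_tirps(db, min_vs = 2, max_gap = 20)
mine_tirps <- function(data, min_vs, max_gap, epsilon = 0, max_size = Inf,
                       keep_instances = TRUE) {
  if (min_vs <= 0 || max_gap <= 0 || epsilon < 0 || max_size < 1) {
    rlang::abort("invalid mining configuration",
                 class = "tirpscope_config_error")
  }
  txns <- split_transactions(data)
  n_txn <- length(txns)
  threshold <- if (min_vs < 1) as.integer(ceiling(min_vs * n_txn))
               else as.integer(min_vs)
  config <- list(min_vs = min_vs, threshold = threshold, max_gap = max_gap,
                 epsilon = epsilon, max_size = max_size)
  alphabet <- sort(unique(as.character(data$symbol)))
  if (n_txn == 0L) {
    return(new_tirp_tree(empty_nodes(), alphabet, 0L, config))
  }
  if (threshold > n_txn) {
    rlang::warn("min_vs exceeds the number of transactions; empty tree")
    return(new_tirp_tree(empty_nodes(), alphabet, n_txn, config))
  }

  txn_ids <- names(txns)
  # working node store: list of lists with fields symbols, relations,
  # parent, inst (list of list(txn = int, pos = int vector))
  work <- list()

  # ---- level 1 ----
  for (sym in alphabet) {
    inst <- list()
    for (t in seq_len(n_txn)) {
      hits <- which(txns[[t]]$symbol == sym)
      for (e in hits) inst[[length(inst) + 1L]] <- list(txn = t, pos = e)
    }
    n_support <- length(unique(vapply(inst, `[[`, integer(1), "txn")))
    if (n_support >= threshold) {
      work[[length(work) + 1L]] <-
        list(symbols = sym, relations = character(0), parent = NA_character_,
             inst = inst)
    }
  }

  # ---- levelwise extension ----
  frontier <- seq_along(work)
  while (length(frontier)) {
    next_frontier <- integer(0)
    for (idx in frontier) {
      node <- work[[idx]]
      k <- length(node$symbols)
      if (k >= max_size) next
      groups <- list() # key -> list(sym, col, inst = list)
      for (ins in node$inst) {
        txn <- txns[[ins$txn]]
        last <- ins$pos[k]
        n_sti <- length(txn$symbol)
        if (last >= n_sti) next
        for (e in (last + 1L):n_sti) {
          col <- allen_relation(txn$start[ins$pos], txn$end[ins$pos],
                                txn$start[e], txn$end[e],
                                epsilon = epsilon, max_gap = max_gap)
          if (any(col == "unrelated")) next
          key <- paste0(txn$symbol[e], "\x1f", paste(col, collapse = ""))
          if (is.null(groups[[key]])) {
            groups[[key]] <- list(sym = txn$symbol[e], col = col, inst = list())
          }
          groups[[key]]$inst[[length(groups[[key]]$inst) + 1L]] <-
            list(txn = ins$txn, pos = c(ins$pos, e))
        }
      }
      if (!length(groups)) next
      ord <- order(vapply(groups, `[[`, character(1), "sym"),
                   vapply(groups, function(g) paste(g$col, collapse = ""),
                          character(1)))
      for (g in groups[ord]) {
        n_support <- length(unique(vapply(g$inst, `[[`, integer(1), "txn")))
        if (n_support < threshold) next
        work[[length(work) + 1L]] <- list(
          symbols = c(node$symbols, g$sym),
          relations = c(node$relations, g$col),
          parent = idx,
          inst = g$inst
        )
        next_frontier <- c(next_frontier, length(work))
      }
    }
    frontier <- next_frontier
  }

  # ---- materialise nodes ----
  n_nodes <- length(work)
  ids <- paste0("T", seq_len(n_nodes))
  rows <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    node <- work[[i]]
    k <- length(node$symbols)
    inst_tbl <- instances_to_tibble(node$inst, txns, txn_ids, k)
    m <- tirp_metrics(inst_tbl, n_txn)
    rows[[i]] <- tibble::tibble(
      id = ids[i],
      parent = if (is.na(node$parent[1]) || !is.numeric(node$parent))
        NA_character_ else ids[node$parent],
      size = k,
      symbols = list(node$symbols),
      relations = list(node$relations),
      vs = m$vs, relative_vs = m$relative_vs, mhs = m$mhs, mmd = m$mmd,
      support = list(unique(inst_tbl$entity_id)),
      instances = list(if (keep_instances) inst_tbl else NULL)
    )
  }
  nodes <- if (n_nodes) dplyr::bind_rows(rows) else empty_nodes()
  new_tirp_tree(nodes, alphabet, n_txn, config)
}

instances_to_tibble <- function(inst, txns, txn_ids, k) {
  n <- length(inst)
  ent <- character(n * k); instance <- integer(n * k)
  position <- integer(n * k); st <- numeric(n * k); en <- numeric(n * k)
  sym <- character(n * k)
  row <- 0L
  for (j in seq_len(n)) {
    txn <- txns[[inst[[j]]$txn]]
    pos <- inst[[j]]$pos
    ix <- row + seq_len(k)
    ent[ix] <- txn_ids[inst[[j]]$txn]
    instance[ix] <- j
    position[ix] <- seq_len(k)
    sym[ix] <- txn$symbol[pos]
    st[ix] <- txn$start[pos]
    en[ix] <- txn$end[pos]
    row <- row + k
  }
  tibble::tibble(entity_id = ent, instance = instance, position = position,
                 symbol = sym, start = st, end = en)
}
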