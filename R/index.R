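# Bidirectional pair index over an enumeration tree: two nested hash maps
# keyed by ordered symbol pairs, listing every TIRP in which the pair
# occurs at consecutive positions, with the relation between them. The
# forward map is keyed (earlier symbol, later symbol), the backward map
# (later symbol, earlier symbol); both hold the same entries.

KEY_SEP <- "\x1f"

#' Build forward and backward pair indices
#'
#' Single pass over all tree nodes: for each TIRP and each consecutive
#' position pair `(i, i + 1)` an entry `(node, position = i, relation =
#' r(i, i + 1))` is appended to the forward bucket keyed by
#' `(symbol_i, symbol_{i+1})` and to the backward bucket keyed by
#' `(symbol_{i+1}, symbol_i)`. The work is proportional to the total
#' number of consecutive pairs, `sum(size - 1)` over nodes, bounded by
#' `N * (Lmax - 1)`; bucket count is bounded by the squared alphabet size.
#'
#' @param tree A `tirp_tree`.
#' @return A `tirp_index` holding the shared entry table plus the two
#'   nested maps; operation counters are attached for complexity
#'   diagnostics (`$ops$nodes_visited`, `$ops$entries_appended`).
#' @export
build_tirp_index <- function(tree) {
  nodes <- tree$nodes
  n_pairs_per_node <- pmax(nodes$size - 1L, 0L)
  total <- sum(n_pairs_per_node)
  if (total == 0L) {
    entries <- tibble::tibble(first = character(0), second = character(0),
                              node = character(0), position = integer(0),
                              relation = character(0))
  } else {
    node_id <- rep(nodes$id, times = n_pairs_per_node)
    position <- unlist(lapply(n_pairs_per_node, seq_len), use.names = FALSE)
    firsts <- unlist(lapply(nodes$symbols, function(s) s[-length(s)]),
                     use.names = FALSE)
    seconds <- unlist(lapply(nodes$symbols, function(s) s[-1]),
                      use.names = FALSE)
    rels <- unlist(
      purrr::map2(nodes$relations, nodes$size, function(r, k) {
        if (k < 2L) character(0)
        else vapply(seq_len(k - 1L), function(i) r[[rel_index(i, i + 1L)]],
                    character(1))
      }),
      use.names = FALSE
    )
    entries <- tibble::tibble(first = firsts, second = seconds,
                              node = node_id, position = position,
                              relation = rels)
  }
  rows <- seq_len(nrow(entries))
  split0 <- function(keys) if (length(rows)) split(rows, keys) else list()
  structure(
    list(
      entries = entries,
      forward = split0(paste0(entries$first, KEY_SEP, entries$second)),
      backward = split0(paste0(entries$second, KEY_SEP, entries$first)),
      by_first = split0(entries$first),
      by_second = split0(entries$second),
      ops = list(nodes_visited = nrow(nodes), entries_appended = nrow(entries))
    ),
    class = "tirp_index"
  )
}

#' @export
print.tirp_index <- function(x, ...) {
  cat(sprintf("<tirp_index> %d pair entries, %d forward buckets\n",
              nrow(x$entries), length(x$forward)))
  invisible(x)
}

#' Tidy a pair index into its entry table
#' @param x A `tirp_index`.
#' @param ... Unused.
#' @return The entry tibble (`first`, `second`, `node`, `position`,
#'   `relation`).
#' @export
tidy.tirp_index <- function(x, ...) x$entries

#' Inspect one index bucket
#'
#' @param index A `tirp_index`.
#' @param direction `"forward"` (key order: earlier symbol, later symbol)
#'   or `"backward"` (later, earlier).
#' @param key1,key2 The two symbols, in the direction's key order.
#' @return The bucket's entries as a tibble (possibly empty).
#' @export
index_bucket <- function(index, direction = c("forward", "backward"),
                         key1, key2) {
  direction <- match.arg(direction)
  rows <- index[[direction]][[paste0(key1, KEY_SEP, key2)]]
  if (is.null(rows)) index$entries[0, ] else index$entries[rows, ]
}

#' Fixed STI sequence
#'
#' The exploration engine's unit of state: an ordered run of symbols plus
#' the complete upper-triangular relation sub-matrix among them, as fixed
#' by the user's selections.
#'
#' @param symbols Character vector, length `m >= 1`.
#' @param relations The `m (m - 1) / 2` relation codes in column order;
#'   a single string such as `"b"` or `"bbo"` is also accepted.
#' @param provenance Optional character vector of node ids the selections
#'   came from.
#' @return A `fixed_sequence` object.
#' @export
#' @examples
#' fixed_sequence(c("Fluids.Low", "Fall.Event"), "b")
fixed_sequence <- function(symbols, relations = character(0),
                           provenance = character(0)) {
  if (length(relations) == 1L && nchar(relations[1]) > 1L) {
    relations <- strsplit(relations, "")[[1]]
  }
  m <- length(symbols)
  if (m < 1L) {
    rlang::abort("a fixed sequence needs at least one symbol",
                 class = "tirpscope_config_error")
  }
  if (length(relations) != (m * (m - 1L)) %/% 2L) {
    rlang::abort("relation vector length must be m(m-1)/2",
                 class = "tirpscope_config_error")
  }
  bad <- setdiff(relations, unname(temporal_relations()))
  if (length(bad)) {
    rlang::abort(paste("unknown relation code(s):", paste(bad, collapse = ", ")),
                 class = "tirpscope_config_error")
  }
  structure(list(symbols = as.character(symbols),
                 relations = as.character(relations),
                 provenance = provenance),
            class = "fixed_sequence")
}

#' @export
print.fixed_sequence <- function(x, ...) {
  cat("<fixed_sequence>", paste(x$symbols, collapse = " "),
      if (length(x$relations)) paste0("[", paste(x$relations, collapse = ""), "]"),
      "\n")
  invisible(x)
}

#' Positions at which a TIRP contains a fixed sequence consecutively
#'
#' Returns every start position `p` such that the TIRP's symbols at
#' `p .. p + m - 1` equal the sequence's symbols and the TIRP's relation
#' sub-matrix over those positions equals the sequence's relations.
#'
#' @param symbols,relations The TIRP's symbol sequence and flat relation
#'   vector.
#' @param seq A [fixed_sequence()].
#' @param match_relations If `FALSE`, only symbols are compared.
#' @return Integer vector of matching start positions (possibly empty).
#' @export
matches_consecutively <- function(symbols, relations, seq,
                                  match_relations = TRUE) {
  m <- length(seq$symbols)
  k <- length(symbols)
  if (m > k) return(integer(0))
  out <- integer(0)
  for (p in seq_len(k - m + 1L)) {
    if (!identical(symbols[p:(p + m - 1L)], seq$symbols)) next
    if (match_relations && m > 1L) {
      ok <- TRUE
      for (j in 2:m) {
        for (i in seq_len(j - 1L)) {
          if (relations[[rel_index(p + i - 1L, p + j - 1L)]] !=
              seq$relations[[rel_index(i, j)]]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) next
    }
    out <- c(out, p)
  }
  out
}

# gather candidate node ids from the index buckets for a sequence
candidate_nodes <- function(index, seq, direction) {
  m <- length(seq$symbols)
  if (m == 1L) {
    rows <- if (direction == "forward") index$by_first[[seq$symbols[1]]]
            else index$by_second[[seq$symbols[1]]]
    if (is.null(rows)) return(character(0))
    return(unique(index$entries$node[rows]))
  }
  # one bucket per consecutive pair, filtered by the fixed relation;
  # start from the rarest bucket and verification does the rest
  buckets <- lapply(seq_len(m - 1L), function(j) {
    rows <- index$forward[[paste0(seq$symbols[j], KEY_SEP, seq$symbols[j + 1L])]]
    if (is.null(rows)) return(integer(0))
    rel <- seq$relations[[rel_index(j, j + 1L)]]
    rows[index$entries$relation[rows] == rel]
  })
  sizes <- lengths(buckets)
  if (any(sizes == 0L)) return(character(0))
  unique(index$entries$node[buckets[[which.min(sizes)]]])
}

empty_rows <- function() {
  tibble::tibble(direction = character(0), symbol = character(0),
                 relation = character(0), node = character(0),
                 position = integer(0), size = integer(0),
                 size_label = character(0), match_pos = integer(0),
                 vs = integer(0), relative_vs = numeric(0),
                 mhs = numeric(0), mmd = numeric(0), selected = logical(0))
}

lookup_rows <- function(tree, index, seq, direction, center = NULL,
                        match_relations = TRUE) {
  m <- length(seq$symbols)
  if (is.null(center)) center <- if (direction == "later") m else 1L
  stopifnot(center >= 1L, center <= m)
  if (!all(seq$symbols %in% tree$alphabet)) {
    rlang::warn(paste("symbol(s) not in tree alphabet:",
                      paste(setdiff(seq$symbols, tree$alphabet), collapse = ", ")))
    return(empty_rows())
  }
  idx_dir <- if (direction == "later") "forward" else "backward"
  cand <- candidate_nodes(index, seq, idx_dir)
  if (!length(cand)) return(empty_rows())
  nodes <- tree$nodes[match(cand, tree$nodes$id), ]
  out <- list()
  for (r in seq_len(nrow(nodes))) {
    sym <- nodes$symbols[[r]]; rel <- nodes$relations[[r]]
    k <- nodes$size[r]
    ps <- matches_consecutively(sym, rel, seq, match_relations)
    ps <- if (direction == "later") ps[ps + m - 1L < k] else ps[ps > 1L]
    for (p in ps) {
      q <- if (direction == "later") p + m else p - 1L
      cpos <- p + center - 1L
      out[[length(out) + 1L]] <- tibble::tibble(
        direction = direction,
        symbol = sym[q],
        relation = rel[[rel_index(min(cpos, q), max(cpos, q))]],
        node = nodes$id[r],
        position = as.integer(q),
        size = k,
        size_label = paste0(q, "/", k),
        match_pos = as.integer(p),
        vs = nodes$vs[r], relative_vs = nodes$relative_vs[r],
        mhs = nodes$mhs[r], mmd = nodes$mmd[r],
        selected = FALSE
      )
    }
  }
  if (!length(out)) return(empty_rows())
  dplyr::bind_rows(out) |>
    dplyr::distinct(.data$node, .data$position, .keep_all = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$vs), .data$symbol, .data$node)
}

#' Forward (later-STI) extension lookup
#'
#' Finds every TIRP that contains the fixed sequence at consecutive
#' positions with at least one additional STI afterwards, via the pair
#' index: candidate nodes are gathered from the buckets of the sequence's
#' consecutive symbol pairs (rarest bucket first) and verified with
#' [matches_consecutively()]. One row is returned per (node, extending
#' position); `relation` is read between the center STI and the extending
#' STI off the node's full relation matrix.
#'
#' @param tree A `tirp_tree`.
#' @param index The [build_tirp_index()] result for `tree`.
#' @param seq A [fixed_sequence()] (a bare symbol string is promoted to a
#'   length-1 sequence).
#' @param center Center position within the sequence that `relation` is
#'   read against; defaults to the sequence end nearest the extension.
#' @param match_relations If `FALSE`, sequence matching compares symbols
#'   only.
#' @return A tibble of extension rows ordered by vertical support
#'   (descending), symbol, node id.
#' @export
forward_lookup <- function(tree, index, seq, center = NULL,
                           match_relations = TRUE) {
  if (is.character(seq)) seq <- fixed_sequence(seq)
  lookup_rows(tree, index, seq, "later", center, match_relations)
}

#' Backward (earlier-STI) extension lookup
#'
#' Mirror image of [forward_lookup()]: every TIRP containing the fixed
#' sequence consecutively with at least one additional STI beforehand; the
#' extending position is the one immediately before the match.
#'
#' @inheritParams forward_lookup
#' @return A tibble of extension rows.
#' @export
backward_lookup <- function(tree, index, seq, center = NULL,
                            match_relations = TRUE) {
  if (is.character(seq)) seq <- fixed_sequence(seq)
  lookup_rows(tree, index, seq, "earlier", center, match_relations)
}
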