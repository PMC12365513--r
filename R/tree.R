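#' @importFrom rlang .data
NULL

# Construct a tirp_tree object from its parts. `nodes` is a tibble with
# columns id, parent, size, symbols (list of chr), relations (list of chr,
# flat upper-triangular, column order), vs, relative_vs, mhs, mmd,
# support (list of chr entity ids) and optionally instances (list of
# tibbles: entity_id, instance, position, start, end).
new_tirp_tree <- function(nodes, alphabet, n_transactions, config = list()) {
  structure(
    list(nodes = nodes, alphabet = sort(unique(alphabet)),
         n_transactions = as.integer(n_transactions), config = config),
    class = "tirp_tree"
  )
}

empty_nodes <- function() {
  tibble::tibble(
    id = character(0), parent = character(0), size = integer(0),
    symbols = list(), relations = list(),
    vs = integer(0), relative_vs = numeric(0),
    mhs = numeric(0), mmd = numeric(0),
    support = list(), instances = list()
  )
}

#' Number of patterns in an enumeration tree
#' @param tree A `tirp_tree`.
#' @return Integer node count.
#' @export
n_patterns <- function(tree) nrow(tree$nodes)

#' Retrieve one node of an enumeration tree
#' @param tree A `tirp_tree`.
#' @param id Node identifier.
#' @return A one-row tibble (list-columns for symbols, relations, support,
#'   instances).
#' @export
tree_node <- function(tree, id) {
  row <- tree$nodes[tree$nodes$id == id, ]
  if (nrow(row) != 1L) {
    rlang::abort(sprintf("no node '%s' in tree", id),
                 class = "tirpscope_lookup_error")
  }
  row
}

#' @export
print.tirp_tree <- function(x, ...) {
  cat(sprintf(
    "<tirp_tree> %d frequent TIRPs over %d symbols (%d transactions), max size %s\n",
    nrow(x$nodes), length(x$alphabet), x$n_transactions,
    if (nrow(x$nodes)) max(x$nodes$size) else 0L
  ))
  invisible(x)
}

#' Validate enumeration-tree structure
#'
#' Checks the structural invariants every enumeration tree must satisfy:
#' unique ids, parents preceding children, each child's symbol sequence
#' equal to its parent's plus one appended symbol, each child's relation
#' vector extending its parent's by one column, triangular relation-vector
#' lengths, and anti-monotone vertical support along every edge.
#'
#' @param tree A `tirp_tree`.
#' @return `TRUE` invisibly; aborts with a descriptive error otherwise.
#' @export
validate_tree <- function(tree) {
  nodes <- tree$nodes
  fail <- function(msg) rlang::abort(msg, class = "tirpscope_tree_error")
  if (anyDuplicated(nodes$id)) fail("duplicate node ids")
  pos <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  for (r in seq_len(nrow(nodes))) {
    k <- nodes$size[r]
    if (length(nodes$symbols[[r]]) != k) fail("size does not match symbols")
    if (length(nodes$relations[[r]]) != (k * (k - 1L)) %/% 2L) {
      fail(sprintf("node %s: relation vector length is not k(k-1)/2",
                   nodes$id[r]))
    }
    p <- nodes$parent[r]
    if (is.na(p)) {
      if (k != 1L) fail(sprintf("root %s has size %d", nodes$id[r], k))
    } else {
      if (!p %in% names(pos)) fail(sprintf("missing parent '%s'", p))
      if (pos[[p]] >= r) fail("parent does not precede child")
      pr <- pos[[p]]
      if (nodes$size[pr] != k - 1L ||
          !identical(nodes$symbols[[pr]], nodes$symbols[[r]][-k])) {
        fail(sprintf("node %s is not a one-symbol extension of its parent",
                     nodes$id[r]))
      }
      np <- length(nodes$relations[[pr]])
      if (np > 0 &&
          !identical(nodes$relations[[pr]], nodes$relations[[r]][seq_len(np)])) {
        fail(sprintf("node %s: relations do not extend the parent's",
                     nodes$id[r]))
      }
      if (nodes$vs[r] > nodes$vs[pr]) {
        fail(sprintf("node %s: vertical support exceeds its parent's",
                     nodes$id[r]))
      }
    }
  }
  invisible(TRUE)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an enumeration tree into one row per pattern
#'
#' @param x A `tirp_tree`.
#' @param ... Unused.
#' @return A tibble with columns `id`, `parent`, `size`, `pattern` (a
#'   human-readable rendering), `relations` (the flat code string), `vs`,
#'   `relative_vs`, `mhs`, `mmd`.
#' @export
tidy.tirp_tree <- function(x, ...) {
  nodes <- x$nodes
  tibble::tibble(
    id = nodes$id,
    parent = nodes$parent,
    size = nodes$size,
    pattern = vapply(nodes$symbols, paste, character(1), collapse = " "),
    relations = vapply(nodes$relations, paste, character(1), collapse = ""),
    vs = nodes$vs,
    relative_vs = nodes$relative_vs,
    mhs = nodes$mhs,
    mmd = nodes$mmd
  )
}

#' One-row summary of an enumeration tree
#'
#' @param x A `tirp_tree`.
#' @param ... Unused.
#' @return A tibble with `n_patterns`, `max_size`, `n_symbols`,
#'   `n_transactions`.
#' @export
glance.tirp_tree <- function(x, ...) {
  tibble::tibble(
    n_patterns = nrow(x$nodes),
    max_size = if (nrow(x$nodes)) max(x$nodes$size) else 0L,
    n_symbols = length(x$alphabet),
    n_transactions = x$n_transactions
  )
}
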