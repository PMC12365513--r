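# Session semantics of associative exploration: a fixed STI sequence with
# its relation sub-matrix, a center position, and the two side panels of
# earlier/later extensions computed from the bidirectional index.

# contiguous-submatrix extraction, column order
rel_submatrix <- function(relations, positions) {
  m <- length(positions)
  if (m < 2L) return(character(0))
  unlist(lapply(2:m, function(j) {
    vapply(seq_len(j - 1L), function(i) {
      relations[[rel_index(positions[i], positions[j])]]
    }, character(1))
  }))
}

new_session <- function(tree, index, fixed, center, selected_node, anchor,
                        panels, row_limit, history = list()) {
  structure(
    list(tree = tree, index = index, fixed = fixed, center = center,
         selected_node = selected_node, anchor = anchor, panels = panels,
         row_limit = row_limit, history = history),
    class = "tirp_session"
  )
}

cap_rows <- function(rows, limit) {
  if (is.finite(limit) && nrow(rows) > limit) rows[seq_len(limit), ] else rows
}

#' Start an exploration session from a single STI
#'
#' The session begins by fixing one symbol of interest. The center block
#' shows the size-1 TIRP of that symbol; the later (right) and earlier
#' (left) panels list every extension found through the forward and
#' backward indices.
#'
#' @param tree A `tirp_tree`.
#' @param index The [build_tirp_index()] result for `tree`.
#' @param symbol A symbol that is a frequent size-1 pattern in the tree.
#' @param row_limit Optional cap on panel rows (after the deterministic
#'   ordering). Default unlimited.
#' @return A `tirp_session`.
#' @export
start_session <- function(tree, index, symbol, row_limit = Inf) {
  root <- tree$nodes[tree$nodes$size == 1L &
                       vapply(tree$nodes$symbols, `[[`, character(1), 1) == symbol, ]
  if (nrow(root) != 1L) {
    near <- utils::head(sort(tree$alphabet[startsWith(
      tolower(tree$alphabet), tolower(substr(symbol, 1, 3)))]), 5)
    rlang::abort(
      paste0("'", symbol, "' is not a frequent size-1 pattern in this tree",
             if (length(near)) paste0("; nearest symbols: ",
                                      paste(near, collapse = ", ")) else ""),
      class = "tirpscope_unknown_symbol_error"
    )
  }
  fixed <- fixed_sequence(symbol, provenance = root$id)
  panels <- list(
    earlier = cap_rows(backward_lookup(tree, index, fixed, center = 1L),
                       row_limit),
    later = cap_rows(forward_lookup(tree, index, fixed, center = 1L),
                     row_limit)
  )
  new_session(tree, index, fixed, center = 1L, selected_node = root$id,
              anchor = 1L, panels = panels, row_limit = row_limit)
}

#' Center-block summary of a session
#'
#' @param x A `tirp_session`.
#' @param ... Unused.
#' @return One-row tibble: the center symbol, the selected node's metrics
#'   and the size label `X/Y` where `Y` is the selected TIRP's size and
#'   `X` the center STI's position within it.
#' @export
glance.tirp_session <- function(x, ...) {
  node <- tree_node(x$tree, x$selected_node)
  xpos <- x$anchor + x$center - 1L
  tibble::tibble(
    center_symbol = x$fixed$symbols[x$center],
    selected_node = x$selected_node,
    vs = node$vs, relative_vs = node$relative_vs,
    mhs = node$mhs, mmd = node$mmd,
    size_label = paste0(xpos, "/", node$size)
  )
}

#' Panels of a session as one tibble
#' @param x A `tirp_session`.
#' @param ... Unused.
#' @return The earlier and later panel rows bound together.
#' @export
tidy.tirp_session <- function(x, ...) {
  dplyr::bind_rows(x$panels$earlier, x$panels$later)
}

#' @export
print.tirp_session <- function(x, ...) {
  cat("<tirp_session>\n  fixed:",
      paste(x$fixed$symbols, collapse = " "), "\n  center:",
      x$fixed$symbols[x$center], sprintf("(position %d of %d)", x$center,
                                         length(x$fixed$symbols)),
      "\n  selected TIRP:", x$selected_node,
      sprintf("\n  panels: %d earlier, %d later\n",
              nrow(x$panels$earlier), nrow(x$panels$later)))
  invisible(x)
}

# the single marked row a non-boundary side collapses to after a shift
fixed_neighbor_row <- function(session, direction) {
  offset <- if (direction == "earlier") -1L else 1L
  npos <- session$center + offset
  nd <- tree_node(session$tree, session$selected_node)
  cpos <- session$anchor + session$center - 1L
  qpos <- session$anchor + npos - 1L
  tibble::tibble(
    direction = direction,
    symbol = session$fixed$symbols[npos],
    relation = nd$relations[[1]][[rel_index(min(cpos, qpos), max(cpos, qpos))]],
    node = nd$id, position = qpos, size = nd$size,
    size_label = paste0(qpos, "/", nd$size),
    match_pos = session$anchor,
    vs = nd$vs, relative_vs = nd$relative_vs,
    mhs = nd$mhs, mmd = nd$mmd,
    selected = TRUE
  )
}

recompute_panel <- function(session, direction) {
  m <- length(session$fixed$symbols)
  boundary <- if (direction == "earlier") session$center == 1L
              else session$center == m
  if (!boundary) return(fixed_neighbor_row(session, direction))
  f <- if (direction == "earlier") backward_lookup else forward_lookup
  cap_rows(f(session$tree, session$index, session$fixed,
             center = session$center), session$row_limit)
}

#' Select an extension row, fixing a longer sequence
#'
#' Selecting a row from the later (or earlier) panel appends (prepends)
#' the row's symbol to the fixed sequence; the sequence's relation
#' sub-matrix gains the relations read from the row's TIRP between the new
#' element and every fixed element. The selected TIRP becomes the one the
#' center block reports, the opposite panel is recomputed against the
#' enlarged sequence, and the same-side panel is retained with the chosen
#' row marked. The center STI itself does not move.
#'
#' @param session A `tirp_session`.
#' @param direction `"later"` or `"earlier"`: which panel the row is from.
#' @param row Row number within that panel.
#' @return The new `tirp_session` (the previous state is kept for
#'   [undo_selection()]).
#' @export
select_extension <- function(session, direction = c("later", "earlier"),
                             row) {
  direction <- match.arg(direction)
  m <- length(session$fixed$symbols)
  boundary <- if (direction == "earlier") session$center == 1L
              else session$center == m
  if (!boundary) {
    rlang::abort(paste0("the ", direction,
                        " side is already fixed at this center; shift first"),
                 class = "tirpscope_selection_error")
  }
  panel <- session$panels[[direction]]
  if (!is.numeric(row) || row < 1 || row > nrow(panel)) {
    rlang::abort("row is not in the current panel (stale selection?)",
                 class = "tirpscope_stale_selection_error")
  }
  chosen <- panel[row, ]
  node <- tree_node(session$tree, chosen$node)
  p <- chosen$match_pos
  new_start <- if (direction == "later") p else p - 1L
  positions <- new_start:(new_start + m)
  fixed <- fixed_sequence(node$symbols[[1]][positions],
                          rel_submatrix(node$relations[[1]], positions),
                          provenance = c(session$fixed$provenance, node$id))
  center <- if (direction == "earlier") session$center + 1L else session$center
  same <- panel
  same$selected <- seq_len(nrow(same)) == row
  out <- new_session(session$tree, session$index, fixed, center,
                     selected_node = node$id, anchor = new_start,
                     panels = session$panels, row_limit = session$row_limit,
                     history = c(session$history, list(session)))
  opposite <- if (direction == "later") "earlier" else "later"
  out$panels[[direction]] <- same
  out$panels[[opposite]] <- recompute_panel(out, opposite)
  out
}

shift_session <- function(session, delta) {
  m <- length(session$fixed$symbols)
  target <- session$center + delta
  if (target < 1L || target > m) {
    rlang::abort("cannot shift beyond the fixed sequence",
                 class = "tirpscope_shift_error")
  }
  out <- session
  out$center <- target
  out$history <- c(session$history, list(session))
  out$panels <- list(earlier = recompute_panel(out, "earlier"),
                     later = recompute_panel(out, "later"))
  out
}

#' Shift the center one STI later
#'
#' Further exploration: the fixed sequence, its relations and the selected
#' TIRP are unchanged; only the center moves. The side where a fixed
#' neighbor now exists collapses to that neighbor as a single marked row;
#' a boundary side shows the extensions of the whole fixed sequence.
#'
#' @param session A `tirp_session` whose center has a later fixed
#'   neighbor.
#' @return The shifted `tirp_session`.
#' @export
shift_forward <- function(session) shift_session(session, +1L)

#' Shift the center one STI earlier
#' @param session A `tirp_session` whose center has an earlier fixed
#'   neighbor.
#' @return The shifted `tirp_session`.
#' @export
shift_backward <- function(session) shift_session(session, -1L)

#' Undo the most recent selection or shift
#' @param session A `tirp_session`.
#' @return The previous `tirp_session`.
#' @export
undo_selection <- function(session) {
  h <- session$history
  if (!length(h)) {
    rlang::abort("nothing to undo", class = "tirpscope_undo_error")
  }
  h[[length(h)]]
}

#' Positional pattern query (first / intermediate / last)
#'
#' The query-style retrieval that associative exploration is compared
#' against: select every pattern whose first symbol, last symbol and/or
#' some strictly interior symbol match the given constraints. Because the
#' intermediate constraint may match anywhere inside the pattern, the
#' result is typically a superset of what an immediate-neighbor
#' exploration returns.
#'
#' @param tree A `tirp_tree`.
#' @param first,intermediate,last Optional symbols; at least one must be
#'   given. `first` must equal the pattern's first symbol, `last` its
#'   final symbol, and `intermediate` must occur at a position strictly
#'   between the first and last positions.
#' @return A tibble of matching nodes (as in [tidy.tirp_tree()]).
#' @export
positional_query <- function(tree, first = NULL, intermediate = NULL,
                                 last = NULL) {
  if (is.null(first) && is.null(intermediate) && is.null(last)) {
    rlang::abort("at least one of first/intermediate/last is required",
                 class = "tirpscope_config_error")
  }
  keep <- vapply(tree$nodes$symbols, function(sym) {
    k <- length(sym)
    if (!is.null(first) && sym[1] != first) return(FALSE)
    if (!is.null(last) && sym[k] != last) return(FALSE)
    if (!is.null(intermediate)) {
      if (k < 3L) return(FALSE)
      if (!intermediate %in% sym[2:(k - 1L)]) return(FALSE)
    }
    TRUE
  }, logical(1))
  tidy(tree)[keep, ]
}
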