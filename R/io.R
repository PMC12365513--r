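# Readers and writers for the artifact formats: STI and time-series CSVs
# (RFC 4180, header required), and canonical JSON documents for trees,
# indices and chart payloads. Readers reject malformed input rather than
# coercing it; writers are deterministic (canonical ordering, 6
# significant digits for floats).

TREE_FORMAT <- "tirpscope-tree/1"

read_csv_strict <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    rlang::abort(paste0(path, ": missing column(s) ",
                        paste(miss, collapse = ", ")),
                 class = "tirpscope_format_error")
  }
  df
}

parse_num <- function(x, path, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    rlang::abort(sprintf("%s: non-numeric %s at line %d (value '%s')",
                         path, column, bad[1] + 1L, x[bad[1]]),
                 class = "tirpscope_format_error")
  }
  out
}

#' Read an STI database from CSV
#'
#' @param path CSV with header `entity_id, symbol, start, end`.
#' @return A tibble of STIs sorted by entity and [sti_order()]; row count
#'   equals the file's data-row count.
#' @export
read_sti_csv <- function(path) {
  df <- read_csv_strict(path, c("entity_id", "symbol", "start", "end"))
  start <- parse_num(df$start, path, "start")
  end <- parse_num(df$end, path, "end")
  bad <- which(start > end)
  if (length(bad)) {
    rlang::abort(sprintf("%s: start > end at line %d", path, bad[1] + 1L),
                 class = "tirpscope_format_error")
  }
  arrange_stis(tibble::tibble(entity_id = df$entity_id, symbol = df$symbol,
                              start = start, end = end))
}

#' Write an STI database to CSV
#' @param stis STI tibble (`entity_id, symbol, start, end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sti_csv <- function(stis, path) {
  utils::write.csv(arrange_stis(check_sti_frame(stis))[,
                     c("entity_id", "symbol", "start", "end")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read static attributes from CSV
#' @param path CSV with header `entity_id, attribute, value`.
#' @return A tibble.
#' @export
read_attributes_csv <- function(path) {
  tibble::as_tibble(read_csv_strict(path, c("entity_id", "attribute", "value")))
}

#' Read raw time series from CSV
#'
#' @param path CSV with header `entity_id, variable, timestamp, value`.
#' @return A tibble sorted by entity, variable and timestamp; duplicate
#'   timestamps within one `(entity, variable)` series are rejected.
#' @export
read_timeseries_csv <- function(path) {
  df <- read_csv_strict(path, c("entity_id", "variable", "timestamp", "value"))
  out <- tibble::tibble(
    entity_id = df$entity_id, variable = df$variable,
    timestamp = parse_num(df$timestamp, path, "timestamp"),
    value = parse_num(df$value, path, "value")
  ) |>
    dplyr::arrange(.data$entity_id, .data$variable, .data$timestamp)
  dup <- out |>
    dplyr::summarise(dup = anyDuplicated(.data$timestamp) > 0L,
                     .by = c("entity_id", "variable"))
  if (any(dup$dup)) {
    first <- dup[dup$dup, ][1, ]
    rlang::abort(sprintf("%s: duplicate timestamp in series (%s, %s)",
                         path, first$entity_id, first$variable),
                 class = "tirpscope_format_error")
  }
  out
}

canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null", pretty = FALSE)
}

sig6 <- function(x) signif(as.numeric(x), 6)

#' Write an enumeration tree to canonical JSON
#'
#' The document carries the format version, the mining configuration, the
#' alphabet and one record per node (id, parent, symbols, relation code
#' string, metrics, supporting transaction ids). Instance tables are not
#' serialized. Writing is canonical — fixed key order, floats at 6
#' significant digits — so `write(read(x))` is byte-identical.
#'
#' @param tree A `tirp_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  nodes <- lapply(seq_len(nrow(tree$nodes)), function(i) {
    n <- tree$nodes[i, ]
    list(
      id = n$id,
      parent = if (is.na(n$parent)) NULL else n$parent,
      symbols = as.list(n$symbols[[1]]),
      relations = paste(n$relations[[1]], collapse = ""),
      vs = as.integer(n$vs),
      relative_vs = sig6(n$relative_vs),
      mhs = sig6(n$mhs),
      mmd = sig6(n$mmd),
      support = as.list(sort(n$support[[1]]))
    )
  })
  cfg <- tree$config
  doc <- list(
    format = TREE_FORMAT,
    config = list(
      min_vs = if (is.null(cfg$min_vs)) NULL else sig6(cfg$min_vs),
      max_gap = if (is.null(cfg$max_gap)) NULL else sig6(cfg$max_gap),
      epsilon = if (is.null(cfg$epsilon)) NULL else sig6(cfg$epsilon),
      max_size = if (is.null(cfg$max_size) || !is.finite(cfg$max_size)) NULL
                 else as.integer(cfg$max_size)
    ),
    n_transactions = tree$n_transactions,
    alphabet = as.list(tree$alphabet),
    nodes = nodes
  )
  writeLines(canonical_json(doc), path, useBytes = TRUE)
  invisible(path)
}

#' Read an enumeration tree from JSON
#'
#' Validates the document (unique ids, parents preceding children,
#' triangular relation strings over the `b m o s c f e` alphabet,
#' extension consistency) and aborts with a descriptive error on any
#' violation.
#'
#' @param path A [write_tree()] document.
#' @return A `tirp_tree` (without instance tables).
#' @export
read_tree <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, TREE_FORMAT)) {
    rlang::abort(paste0(path, ": not a ", TREE_FORMAT, " document"),
                 class = "tirpscope_format_error")
  }
  codes <- unname(temporal_relations())
  rows <- lapply(doc$nodes, function(n) {
    rel <- if (nchar(n$relations)) strsplit(n$relations, "")[[1]] else character(0)
    if (length(setdiff(rel, codes))) {
      rlang::abort(sprintf("%s: node %s has invalid relation codes", path, n$id),
                   class = "tirpscope_format_error")
    }
    k <- length(n$symbols)
    if (length(rel) != (k * (k - 1L)) %/% 2L) {
      rlang::abort(sprintf("%s: node %s relation string length != k(k-1)/2",
                           path, n$id),
                   class = "tirpscope_format_error")
    }
    tibble::tibble(
      id = n$id,
      parent = if (is.null(n$parent) || !length(n$parent)) NA_character_
               else as.character(n$parent[[1]]),
      size = k,
      symbols = list(unlist(n$symbols)),
      relations = list(rel),
      vs = as.integer(n$vs),
      relative_vs = as.numeric(n$relative_vs),
      mhs = as.numeric(n$mhs),
      mmd = as.numeric(n$mmd),
      support = list(as.character(unlist(n$support))),
      instances = list(NULL)
    )
  })
  nodes <- if (length(rows)) dplyr::bind_rows(rows) else empty_nodes()
  cfg <- doc$config
  if (!is.null(cfg$max_size)) cfg$max_size <- as.numeric(cfg$max_size)
  tree <- new_tirp_tree(nodes, unlist(doc$alphabet),
                        as.integer(doc$n_transactions), cfg)
  validate_tree(tree)
  tree
}

#' Write a pair index to canonical JSON
#' @param index A `tirp_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  e <- index$entries
  doc <- list(
    format = "tirpscope-index/1",
    entries = lapply(seq_len(nrow(e)), function(i) {
      list(first = e$first[i], second = e$second[i], node = e$node[i],
           position = e$position[i], relation = e$relation[i])
    })
  )
  writeLines(canonical_json(doc), path, useBytes = TRUE)
  invisible(path)
}

#' Write a chart payload (any data frame) to canonical JSON
#' @param payload A data frame (timeline bars, bubble points, breakdown).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_payload_json <- function(payload, path) {
  payload <- as.data.frame(payload)
  num <- vapply(payload, is.numeric, logical(1))
  payload[num] <- lapply(payload[num], sig6)
  writeLines(jsonlite::toJSON(payload, dataframe = "rows", digits = NA,
                              na = "null"),
             path, useBytes = TRUE)
  invisible(path)
}
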