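#' Equal-width discretization cutoffs
#'
#' Computes the `n_bins - 1` interior cutoffs that split the observed value
#' range into bins of equal width, the standard data-driven alternative to
#' expert-given cutoffs for state abstraction.
#'
#' @param values Numeric vector of observed values.
#' @param n_bins Number of bins, at least 2.
#' @return Ascending numeric vector of `n_bins - 1` cutoffs.
#' @export
#' @examples
#' ewd_cutoffs(c(0, 3, 10), n_bins = 2) # 5
#' ewd_cutoffs(c(0, 10), n_bins = 4)    # 2.5 5 7.5
ewd_cutoffs <- function(values, n_bins) {
  stopifnot(n_bins >= 2)
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2L || rng[1] == rng[2]) {
    rlang::abort(
      "equal-width discretization needs at least two distinct values",
      class = "tirpscope_degenerate_range_error"
    )
  }
  rng[1] + seq_len(n_bins - 1L) * diff(rng) / n_bins
}

#' State labels for sampled values
#'
#' Assigns each value its state label given ascending cutoffs: bin `i`
#' covers `[cutoffs[i-1], cutoffs[i])`, with the top bin right-closed, so a
#' value equal to a cutoff takes the label above it. Emitted symbols follow
#' the `"Variable.Label"` convention.
#'
#' @param values Numeric vector.
#' @param cutoffs Strictly ascending numeric cutoffs.
#' @param labels Character vector of `length(cutoffs) + 1` state labels.
#' @param variable Variable name used as the symbol prefix, or `NULL` to
#'   return bare labels.
#' @return Character vector of symbols, one per value.
#' @export
#' @examples
#' label_states(c(1, 5, 6), cutoffs = 5, labels = c("Low", "High"), "Var")
label_states <- function(values, cutoffs, labels, variable = NULL) {
  stopifnot(length(labels) == length(cutoffs) + 1L,
            !is.unsorted(cutoffs, strictly = TRUE))
  if (length(values) == 0L) return(character(0))
  lab <- labels[findInterval(values, cutoffs) + 1L]
  if (is.null(variable)) lab else paste(variable, lab, sep = ".")
}

#' Gradient labels for consecutive sample pairs
#'
#' First-derivative abstraction: each consecutive sample pair becomes a
#' segment spanning the two timestamps, labelled `Increasing` when the
#' slope exceeds `theta`, `Decreasing` when it is below `-theta`, and
#' `Stable` otherwise.
#'
#' @param timestamps Strictly increasing numeric vector, length at least 2.
#' @param values Numeric vector, same length.
#' @param theta Non-negative stability threshold on the slope. Default 0:
#'   any nonzero slope is a trend.
#' @param variable Optional variable name used as symbol prefix.
#' @return A tibble with columns `symbol`, `start`, `end`, one row per
#'   segment.
#' @export
#' @examples
#' label_gradients(c(0, 1, 2), c(1, 2, 2), theta = 0.1, variable = "Var")
label_gradients <- function(timestamps, values, theta = 0, variable = NULL) {
  stopifnot(theta >= 0)
  n <- length(timestamps)
  if (n < 2L) {
    rlang::abort("gradient abstraction needs at least two samples",
                 class = "tirpscope_insufficient_data_error")
  }
  if (is.unsorted(timestamps, strictly = TRUE)) {
    rlang::abort("timestamps must be strictly increasing",
                 class = "tirpscope_format_error")
  }
  slope <- diff(values) / diff(timestamps)
  lab <- dplyr::case_when(
    slope > theta  ~ "Increasing",
    slope < -theta ~ "Decreasing",
    .default = "Stable"
  )
  if (!is.null(variable)) lab <- paste(variable, lab, sep = ".")
  tibble::tibble(symbol = lab,
                 start = timestamps[-n],
                 end = timestamps[-1])
}

#' Merge runs of identical labels into STIs
#'
#' Concatenates maximal runs of time-adjacent elements carrying the same
#' symbol into single STIs spanning from the first element's start to the
#' last element's end. A run is broken when the time step from one
#' element's end to the next element's start exceeds `max_sample_gap`.
#' Point samples (`start == end`) produce zero-duration STIs when they
#' stand alone.
#'
#' @param labelled A data frame with columns `symbol`, `start`, `end`,
#'   ordered by time.
#' @param max_sample_gap Maximal permitted time step inside a run.
#'   Default `Inf` (no run breaking).
#' @return A tibble of STIs with columns `symbol`, `start`, `end`.
#' @export
#' @examples
#' runs_to_stis(tibble::tibble(symbol = c("A", "A", "B"),
#'                             start = 1:3, end = 1:3))
runs_to_stis <- function(labelled, max_sample_gap = Inf) {
  n <- nrow(labelled)
  if (n == 0L) {
    return(tibble::tibble(symbol = character(0), start = numeric(0),
                          end = numeric(0)))
  }
  new_run <- c(TRUE,
               labelled$symbol[-1] != labelled$symbol[-n] |
                 (labelled$start[-1] - labelled$end[-n]) > max_sample_gap)
  run_id <- cumsum(new_run)
  labelled |>
    dplyr::mutate(.run = run_id) |>
    dplyr::summarise(symbol = dplyr::first(.data$symbol),
                     start = dplyr::first(.data$start),
                     end = dplyr::last(.data$end),
                     .by = ".run") |>
    dplyr::select(!".run")
}

#' Temporal-abstraction configuration for one variable
#'
#' @param variable Variable name the configuration applies to.
#' @param method `"state"` (cutoff-based) or `"gradient"`
#'   (first-derivative).
#' @param cutoffs For state abstraction: strictly ascending cutoffs, expert
#'   given or from [ewd_cutoffs()].
#' @param labels For state abstraction: `length(cutoffs) + 1` bin labels.
#' @param theta For gradient abstraction: stability threshold on the slope.
#' @param max_sample_gap Run-break threshold passed to [runs_to_stis()].
#' @param extend_to_next For state abstraction: if `TRUE`, each sample's
#'   state is held until the next sample's timestamp instead of ending at
#'   its own; default `FALSE` (no unobserved duration is invented).
#' @return An `abstraction_config` object (a list).
#' @export
abstraction_config <- function(variable,
                               method = c("state", "gradient"),
                               cutoffs = NULL, labels = NULL,
                               theta = 0, max_sample_gap = Inf,
                               extend_to_next = FALSE) {
  method <- match.arg(method)
  if (method == "state") {
    stopifnot(!is.null(cutoffs), !is.null(labels),
              length(labels) == length(cutoffs) + 1L)
  }
  structure(
    list(variable = variable, method = method, cutoffs = cutoffs,
         labels = labels, theta = theta, max_sample_gap = max_sample_gap,
         extend_to_next = extend_to_next),
    class = "abstraction_config"
  )
}

#' Abstract raw multivariate time series into an STI database
#'
#' Applies per-variable state or gradient abstraction to a long table of
#' raw samples and returns the resulting STI records, the tabular form all
#' mining functions consume.
#'
#' @param data A data frame with columns `entity_id`, `variable`,
#'   `timestamp`, `value`; timestamps must be strictly increasing within
#'   each `(entity_id, variable)` series.
#' @param configs A list of [abstraction_config()] objects; variables
#'   without a configuration are dropped with a warning.
#' @return A tibble with columns `entity_id`, `symbol`, `start`, `end`,
#'   sorted by entity and [sti_order()].
#' @export
abstract_timeseries <- function(data, configs) {
  stopifnot(all(c("entity_id", "variable", "timestamp", "value")
                %in% names(data)))
  cfg_vars <- vapply(configs, function(cf) cf$variable, character(1))
  names(configs) <- cfg_vars
  missing_cfg <- setdiff(unique(data$variable), cfg_vars)
  if (length(missing_cfg)) {
    rlang::warn(paste("no abstraction config for variable(s):",
                      paste(missing_cfg, collapse = ", ")))
  }
  data <- dplyr::filter(data, .data$variable %in% cfg_vars)
  if (nrow(data) == 0L) {
    return(tibble::tibble(entity_id = character(0), symbol = character(0),
                          start = numeric(0), end = numeric(0)))
  }
  data |>
    dplyr::arrange(.data$entity_id, .data$variable, .data$timestamp) |>
    dplyr::group_by(.data$entity_id, .data$variable) |>
    dplyr::group_modify(function(df, key) {
      cf <- configs[[key$variable]]
      if (cf$method == "state") {
        sym <- label_states(df$value, cf$cutoffs, cf$labels, key$variable)
        ends <- if (isTRUE(cf$extend_to_next) && nrow(df) > 1L) {
          c(df$timestamp[-1], df$timestamp[nrow(df)])
        } else {
          df$timestamp
        }
        lab <- tibble::tibble(symbol = sym, start = df$timestamp, end = ends)
      } else {
        lab <- label_gradients(df$timestamp, df$value, cf$theta, key$variable)
      }
      runs_to_stis(lab, cf$max_sample_gap)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("entity_id", "symbol", "start", "end") |>
    arrange_stis()
}

# canonical STI ordering within entity
arrange_stis <- function(stis) {
  dplyr::arrange(stis, .data$entity_id, .data$start, .data$end, .data$symbol)
}
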