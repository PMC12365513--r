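# Generators: planted-pattern STI databases, random enumeration trees for
# index fuzzing, and a small hand-built demonstration tree.

#' Generate an STI database with a planted pattern
#'
#' Each of `n` transactions independently receives the template — a
#' concrete STI list realising the target pattern — with probability `pi`,
#' rigidly shifted in time by a uniform draw from `[0, shift_max]` (a
#' global shift preserves every pairwise relation; per-STI jitter is
#' deliberately not offered, since it can flip knife-edge relations such
#' as meets). Background noise STIs are added independently: a Poisson
#' count per transaction, symbols drawn from `noise_symbols`, uniform
#' starts over `[0, horizon]` and uniform durations.
#'
#' @param template Data frame (`symbol`, `start`, `end`) realising the
#'   planted pattern, in [sti_order()].
#' @param n Number of transactions.
#' @param pi Plant probability per transaction, in `(0, 1]` (0 allowed for
#'   negative controls).
#' @param noise_mean Poisson mean of background STIs per transaction.
#' @param noise_symbols Symbol pool for noise (keep disjoint from the
#'   template's symbols to make the planted support identifiable).
#' @param horizon Time horizon for noise starts.
#' @param duration_range Uniform range of noise STI durations.
#' @param shift_max Maximal rigid time shift applied to the template.
#' @param template_relations Optional expected relation vector for the
#'   template; construction aborts if the template does not realise it.
#' @param seed Optional RNG seed for full reproducibility.
#' @return A list: `stis` (the database tibble), `planted` (entity ids
#'   that received the template), `template_symbols`,
#'   `template_relations` (the realised signature).
#' @export
generate_sti_db <- function(template = default_template(), n = 200,
                            pi = 0.6, noise_mean = 3,
                            noise_symbols = paste0("Noise.S", 1:8),
                            horizon = 100, duration_range = c(1, 5),
                            shift_max = 20, template_relations = NULL,
                            seed = NULL) {
  stopifnot(pi >= 0, pi <= 1, n >= 1, noise_mean >= 0)
  if (!is.null(seed)) set.seed(seed)
  template <- template[order(template$start, template$end, template$symbol), ]
  realised <- relations_from_stis(template$start, template$end)
  if (!is.null(template_relations) &&
      !identical(realised, as.character(template_relations))) {
    rlang::abort("template intervals do not realise the stated relations",
                 class = "tirpscope_spec_error")
  }
  ids <- sprintf("E%03d", seq_len(n))
  planted <- ids[stats::runif(n) < pi]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    parts <- list()
    if (ids[i] %in% planted) {
      shift <- stats::runif(1, 0, shift_max)
      parts$plant <- tibble::tibble(entity_id = ids[i],
                                    symbol = template$symbol,
                                    start = template$start + shift,
                                    end = template$end + shift)
    }
    k <- stats::rpois(1, noise_mean)
    if (k > 0) {
      st <- stats::runif(k, 0, horizon)
      du <- stats::runif(k, duration_range[1], duration_range[2])
      parts$noise <- tibble::tibble(entity_id = ids[i],
                                    symbol = sample(noise_symbols, k,
                                                    replace = TRUE),
                                    start = st, end = st + du)
    }
    rows[[i]] <- dplyr::bind_rows(parts)
  }
  stis <- arrange_stis(dplyr::bind_rows(rows))
  list(stis = stis, planted = planted,
       template_symbols = template$symbol,
       template_relations = realised)
}

#' Default planted template
#'
#' Three clinical abstraction symbols in a before-chain (gaps of 3 time
#' units, well inside a 20-unit maximal gap).
#' @return A tibble (`symbol`, `start`, `end`).
#' @export
default_template <- function() {
  tibble::tibble(
    symbol = c("Glucose.High", "Exercise.Low", "Fatigue.High"),
    start = c(0, 8, 15),
    end = c(5, 12, 20)
  )
}

# ---- demonstration tree ---------------------------------------------------

#' Hand-built demonstration enumeration tree
#'
#' A small 18-node tree over five care-home symbols (falls domain:
#' `Fall.Event`, `Fluids.Low`, `Happiness.Decreased`,
#' `Appetite.Decreased`, `Activity.Decreased`), used throughout the
#' examples, the vignette and the test suite. Every node's relation
#' matrix is derived from a concrete interval realisation, so all
#' matrices are guaranteed realisable; support metrics are synthetic
#' (anti-monotone by construction) over a notional 100 transactions.
#'
#' Notable structure: `P7 = <Fluids.Low before Fall.Event>`; its forward
#' extensions in the tree are P12, P13 and P18, its backward extensions
#' P16 and P18; P17 is a 4-sized pattern whose first STI
#' (`Happiness.Decreased`) overlaps `Fall.Event`.
#'
#' @return A `tirp_tree`.
#' @export
#' @examples
#' tree <- toy_falls_tree()
#' idx <- build_tirp_index(tree)
#' forward_lookup(tree, idx, fixed_sequence(c("Fluids.Low", "Fall.Event"), "b"))
toy_falls_tree <- function() {
  Fv <- "Fall.Event"; L <- "Fluids.Low"; H <- "Happiness.Decreased"
  A <- "Appetite.Decreased"; Ph <- "Activity.Decreased"
  mk <- function(id, parent, symbols, start, end, vs, mhs, mmd) {
    rel <- relations_from_stis(start, end, epsilon = 0, max_gap = 20)
    stopifnot(!any(rel == "unrelated"))
    tibble::tibble(id = id, parent = parent, size = length(symbols),
                   symbols = list(symbols), relations = list(rel),
                   vs = as.integer(vs), relative_vs = vs / 100,
                   mhs = mhs, mmd = mmd,
                   support = list(character(0)), instances = list(NULL))
  }
  nodes <- dplyr::bind_rows(
    mk("P1", NA, Fv, 0, 0, 90, 1.5, 0),
    mk("P2", NA, L, 0, 2, 85, 1.8, 2),
    mk("P3", NA, H, 0, 5, 70, 1.2, 5),
    mk("P4", NA, A, 0, 2, 60, 1.1, 2),
    mk("P5", NA, Ph, 0, 2, 65, 1.3, 2),
    mk("P6", "P1", c(Fv, Ph), c(0, 4), c(2, 6), 40, 1.2, 6),
    mk("P7", "P2", c(L, Fv), c(0, 4), c(2, 6), 55, 1.4, 6),
    mk("P8", "P2", c(L, H), c(0, 4), c(2, 6), 35, 1.1, 6),
    mk("P9", "P3", c(H, Fv), c(0, 3), c(5, 8), 45, 1.2, 8),
    mk("P10", "P5", c(Ph, L), c(0, 4), c(2, 6), 50, 1.3, 6),
    mk("P11", "P1", c(Fv, A), c(0, 4), c(2, 6), 30, 1.0, 6),
    mk("P12", "P7", c(L, Fv, A), c(0, 4, 8), c(2, 6, 10), 25, 1.2, 10),
    mk("P13", "P7", c(L, Fv, H), c(0, 4, 8), c(2, 6, 10), 22, 1.1, 10),
    mk("P14", "P9", c(H, Fv, A), c(0, 3, 10), c(5, 8, 12), 28, 1.1, 12),
    mk("P15", "P8", c(L, H, Fv), c(0, 4, 7), c(2, 9, 12), 20, 1.0, 12),
    mk("P16", "P10", c(Ph, L, Fv), c(0, 4, 8), c(2, 6, 10), 30, 1.2, 10),
    mk("P17", "P14", c(H, Fv, A, Ph), c(0, 3, 10, 14), c(5, 8, 12, 16),
       15, 1.0, 16),
    mk("P18", "P16", c(Ph, L, Fv, A), c(0, 4, 8, 12), c(2, 6, 10, 14),
       18, 1.1, 14)
  )
  tree <- new_tirp_tree(nodes, c(Fv, L, H, A, Ph), 100,
                        list(min_vs = 0.15, max_gap = 20, epsilon = 0))
  validate_tree(tree)
  tree
}

#' Random structurally valid enumeration tree
#'
#' Fuzzing input for the index and exploration code: starts from one root
#' per symbol and repeatedly extends a random eligible node by one random
#' symbol with a random new relation column. The result always satisfies
#' [validate_tree()] (prefix property, triangular relation vectors,
#' anti-monotone synthetic support).
#'
#' @param n_symbols Alphabet size (symbols `S01`, `S02`, ...).
#' @param n_nodes Total node count, at least `n_symbols`.
#' @param max_size Maximal pattern size.
#' @param seed Optional RNG seed.
#' @return A `tirp_tree` (synthetic metrics, no instances).
#' @export
random_tirp_tree <- function(n_symbols, n_nodes, max_size = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_nodes < n_symbols || (max_size == 1L && n_nodes > n_symbols)) {
    rlang::abort("infeasible tree parameters",
                 class = "tirpscope_spec_error")
  }
  alphabet <- sprintf("S%02d", seq_len(n_symbols))
  codes <- unname(temporal_relations())
  n_txn <- 1000L
  symbols <- vector("list", n_nodes)
  relations <- vector("list", n_nodes)
  parent <- character(n_nodes)
  size <- integer(n_nodes)
  vs <- integer(n_nodes)
  for (i in seq_len(n_symbols)) {
    symbols[[i]] <- alphabet[i]
    relations[[i]] <- character(0)
    parent[i] <- NA_character_
    size[i] <- 1L
    vs[i] <- sample(200:1000, 1)
  }
  if (n_nodes > n_symbols) {
    for (i in (n_symbols + 1L):n_nodes) {
      eligible <- which(size[seq_len(i - 1L)] < max_size)
      p <- if (length(eligible) == 1L) eligible else sample(eligible, 1)
      k <- size[p] + 1L
      symbols[[i]] <- c(symbols[[p]], sample(alphabet, 1))
      relations[[i]] <- c(relations[[p]],
                          sample(codes, k - 1L, replace = TRUE))
      parent[i] <- paste0("R", p)
      size[i] <- k
      vs[i] <- sample.int(vs[p], 1)
    }
  }
  nodes <- tibble::tibble(
    id = paste0("R", seq_len(n_nodes)), parent = parent, size = size,
    symbols = symbols, relations = relations, vs = vs,
    relative_vs = vs / n_txn,
    mhs = 1 + round(stats::runif(n_nodes, 0, 2), 2),
    mmd = round(stats::runif(n_nodes, 1, 30), 2),
    support = replicate(n_nodes, character(0), simplify = FALSE),
    instances = replicate(n_nodes, NULL, simplify = FALSE)
  )
  tree <- new_tirp_tree(nodes, alphabet, n_txn, list())
  validate_tree(tree)
  tree
}
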