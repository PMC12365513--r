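#' Temporal relation codes
#'
#' The seven non-inverse Allen interval relations used throughout the
#' package, each with its fixed single-character code: before (`b`),
#' meets (`m`), overlaps (`o`), starts (`s`), contains (`c`),
#' finished-by (`f`) and equals (`e`). Because symbolic time intervals
#' (STIs) are always compared in their lexicographic order (see
#' [sti_order()]), the six inverse relations are never needed.
#'
#' @return A named character vector mapping relation names to codes.
#' @export
#' @examples
#' temporal_relations()
temporal_relations <- function() {
  c(
    BEFORE      = "b",
    MEETS       = "m",
    OVERLAPS    = "o",
    STARTS      = "s",
    CONTAINS    = "c",
    FINISHED_BY = "f",
    EQUALS      = "e"
  )
}

#' Lexicographic order of symbolic time intervals
#'
#' Total order over STIs by `(start, end, symbol)` ascending. This is the
#' convention under which the seven non-inverse Allen relations suffice to
#' describe any ordered pair, and the order in which every transaction's
#' STIs are kept and every pattern instance is enumerated.
#'
#' All arguments are vectorised and recycled.
#'
#' @param start_a,end_a,symbol_a First STI's start, end and symbol.
#' @param start_b,end_b,symbol_b Second STI's start, end and symbol.
#' @return Integer vector in `{-1, 0, 1}`: `-1` if the first STI sorts
#'   earlier, `0` if identical, `1` if it sorts later.
#' @export
#' @examples
#' sti_order(1, 3, "A", 2, 4, "B") # -1: earlier start
#' sti_order(1, 5, "A", 1, 3, "B") # +1: same start, later end
sti_order <- function(start_a, end_a, symbol_a, start_b, end_b, symbol_b) {
  out <- sign(start_a - start_b)
  tie <- out == 0L
  out[tie] <- sign(end_a - end_b)[tie]
  tie <- out == 0L
  out[tie] <- sign((symbol_a > symbol_b) - (symbol_a < symbol_b))[tie]
  as.integer(out)
}

# epsilon-tolerant three-way comparison: 0 if |x - y| <= eps
cmp_eps <- function(x, y, eps) {
  out <- integer(length(x))
  d <- x - y
  out[d > eps] <- 1L
  out[d < -eps] <- -1L
  out
}

#' Allen relation between two lexicographically ordered STIs
#'
#' Classifies the pair `(a, b)` with `a` not after `b` in [sti_order()]
#' into one of the seven temporal relations, or `"unrelated"` when the two
#' intervals are separated by more than `max_gap` time units. Endpoint
#' comparisons treat values within `epsilon` of each other as equal, so
#' noisy timestamps can still hit the knife-edge relations (meets, starts,
#' finished-by, equals).
#'
#' Vectorised over the endpoint arguments.
#'
#' @param start_a,end_a Endpoints of the lexicographically earlier STI.
#' @param start_b,end_b Endpoints of the later STI.
#' @param epsilon Non-negative tolerance under which two time points are
#'   considered equal. Default 0.
#' @param max_gap Maximal allowed gap `start_b - end_a` for the before
#'   relation; a larger gap yields `"unrelated"`. Default `Inf`.
#' @return Character vector of relation codes (`b m o s c f e`) or
#'   `"unrelated"`.
#' @export
#' @examples
#' allen_relation(0, 5, 7, 10, max_gap = 20) # "b"
#' allen_relation(0, 5, 3, 9)                # "o"
#' allen_relation(0, 5, 30, 40, max_gap = 20) # "unrelated"
allen_relation <- function(start_a, end_a, start_b, end_b,
                           epsilon = 0, max_gap = Inf) {
  stopifnot(epsilon >= 0, max_gap > 0)
  n <- max(length(start_a), length(end_a), length(start_b), length(end_b))
  start_a <- rep_len(start_a, n); end_a <- rep_len(end_a, n)
  start_b <- rep_len(start_b, n); end_b <- rep_len(end_b, n)
  bad <- sti_order(start_a, end_a, "", start_b, end_b, "") > 0L
  if (any(bad)) {
    rlang::abort(
      "`allen_relation()` requires the first STI to precede the second in `sti_order()`.",
      class = "tirpscope_ordering_error"
    )
  }
  s <- cmp_eps(start_a, start_b, epsilon)
  e <- cmp_eps(end_a, end_b, epsilon)
  g <- cmp_eps(end_a, start_b, epsilon)

  out <- character(n)
  same_start <- s == 0L
  out[same_start & e == 0L] <- "e"
  out[same_start & e < 0L] <- "s"
  # reachable only when epsilon blurs the start comparison; treated as the
  # nearest superset relation
  out[same_start & e > 0L] <- "c"

  first <- s < 0L
  out[first & e == 0L] <- "f"
  out[first & e > 0L] <- "c"
  ov <- first & e < 0L
  out[ov & g == 0L] <- "m"
  out[ov & g > 0L] <- "o"
  before <- ov & g < 0L
  gap_ok <- (start_b - end_a) <= max_gap
  out[before & gap_ok] <- "b"
  out[before & !gap_ok] <- "unrelated"
  out
}

# ---- upper-triangular relation storage ------------------------------------
#
# A size-k TIRP's k(k-1)/2 pairwise relations are stored as a flat character
# vector in column order: for j = 2..k the relations r(1,j), ..., r(j-1,j).
# A child TIRP's vector is therefore its parent's vector followed by the new
# column, which is what makes tree extension cheap.

# flat index of pair (i, j), i < j
rel_index <- function(i, j) {
  ((j - 1L) * (j - 2L)) %/% 2L + i
}

#' Pairwise relation inside a TIRP
#'
#' Looks up the temporal relation between the `i`-th and `j`-th STI
#' (`i < j`, both 1-based) of a TIRP whose relations are stored as a flat
#' upper-triangular vector in column order (`r(1,2), r(1,3), r(2,3), ...`).
#'
#' @param relations Character vector of relation codes of length
#'   `k * (k - 1) / 2`.
#' @param i,j Positions with `1 <= i < j <= k`.
#' @return A single relation code.
#' @export
#' @examples
#' pair_relation(c("b", "b", "o"), 2, 3) # "o"
pair_relation <- function(relations, i, j) {
  k <- tirp_size_from_relations(length(relations))
  if (i < 1L || j <= i || j > k) {
    rlang::abort(
      sprintf("pair (%d, %d) out of range for a size-%d TIRP", i, j, k),
      class = "tirpscope_index_error"
    )
  }
  relations[[rel_index(i, j)]]
}

# invert k(k-1)/2 = len
tirp_size_from_relations <- function(len) {
  k <- as.integer(round((1 + sqrt(1 + 8 * len)) / 2))
  if ((k * (k - 1L)) %/% 2L != len) {
    rlang::abort("relation vector length is not triangular",
                 class = "tirpscope_format_error")
  }
  k
}

# relations vector from concrete, lexicographically sorted STIs
relations_from_stis <- function(start, end, epsilon = 0, max_gap = Inf) {
  k <- length(start)
  if (k < 2L) return(character(0))
  pairs_i <- unlist(lapply(2:k, function(j) seq_len(j - 1L)))
  pairs_j <- rep(2:k, times = 1:(k - 1L))
  allen_relation(start[pairs_i], end[pairs_i], start[pairs_j], end[pairs_j],
                 epsilon = epsilon, max_gap = max_gap)
}

#' Check a candidate instance against a TIRP
#'
#' An instance of a TIRP is a lexicographically sorted selection of STIs
#' from one transaction whose symbols match the TIRP's symbol sequence
#' positionally and whose pairwise Allen relations equal the TIRP's
#' relation matrix (every pair; a pair more than `max_gap` apart makes the
#' instance invalid).
#'
#' @param symbols Character vector: the TIRP's symbol sequence.
#' @param relations Flat upper-triangular relation vector (see
#'   [pair_relation()]).
#' @param sti_symbols,sti_start,sti_end The candidate STIs, already in
#'   [sti_order()].
#' @inheritParams allen_relation
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' validate_instance(c("A", "B"), "b", c("A", "B"), c(1, 5), c(2, 6),
#'                   max_gap = 20)
validate_instance <- function(symbols, relations, sti_symbols, sti_start,
                              sti_end, epsilon = 0, max_gap = Inf) {
  if (length(sti_symbols) != length(symbols)) return(FALSE)
  if (!identical(as.character(sti_symbols), as.character(symbols))) return(FALSE)
  obs <- relations_from_stis(sti_start, sti_end, epsilon, max_gap)
  identical(obs, as.character(relations))
}
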