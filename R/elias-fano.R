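# Elias-Fano encoding of a non-decreasing integer sequence, supporting
# random access and predecessor search. Used for the prefix sums L of the
# run lengths, where a weight lookup at hash code i reduces to finding
# the largest t with L[t] <= i - 1.
#
# Layout: each value v < universe is split into a low part of `low_width`
# bits (low_width = max(0, floor(log2(universe / r)))) and a high part
# v >> low_width. The high parts are stored in negated unary in a bit
# vector of length r + (universe >> low_width) + 1: the t-th one-bit sits
# at position (high part of values[t]) + t (1-based). Payload size is
# r * low_width + length(high_bits) bits, which is at most
# r * ceil(log2(universe / r)) + 2r + O(1).

.bit_width <- function(x) {
  # number of bits needed to write x (0 -> 0)
  if (x <= 0) return(0L)
  as.integer(ceiling(log2(x + 1)))
}

#' Build an Elias-Fano sequence
#'
#' @param values non-decreasing vector of non-negative integers, each
#'   strictly less than `universe`. At least one value is required.
#' @param universe exclusive upper bound on the values.
#' @return an object of class `elias_fano` with fields `r`, `universe`,
#'   `low_width`, `low` (the r low parts, as integers), and `high` (the
#'   0/1 high bit vector).
#' @export
ef_build <- function(values, universe) {
  if (!length(values)) stop("empty sequence not supported", call. = FALSE)
  if (anyNA(values) || any(values < 0) || any(values != floor(values))) {
    stop("values must be non-negative integers", call. = FALSE)
  }
  if (is.unsorted(values)) stop("values must be non-decreasing", call. = FALSE)
  if (any(values >= universe)) {
    stop("all values must be < universe", call. = FALSE)
  }
  r <- length(values)
  low_width <- max(0L, as.integer(floor(log2(universe / r))))
  pow <- 2^low_width
  low <- as.integer(values %% pow)
  hi <- values %/% pow
  high <- integer(r + (universe %/% pow) + 1L)
  high[hi + seq_len(r)] <- 1L
  structure(
    list(
      r = r, universe = as.integer(universe), low_width = low_width,
      low = low, high = high,
      # positions of the one-bits, cached for O(1) access
      sel = which(high == 1L)
    ),
    class = "elias_fano"
  )
}

#' @export
print.elias_fano <- function(x, ...) {
  cat(
    "Elias-Fano sequence: r =", x$r, ", universe =", x$universe,
    ", low_width =", x$low_width, ",", ef_size_bits(x)$payload, "payload bits\n"
  )
  invisible(x)
}

#' Random access into an Elias-Fano sequence
#'
#' @param seq an `elias_fano` object.
#' @param t 1-based position(s).
#' @return the stored value(s) at position(s) `t`.
#' @export
ef_access <- function(seq, t) {
  stopifnot(inherits(seq, "elias_fano"))
  if (any(t < 1L) || any(t > seq$r)) stop("position out of range", call. = FALSE)
  hi <- seq$sel[t] - t
  hi * 2^seq$low_width + seq$low[t]
}

#' Predecessor search
#'
#' Largest 1-based position `t` such that `ef_access(seq, t) <= x`, or
#' `NA_integer_` when every stored value exceeds `x`.
#'
#' @param seq an `elias_fano` object.
#' @param x a non-negative integer.
#' @return position of the predecessor, or `NA_integer_`.
#' @export
ef_predecessor_index <- function(seq, x) {
  stopifnot(inherits(seq, "elias_fano"), length(x) == 1L, x >= 0)
  lo <- 1L
  hi <- seq$r
  if (ef_access(seq, 1L) > x) return(NA_integer_)
  while (lo < hi) {
    mid <- lo + (hi - lo + 1L) %/% 2L
    if (ef_access(seq, mid) <= x) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Space accounting for an Elias-Fano sequence
#'
#' @param seq an `elias_fano` object.
#' @return list with `low_bits`, `high_bits`, `payload` (their sum) and
#'   `header_bits` (the fixed-size r / universe / low_width header of the
#'   serialised form, reported separately).
#' @export
ef_size_bits <- function(seq) {
  stopifnot(inherits(seq, "elias_fano"))
  low_bits <- seq$r * seq$low_width
  high_bits <- length(seq$high)
  list(
    low_bits = low_bits,
    high_bits = high_bits,
    payload = low_bits + high_bits,
    header_bits = 3L * 32L
  )
}
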