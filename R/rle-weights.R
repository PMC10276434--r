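# Run-length representation of the global weight sequence W[1..n] and its
# compressed encoding:
#
#   D      sorted table of the distinct run values
#   codes  one fixed-width code per run, indexing into D
#   L      Elias-Fano sequence of the prefix sums 0, l_1, ..., l_{r-1}
#
# Retrieving W[i] identifies the run containing position i with a
# predecessor query on L and then decodes its value through D.

#' Extract the runs of a weight sequence
#'
#' @param W vector of positive integer weights, `length(W) >= 1`.
#' @return object of class `rlw`: list with `values`, `lengths` (the
#'   maximal runs, in order; adjacent values always differ) and `n`.
#' @examples
#' compute_runs(c(7, 7, 7))        # one run
#' compute_runs(c(1, 2, 1))$values # 1 2 1
#' @export
compute_runs <- function(W) {
  if (!length(W)) stop("empty weight sequence", call. = FALSE)
  if (anyNA(W) || any(W < 1) || any(W != floor(W))) {
    stop("weights must be positive integers", call. = FALSE)
  }
  z <- rle(as.integer(W))
  structure(
    list(values = z$values, lengths = z$lengths, n = length(W)),
    class = "rlw"
  )
}

#' Expand run-length pairs back to the flat weight sequence
#'
#' @param rlw an `rlw` object (or anything with `values` and `lengths`).
#' @return integer vector of length `sum(lengths)`.
#' @export
expand_runs <- function(rlw) {
  rep(as.integer(rlw$values), rlw$lengths)
}

#' Build run-length pairs directly from values and lengths
#'
#' Validates the run invariants: positive values and lengths, adjacent
#' values distinct, and (if `n` is given) lengths summing to `n`.
#'
#' @param values run values.
#' @param lengths run lengths.
#' @param n expected total, optional.
#' @return an `rlw` object.
#' @export
rlw_pairs <- function(values, lengths, n = sum(lengths)) {
  stopifnot(length(values) == length(lengths), length(values) >= 1L)
  if (any(values < 1) || any(lengths < 1)) {
    stop("run values and lengths must be >= 1", call. = FALSE)
  }
  r <- length(values)
  if (r > 1L && any(values[-1L] == values[-r])) {
    stop("adjacent run values must differ", call. = FALSE)
  }
  if (sum(lengths) != n) stop("run lengths must cover n weights", call. = FALSE)
  structure(
    list(values = as.integer(values), lengths = as.integer(lengths),
         n = as.integer(n)),
    class = "rlw"
  )
}

#' @export
print.rlw <- function(x, ...) {
  cat("Run-length weights:", length(x$values), "runs over", x$n, "weights\n")
  invisible(x)
}

#' Encode run-length weights
#'
#' @param rlw an `rlw` object from [compute_runs()] or [rlw_pairs()].
#' @return object of class `encoded_weights`: `D` (sorted distinct run
#'   values), `code_width` (`ceiling(log2(|D|))`, zero when `|D| == 1`),
#'   `codes` (1-based indexes into `D`, conceptually stored in
#'   `code_width` bits each), `L` (Elias-Fano prefix sums, `L[1] = 0`),
#'   `n`, and `max` (largest weight).
#' @export
encode_weights <- function(rlw) {
  stopifnot(inherits(rlw, "rlw"))
  D <- sort(unique(rlw$values))
  codes <- match(rlw$values, D)
  prefix <- cumsum(c(0L, rlw$lengths[-length(rlw$lengths)]))
  structure(
    list(
      D = D,
      code_width = .bit_width(length(D) - 1L),
      codes = codes,
      L = ef_build(prefix, universe = rlw$n),
      n = rlw$n,
      max = max(rlw$values)
    ),
    class = "encoded_weights"
  )
}

#' Decode back to run-length pairs
#'
#' Exact inverse of [encode_weights()].
#'
#' @param enc an `encoded_weights` object.
#' @return an `rlw` object.
#' @export
decode_weights <- function(enc) {
  stopifnot(inherits(enc, "encoded_weights"))
  r <- enc$L$r
  prefix <- ef_access(enc$L, seq_len(r))
  lengths <- diff(c(prefix, enc$n))
  rlw_pairs(enc$D[enc$codes], lengths, enc$n)
}

#' @export
print.encoded_weights <- function(x, ...) {
  sp <- space_bits(x)
  cat(
    "Encoded weights:", length(x$codes), "runs,", x$n, "weights, |D| =",
    length(x$D), ",", sprintf("%.3f", sp$total / x$n), "bits/k-mer\n"
  )
  invisible(x)
}

#' Retrieve the weight at a hash code
#'
#' Hash codes are 1-based; `i` must lie in `1..n`. The run containing `i`
#' is the predecessor of `i - 1` in `L`.
#'
#' @param enc an `encoded_weights` object.
#' @param i hash code(s) in `1..n`.
#' @return integer weight(s) `W[i]` of the original sequence.
#' @export
lookup_weight <- function(enc, i) {
  stopifnot(inherits(enc, "encoded_weights"))
  if (any(i < 1L) || any(i > enc$n)) {
    stop("hash code out of range 1..n", call. = FALSE)
  }
  j <- vapply(i, function(ii) ef_predecessor_index(enc$L, ii - 1L), integer(1L))
  enc$D[enc$codes[j]]
}

#' Space accounting for encoded weights
#'
#' The distinct-value table is stored with `max(1, ceiling(log2(max + 1)))`
#' bits per entry; the narrower width `ceiling(log2(max))` is reported
#' alongside for comparison (it under-counts by one bit exactly when the
#' largest weight is a power of two).
#'
#' @param enc an `encoded_weights` object.
#' @return list with per-section bit counts (`codes_bits`, `L_bits`,
#'   `D_bits`, `D_bits_narrow`, `dict_width`) and their `total`
#'   (`codes + L payload + D`).
#' @export
space_bits <- function(enc) {
  stopifnot(inherits(enc, "encoded_weights"))
  r <- length(enc$codes)
  codes_bits <- r * enc$code_width
  L_bits <- ef_size_bits(enc$L)$payload
  dict_width <- max(1L, .bit_width(enc$max))
  D_bits <- length(enc$D) * dict_width
  list(
    codes_bits = codes_bits,
    L_bits = L_bits,
    D_bits = D_bits,
    D_bits_narrow = length(enc$D) * max(0L, as.integer(ceiling(log2(enc$max)))),
    dict_width = dict_width,
    total = codes_bits + L_bits + D_bits
  )
}

#' Empirical zero-order entropy of a weight sequence
#'
#' `H0 = -sum_v p_v log2 p_v` over the symbol frequencies of `W`; the
#' baseline (in bits per k-mer) that the run-length encoding is measured
#' against.
#'
#' @param W vector of weights.
#' @return entropy in bits per symbol.
#' @export
empirical_entropy <- function(W) {
  if (!length(W)) stop("empty weight sequence", call. = FALSE)
  p <- tabulate(match(W, unique(W)))
  p <- p / length(W)
  -sum(p * log2(p))
}
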