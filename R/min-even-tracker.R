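# Constant-time reporting of the key of minimum positive value under
# decrease-by-2 updates. The structure keeps an array A of (key, value)
# pairs sorted by value, a map R from value to the half-open index range
# [begin, end) of its equal-valued block in A, and a map P from key to
# its current index in A. R[0] starts as [1, 1), so R[0].end is always
# the position of the smallest positive value and min-key is a single
# array access. A decrease-by-2 swaps the touched entry to the head of
# its value block and shifts the two adjacent range boundaries, so every
# operation touches O(1) entries.
#
# This drives the even-frequency merging phase of the run-minimising
# path cover: keys are weights, values their (even) frequencies.

#' Build a min-even tracker
#'
#' @param keys distinct keys (integers or strings).
#' @param values even integer values `>= 2`, one per key.
#' @return a mutable object of class `min_even_tracker` (an environment;
#'   operations update it in place).
#' @export
min_even_tracker <- function(keys, values) {
  if (length(keys) != length(values)) {
    stop("keys and values must have equal length", call. = FALSE)
  }
  if (anyDuplicated(keys)) stop("keys must be distinct", call. = FALSE)
  if (length(values) &&
      (any(values < 2) || any(values %% 2 != 0))) {
    stop("values must be even integers >= 2", call. = FALSE)
  }
  ord <- order(values)  # stable: ties keep key insertion order
  t <- new.env(parent = emptyenv())
  t$key <- keys[ord]
  t$value <- as.integer(values[ord])
  t$R <- new.env(hash = TRUE, parent = emptyenv())
  t$P <- new.env(hash = TRUE, parent = emptyenv())
  t$R[["0"]] <- c(1L, 1L)
  if (length(t$value)) {
    blocks <- rle(t$value)
    ends <- cumsum(blocks$lengths)
    begins <- c(1L, ends[-length(ends)] + 1L)
    for (b in seq_along(blocks$values)) {
      t$R[[as.character(blocks$values[b])]] <- c(begins[b], ends[b] + 1L)
    }
  }
  for (i in seq_along(t$key)) t$P[[as.character(t$key[i])]] <- i
  class(t) <- "min_even_tracker"
  t
}

#' @export
print.min_even_tracker <- function(x, ...) {
  cat(
    "Min-even tracker:", length(x$key), "keys,",
    sum(x$value > 0L), "with positive value\n"
  )
  invisible(x)
}

#' Does any key still have a positive value?
#'
#' @param t a [min_even_tracker()].
#' @return `TRUE` iff `R[0].end <= |A|`, i.e. some value is still `> 0`.
#' @export
tracker_has_next <- function(t) {
  stopifnot(inherits(t, "min_even_tracker"))
  t$R[["0"]][2L] <= length(t$key)
}

#' Key of minimum positive value
#'
#' @param t a [min_even_tracker()].
#' @return the key stored at `A[R[0].end]`; its value is the minimum over
#'   all values `> 0`.
#' @export
tracker_min_key <- function(t) {
  if (!tracker_has_next(t)) stop("tracker is exhausted", call. = FALSE)
  t$key[t$R[["0"]][2L]]
}

#' Current value of a key
#'
#' @param t a [min_even_tracker()].
#' @param x a key.
#' @return its current value.
#' @export
tracker_value <- function(t, x) {
  stopifnot(inherits(t, "min_even_tracker"))
  j <- t$P[[as.character(x)]]
  if (is.null(j)) stop("unknown key: ", x, call. = FALSE)
  t$value[j]
}

#' Decrease the value of a key by 2
#'
#' Must not be called on a key whose value is already 0. Updates the
#' tracker in place and returns it invisibly.
#'
#' @param t a [min_even_tracker()].
#' @param x a key.
#' @export
tracker_decrease <- function(t, x) {
  stopifnot(inherits(t, "min_even_tracker"))
  j <- t$P[[as.character(x)]]
  if (is.null(j)) stop("unknown key: ", x, call. = FALSE)
  v <- t$value[j]
  if (v < 2L) stop("value of key ", x, " is already 0", call. = FALSE)
  vkey <- as.character(v)
  i <- t$R[[vkey]][1L]  # head of the block of value v
  if (i != j) {
    # swap A[i] and A[j]; both have value v so sortedness is kept
    ki <- t$key[i]
    t$key[i] <- t$key[j]; t$key[j] <- ki
    t$P[[as.character(t$key[i])]] <- i
    t$P[[as.character(t$key[j])]] <- j
  }
  dkey <- as.character(v - 2L)
  if (is.null(t$R[[dkey]])) {
    t$R[[dkey]] <- c(i, i + 1L)
  } else {
    t$R[[dkey]][2L] <- t$R[[dkey]][2L] + 1L
  }
  t$R[[vkey]][1L] <- t$R[[vkey]][1L] + 1L
  if (t$R[[vkey]][1L] == t$R[[vkey]][2L]) rm(list = vkey, envir = t$R)
  t$value[i] <- v - 2L
  invisible(t)
}

# Snapshot of the internal state, for invariant checking in tests.
tracker_state <- function(t) {
  rn <- ls(t$R)
  R <- lapply(rn, function(v) t$R[[v]])
  names(R) <- rn
  pn <- ls(t$P)
  P <- vapply(pn, function(k) t$P[[k]], integer(1L))
  names(P) <- pn
  list(key = t$key, value = t$value, R = R, P = P)
}
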