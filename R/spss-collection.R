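# The in-memory container for a weighted spectrum-preserving string set
# (SPSS): a collection of DNA strings where every k-mer of the underlying
# set appears exactly once (up to reverse complement), each k-mer carrying
# one positive integer weight (its abundance count).

#' Construct a weighted SPSS collection
#'
#' @param k k-mer length.
#' @param strings a list; each element is a `list(seq = <DNA string>,
#'   weights = <integer vector>)` with one weight per k-mer, i.e.
#'   `length(weights) == nchar(seq) - k + 1`.
#' @param validate_spss check that all canonical k-mers across the
#'   collection are pairwise distinct (the SPSS property).
#' @param allow_duplicates when a duplicate canonical k-mer is found, warn
#'   instead of failing. Intended for hand-made files; indexes cannot be
#'   built from such collections.
#' @return an object of class `spss_collection`: a list with fields `k`
#'   and `strings`, the latter holding `seq` and `weights` per record, in
#'   input order (ids are positional, 1..m).
#' @export
spss_collection <- function(k, strings, validate_spss = TRUE,
                            allow_duplicates = FALSE) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1L)
  k <- as.integer(k)
  strings <- lapply(seq_along(strings), function(i) {
    s <- strings[[i]]
    if (is.null(s$seq) || is.null(s$weights)) {
      stop("record ", i, ": each string needs $seq and $weights", call. = FALSE)
    }
    .check_dna(s$seq, paste0("record ", i))
    w <- s$weights
    if (anyNA(w) || any(w < 1) || any(w != floor(w))) {
      stop("record ", i, ": weights must be positive integers", call. = FALSE)
    }
    nk <- nchar(s$seq) - k + 1L
    if (nk < 1L) {
      stop("record ", i, ": sequence shorter than k", call. = FALSE)
    }
    if (length(w) != nk) {
      stop(
        "record ", i, ": ", length(w), " weights for ", nk, " k-mers",
        call. = FALSE
      )
    }
    list(seq = s$seq, weights = as.integer(w))
  })
  coll <- structure(list(k = k, strings = strings), class = "spss_collection")
  if (validate_spss) .check_spss_property(coll, allow_duplicates)
  coll
}

# Duplicate canonical k-mers violate the SPSS property.
.check_spss_property <- function(coll, allow_duplicates = FALSE) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(coll$strings)) {
    for (g in .canonical_stream(coll$strings[[i]]$seq, coll$k)) {
      if (!is.null(seen[[g]])) {
        msg <- paste0(
          "SPSS violation: canonical k-mer ", g, " in record ", i,
          " already seen in record ", seen[[g]]
        )
        if (allow_duplicates) {
          warning(msg, call. = FALSE)
          return(invisible(FALSE))
        }
        stop(msg, call. = FALSE)
      }
      seen[[g]] <- i
    }
  }
  invisible(TRUE)
}

#' @export
print.spss_collection <- function(x, ...) {
  m <- length(x$strings)
  n <- sum(vapply(x$strings, function(s) length(s$weights), integer(1L)))
  cat(
    "Weighted SPSS collection: m =", m, "strings, k =", x$k,
    ", n =", n, "k-mers\n"
  )
  invisible(x)
}

#' @export
length.spss_collection <- function(x) length(x$strings)

# Concatenated weight sequence W[1..n] in collection order.
.flat_weights <- function(coll) {
  unlist(lapply(coll$strings, `[[`, "weights"), use.names = FALSE)
}

#' Count weight runs of a collection
#'
#' A run is a maximal sub-sequence of equal consecutive weights. Runs are
#' counted per string (`r_i`), in total (`R = sum(r_i)`), and over the
#' concatenated weight sequence (`r`), where a run may cross the boundary
#' between two adjacent strings whenever the last weight of one equals
#' the first weight of the next (a "glued junction").
#'
#' @param coll an [spss_collection()].
#' @return list with `per_string`, `R`, and `r`; always `r <= R` and
#'   `r = R - <number of glued junctions>`.
#' @export
count_runs <- function(coll) {
  stopifnot(inherits(coll, "spss_collection"))
  per <- vapply(
    coll$strings,
    function(s) length(rle(s$weights)$lengths),
    integer(1L)
  )
  W <- .flat_weights(coll)
  r <- if (length(W)) length(rle(W)$lengths) else 0L
  list(per_string = per, R = sum(per), r = r)
}
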