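# Seeded generators of valid weighted SPSS collections and random
# end-point graphs, plus exhaustive oracles, so that every part of the
# package is testable without any external dataset.

.gen_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a random weighted SPSS collection
#'
#' Sequences are sampled uniformly over {A,C,G,T} and rejected (with
#' bounded retries) until all canonical k-mers across the collection are
#' pairwise distinct. Weights follow a Markov repeat model: the first
#' k-mer of a string draws its weight uniformly from `1..max_weight`,
#' and each subsequent k-mer keeps the previous weight with probability
#' `1 - p_change`, otherwise redraws a different value. This emulates
#' the empirical structure of abundance counts, where consecutive k-mers
#' of a string usually share their count.
#'
#' @param m number of strings.
#' @param len_range inclusive range of string lengths.
#' @param k k-mer length; `4^k` should comfortably exceed the number of
#'   requested k-mers.
#' @param p_change probability that a k-mer's weight differs from its
#'   predecessor's.
#' @param max_weight weights are drawn from `1..max_weight`.
#' @param seed integer seed; the output is a deterministic function of
#'   the arguments.
#' @param max_retries per-string rejection-sampling budget.
#' @return an [spss_collection()].
#' @export
gen_spss <- function(m, len_range = c(12L, 30L), k = 7L, p_change = 0.2,
                     max_weight = 6L, seed = 1L, max_retries = 200L) {
  stopifnot(m >= 0L, k >= 1L, len_range[1L] >= k,
            len_range[2L] >= len_range[1L], max_weight >= 1L)
  set.seed(seed)
  used <- new.env(hash = TRUE, parent = emptyenv())
  strings <- vector("list", m)
  for (i in seq_len(m)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      len <- if (len_range[1L] == len_range[2L]) len_range[1L] else {
        sample(len_range[1L]:len_range[2L], 1L)
      }
      seq <- .gen_dna(len)
      canon <- .canonical_stream(seq, k)
      if (anyDuplicated(canon)) next
      if (any(vapply(canon, function(g) !is.null(used[[g]]), logical(1L)))) next
      for (g in canon) used[[g]] <- TRUE
      nk <- length(canon)
      w <- integer(nk)
      w[1L] <- sample.int(max_weight, 1L)
      if (nk > 1L) {
        for (j in 2:nk) {
          if (max_weight > 1L && runif(1L) < p_change) {
            cand <- sample.int(max_weight - 1L, 1L)
            w[j] <- if (cand >= w[j - 1L]) cand + 1L else cand
          } else {
            w[j] <- w[j - 1L]
          }
        }
      }
      strings[[i]] <- list(seq = seq, weights = w)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(
        "could not generate a distinct-k-mer string after ", max_retries,
        " retries; increase k or reduce m", call. = FALSE
      )
    }
  }
  spss_collection(k, strings, validate_spss = FALSE)
}

#' Generate random end-point graph nodes
#'
#' Uniform (front, back) pairs over a weight alphabet `1..n_weights`,
#' with ids `1..m` and sign `+1`.
#'
#' @param m number of nodes.
#' @param n_weights size of the weight alphabet.
#' @param seed integer seed.
#' @return data.frame of end-point nodes (unnormalised).
#' @export
gen_endpoint_nodes <- function(m, n_weights = 4L, seed = 1L) {
  stopifnot(m >= 0L, n_weights >= 1L)
  set.seed(seed)
  data.frame(
    id = seq_len(m),
    front = if (m) sample.int(n_weights, m, replace = TRUE) else integer(0L),
    back = if (m) sample.int(n_weights, m, replace = TRUE) else integer(0L),
    sign = rep(1L, m)
  )
}

## ---- exhaustive oracles -------------------------------------------------
## Both oracles search over all signed orderings of the input nodes
## (memoised on the set of used nodes and the open end weight, which is
## all that the remaining choices can depend on). They are definitionally
## correct and serve as the ground truth for the cover algorithms.

#' Exhaustive minimum path cover size
#'
#' Minimum number of maximal glued chains over all `m! * 2^m` signed
#' orderings of the nodes. Refuses graphs with more than `max_m` nodes.
#'
#' @param nodes data.frame of end-point nodes.
#' @param max_m size guard for the exhaustive search.
#' @return the exact optimum `|C*|`.
#' @export
oracle_min_cover_size <- function(nodes, max_m = 7L) {
  m <- nrow(nodes)
  if (m > max_m) stop("graph too large for exhaustive search", call. = FALSE)
  if (!m) return(0L)
  fr <- nodes$front; bk <- nodes$back
  memo <- new.env(hash = TRUE, parent = emptyenv())
  full <- 2^m - 1
  # paths_open(mask, w): min additional paths given an open path ending
  # in weight w; paths_closed(mask): min paths covering the complement
  paths_closed <- function(mask) {
    if (mask == full) return(0L)
    key <- paste0("c", mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- Inf
    for (u in seq_len(m)) {
      bit <- 2^(u - 1)
      if (bitwAnd(mask, bit) > 0) next
      best <- min(
        best,
        1L + paths_open(mask + bit, bk[u]),
        1L + paths_open(mask + bit, fr[u])
      )
    }
    memo[[key]] <- best
    best
  }
  paths_open <- function(mask, w) {
    if (mask == full) return(0L)
    key <- paste0("o", mask, ",", w)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- paths_closed(mask)  # close the open path here
    for (u in seq_len(m)) {
      bit <- 2^(u - 1)
      if (bitwAnd(mask, bit) > 0) next
      if (fr[u] == w) best <- min(best, paths_open(mask + bit, bk[u]))
      if (bk[u] == w) best <- min(best, paths_open(mask + bit, fr[u]))
    }
    memo[[key]] <- best
    best
  }
  as.integer(paths_closed(0))
}

#' Exhaustive minimum run count of a collection
#'
#' Minimum concatenated-run count over all `m! * 2^m` signed orderings
#' of the strings (order and orientation are the only degrees of
#' freedom; strings are atomic). Refuses collections with more than
#' `max_m` strings.
#'
#' @param coll an [spss_collection()].
#' @param max_m size guard for the exhaustive search.
#' @return the exact minimum run count.
#' @export
oracle_min_runs <- function(coll, max_m = 8L) {
  stopifnot(inherits(coll, "spss_collection"))
  m <- length(coll$strings)
  if (m > max_m) stop("collection too large for exhaustive search", call. = FALSE)
  if (!m) return(0L)
  runs <- vapply(coll$strings, function(s) length(rle(s$weights)$lengths),
                 integer(1L))
  fr <- vapply(coll$strings, function(s) s$weights[1L], integer(1L))
  bk <- vapply(coll$strings, function(s) s$weights[length(s$weights)],
               integer(1L))
  memo <- new.env(hash = TRUE, parent = emptyenv())
  full <- 2^m - 1
  # g(mask, w): min runs contributed by the remaining strings, given the
  # previous string ends with weight w (0 = no previous string)
  g <- function(mask, w) {
    if (mask == full) return(0L)
    key <- paste0(mask, ",", w)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- Inf
    for (u in seq_len(m)) {
      bit <- 2^(u - 1)
      if (bitwAnd(mask, bit) > 0) next
      # forward orientation
      best <- min(best, runs[u] - (fr[u] == w) + g(mask + bit, bk[u]))
      # reverse-complemented orientation
      best <- min(best, runs[u] - (bk[u] == w) + g(mask + bit, fr[u]))
    }
    memo[[key]] <- best
    best
  }
  as.integer(g(0, 0L))
}
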