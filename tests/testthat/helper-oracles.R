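# Independent oracles and checkers shared across the suite. These stay
# deliberately naive: enumeration, linear scans and generic graph
# routines, so they cannot share a bug with the implementation paths
# they validate.

# all permutations of a vector (tiny inputs only)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[[i]], rest)
  }
  out
}

# literal enumeration over every ordering and orientation of the
# strings: minimum concatenated run count (m <= 5)
brute_min_runs_enum <- function(coll) {
  m <- length(coll$strings)
  stopifnot(m <= 5L)
  if (!m) return(0L)
  best <- Inf
  for (ord in all_perms(seq_len(m))) {
    for (mask in 0:(2^m - 1L)) {
      W <- integer(0L)
      for (j in seq_len(m)) {
        w <- coll$strings[[ord[j]]]$weights
        if (bitwAnd(mask, 2^(j - 1L)) > 0) w <- rev(w)
        W <- c(W, w)
      }
      best <- min(best, length(rle(W)$lengths))
    }
  }
  as.integer(best)
}

# literal enumeration: minimum number of maximal glued chains over all
# signed orderings of the nodes (m <= 5)
brute_min_cover_enum <- function(nodes) {
  m <- nrow(nodes)
  stopifnot(m <= 5L)
  if (!m) return(0L)
  best <- Inf
  for (ord in all_perms(seq_len(m))) {
    for (mask in 0:(2^m - 1L)) {
      chains <- 1L
      prev_back <- NULL
      for (j in seq_len(m)) {
        u <- ord[j]
        f <- nodes$front[u]; b <- nodes$back[u]
        if (bitwAnd(mask, 2^(j - 1L)) > 0) { tmp <- f; f <- b; b <- tmp }
        if (!is.null(prev_back) && prev_back != f) chains <- chains + 1L
        prev_back <- b
      }
      best <- min(best, chains)
    }
  }
  as.integer(best)
}

# |C_even| + |W_odd| / 2 computed from the simplified graph with
# generic tools (igraph components, plain frequency tables)
theorem1_size <- function(nodes) {
  if (!nrow(nodes)) return(0L)
  eps <- preprocess_nodes(nodes)$endpoints
  mm <- nrow(eps)
  freq <- table(c(eps$front, eps$back))
  w_odd <- as.integer(names(freq))[freq %% 2L == 1L]
  ed <- data.frame(
    from = rep(paste0("n", seq_len(mm)), 2L),
    to = c(paste0("w", eps$front), paste0("w", eps$back))
  )
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  memb <- igraph::components(g)$membership
  n_even_comp <- 0L
  for (comp in unique(memb[paste0("n", seq_len(mm))])) {
    wnames <- names(memb)[memb == comp & startsWith(names(memb), "w")]
    ws <- as.integer(sub("^w", "", wnames))
    if (all(freq[as.character(ws)] %% 2L == 0L)) {
      n_even_comp <- n_even_comp + 1L
    }
  }
  as.integer(n_even_comp + length(w_odd) / 2L)
}

# check that a path cover is valid for its collection: node-disjoint,
# complete, and every junction inside a path glued on equal weights
# (in the orientation given by the signs)
check_cover_valid <- function(cover, coll) {
  ids <- unlist(cover$paths)
  m <- length(coll$strings)
  expect_setequal(abs(ids), seq_len(m))
  expect_equal(anyDuplicated(abs(ids)), 0L)
  for (p in cover$paths) {
    ends <- lapply(p, function(sid) {
      w <- coll$strings[[abs(sid)]]$weights
      if (sid < 0L) w <- rev(w)
      c(w[1L], w[length(w)])
    })
    if (length(p) > 1L) {
      for (j in seq_len(length(p) - 1L)) {
        expect_equal(ends[[j]][2L], ends[[j + 1L]][1L])
      }
    }
  }
  invisible(TRUE)
}

# linear-scan predecessor over a plain vector
predecessor_scan <- function(values, x) {
  hits <- which(values <= x)
  if (!length(hits)) NA_integer_ else max(hits)
}

# full structural invariant check of a min-even tracker
check_tracker_invariants <- function(t) {
  st <- wkdict:::tracker_state(t)
  n <- length(st$key)
  expect_false(is.unsorted(st$value))
  # R must consist of exactly the blocks of equal values, plus the
  # (possibly empty) block of zeros starting at 1
  zeros <- sum(st$value == 0L)
  expected_R <- list(`0` = c(1L, zeros + 1L))
  for (v in unique(st$value[st$value > 0L])) {
    pos <- which(st$value == v)
    expected_R[[as.character(v)]] <- c(min(pos), max(pos) + 1L)
  }
  expect_setequal(names(st$R), names(expected_R))
  for (v in names(expected_R)) {
    expect_equal(unname(st$R[[v]]), unname(expected_R[[v]]),
                 label = paste("range of value", v))
  }
  # P consistent with A
  expect_equal(length(st$P), n)
  for (k in names(st$P)) {
    expect_equal(as.character(st$key[st$P[[k]]]), k)
  }
  invisible(TRUE)
}

# small weighted collections with hand-set weights (sequences generated
# to satisfy the SPSS property)
make_coll <- function(weight_sets, k = 5L, seed = 99L) {
  lens <- vapply(weight_sets, length, integer(1L)) + k - 1L
  set.seed(seed)
  # draw sequences until the canonical k-mer sets are all distinct
  for (try in 1:500) {
    coll <- try(
      gen_spss(length(weight_sets), len_range = rep(max(lens), 2L), k = k,
               seed = seed + try),
      silent = TRUE
    )
    if (inherits(coll, "try-error")) next
    strings <- lapply(seq_along(weight_sets), function(i) {
      list(seq = substr(coll$strings[[i]]$seq, 1L, lens[i]),
           weights = as.integer(weight_sets[[i]]))
    })
    out <- try(spss_collection(k, strings), silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
  }
  stop("could not build fixture collection")
}
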