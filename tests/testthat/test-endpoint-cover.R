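nodes_df <- function(...) {
  # build a node data.frame from (front, back) pairs
  pairs <- list(...)
  data.frame(
    id = seq_along(pairs),
    front = vapply(pairs, `[`, integer(1L), 1L),
    back = vapply(pairs, `[`, integer(1L), 2L),
    sign = rep(1L, length(pairs))
  )
}

test_that("endpoint_nodes normalises front <= back and records the flip", {
  coll <- make_coll(list(c(5L, 5L, 4L), 3L), k = 5L)
  nodes <- endpoint_nodes(coll)
  expect_equal(nodes$front[1], 4L)
  expect_equal(nodes$back[1], 5L)
  expect_equal(nodes$sign[1], -1L)
  expect_equal(nodes$front[2], 3L)  # single k-mer: front == back
  expect_equal(nodes$back[2], 3L)
  expect_equal(nodes$sign[2], 1L)
  expect_equal(nrow(nodes), 2L)
})

test_that("change_orientation flips end-points, sign, and expansion order", {
  u <- endpoint_node(3L, 2L, 7L)
  f <- change_orientation(u)
  expect_equal(f$front, 7L)
  expect_equal(f$back, 2L)
  expect_equal(f$sign, -1L)
  expect_equal(change_orientation(f), u)  # involution
  # merged node: reversal of the expansion with all signs negated
  p <- merge_nodes(endpoint_node(1L, 1L, 3L), endpoint_node(2L, 3L, 7L), 3L)
  expect_equal(expand_node(p), c(1L, 2L))
  expect_equal(expand_node(change_orientation(p)), c(-2L, -1L))
})

test_that("merge orients both operands on the shared weight", {
  p <- merge_nodes(endpoint_node(1L, 1L, 3L), endpoint_node(2L, 3L, 7L), 3L)
  expect_equal(c(p$front, p$back), c(1L, 7L))
  # first operand given as (3,1): it must be flipped to end in 3
  p2 <- merge_nodes(endpoint_node(1L, 3L, 1L), endpoint_node(2L, 3L, 7L), 3L)
  expect_equal(c(p2$front, p2$back), c(1L, 7L))
  expect_equal(expand_node(p2), c(-1L, 2L))
  # (x,w) merged with (w,x) closes into (x,x)
  p3 <- merge_nodes(endpoint_node(1L, 4L, 9L), endpoint_node(2L, 9L, 4L), 9L)
  expect_equal(c(p3$front, p3$back), c(4L, 4L))
  expect_error(merge_nodes(endpoint_node(1L, 1L, 2L),
                           endpoint_node(2L, 3L, 4L), 5L), "end-point")
})

test_that("the pooled engine agrees with the reference nodes on merges", {
  set.seed(101)
  for (rep in 1:20) {
    m <- sample(2:6, 1)
    fr <- sample(1:4, m, replace = TRUE)
    bk <- sample(1:4, m, replace = TRUE)
    eng <- wkdict:::.engine_new()
    ref <- list()
    for (i in 1:m) {
      eng$add(fr[i], bk[i], 1L, i)
      ref[[i]] <- endpoint_node(i, fr[i], bk[i])
    }
    # random sequence of valid merges mirrored on both representations
    live_eng <- seq_len(m)
    live_ref <- seq_len(m)
    while (length(live_eng) >= 2L) {
      a <- sample(seq_along(live_eng), 1L)
      others <- setdiff(seq_along(live_eng), a)
      b <- others[sample.int(length(others), 1L)]
      ia <- live_eng[a]; ib <- live_eng[b]
      ra <- ref[[live_ref[a]]]; rb <- ref[[live_ref[b]]]
      shared <- intersect(c(eng$front(ia), eng$back(ia)),
                          c(eng$front(ib), eng$back(ib)))
      if (!length(shared)) break
      w <- shared[1L]
      ip <- eng$merge(ia, ib, w)
      rp <- merge_nodes(ra, rb, w)
      ref[[length(ref) + 1L]] <- rp
      expect_equal(eng$expand(ip), expand_node(rp))
      expect_equal(c(eng$front(ip), eng$back(ip)), c(rp$front, rp$back))
      # occasionally flip the merged node on both sides
      if (runif(1) < 0.5) {
        eng$flip(ip)
        ref[[length(ref)]] <- change_orientation(rp)
        expect_equal(eng$expand(ip), expand_node(ref[[length(ref)]]))
      }
      live_eng <- c(live_eng[-c(a, b)], ip)
      live_ref <- c(live_ref[-c(a, b)], length(ref))
    }
  }
})

test_that("incidence sets count occurrences, with (x,x) nodes counted twice", {
  nodes <- nodes_df(c(1L, 3L), c(3L, 7L), c(3L, 3L))
  inc <- incidence_sets(nodes)
  i3 <- inc[inc$weight == 3L, ]
  expect_equal(i3$n, 4L)     # once in (1,3), once in (3,7), twice in (3,3)
  expect_equal(i3$size, 3L)
})

test_that("preprocess collapses duplicate pairs to at most two nodes", {
  # |E_{1,3}| = 4 -> two nodes (1,3); |E_{3,7}| = 3 -> one node (3,7)
  nodes <- nodes_df(c(1L, 3L), c(1L, 3L), c(1L, 3L), c(1L, 3L),
                    c(3L, 7L), c(3L, 7L), c(3L, 7L))
  pp <- preprocess_nodes(nodes)
  eps <- pp$endpoints
  expect_equal(sum(eps$front == 1L & eps$back == 3L), 2L)
  expect_equal(sum(eps$front == 3L & eps$back == 7L), 1L)
  # every original node appears exactly once over the expansions
  expect_setequal(abs(unlist(pp$expansions)), nodes$id)
  # two (x,x) nodes plus one (x,y): everything chains into one (x,y)
  nodes2 <- nodes_df(c(1L, 1L), c(1L, 1L), c(1L, 2L))
  pp2 <- preprocess_nodes(nodes2)
  expect_equal(nrow(pp2$endpoints), 1L)
  expect_equal(c(pp2$endpoints$front, pp2$endpoints$back), c(1L, 2L))
  expect_setequal(abs(pp2$expansions[[1L]]), 1:3)
  # a partnerless (x,x) chain stays as a complete component
  nodes3 <- nodes_df(c(4L, 4L), c(4L, 4L), c(4L, 4L))
  pp3 <- preprocess_nodes(nodes3)
  expect_equal(nrow(pp3$endpoints), 1L)
  expect_equal(pp3$endpoints$front, pp3$endpoints$back)
})

test_that("preprocessed expansions are glued paths over the original nodes", {
  set.seed(102)
  for (rep in 1:30) {
    m <- sample(1:12, 1)
    nodes <- gen_endpoint_nodes(m, n_weights = sample(1:4, 1), seed = rep)
    pp <- preprocess_nodes(nodes)
    expect_setequal(abs(unlist(pp$expansions)), nodes$id)
    # each simplified node is an oriented path: check junction gluing
    for (j in seq_along(pp$expansions)) {
      exp_ids <- pp$expansions[[j]]
      ends <- lapply(exp_ids, function(sid) {
        i <- which(nodes$id == abs(sid))
        e <- c(nodes$front[i], nodes$back[i])
        if (sid < 0L) rev(e) else e
      })
      if (length(ends) > 1L) {
        for (q in seq_len(length(ends) - 1L)) {
          expect_equal(ends[[q]][2L], ends[[q + 1L]][1L])
        }
      }
      expect_equal(ends[[1L]][1L], pp$endpoints$front[j])
      expect_equal(ends[[length(ends)]][2L], pp$endpoints$back[j])
    }
  }
})

test_that("merge-even reduces components per the even-frequency invariant", {
  # {(1,2),(2,3)} with freq(2) = 2: one merge, single node (1,3)
  out <- merge_even_nodes(nodes_df(c(1L, 2L), c(2L, 3L)))
  expect_equal(nrow(out$endpoints), 1L)
  expect_equal(c(out$endpoints$front, out$endpoints$back), c(1L, 3L))
  # {(1,2),(2,1)}: the closing merge yields a single (x,x) node
  out2 <- merge_even_nodes(nodes_df(c(1L, 2L), c(2L, 1L)))
  expect_equal(nrow(out2$endpoints), 1L)
  expect_equal(out2$endpoints$front, out2$endpoints$back)
  expect_setequal(abs(out2$expansions[[1L]]), 1:2)
  # property: afterwards each component is a single node, or no weight
  # of even (nonzero) frequency remains in it
  set.seed(103)
  for (rep in 1:40) {
    m <- sample(1:14, 1)
    nodes <- gen_endpoint_nodes(m, n_weights = sample(1:5, 1), seed = 200 + rep)
    out <- merge_even_nodes(nodes)
    expect_setequal(abs(unlist(out$expansions)), nodes$id)
    rem <- out$endpoints
    rem$id <- seq_len(nrow(rem))
    comp <- endpoint_components(rem)
    freq <- table(c(rem$front, rem$back))
    for (cc in unique(comp)) {
      members <- which(comp == cc)
      if (length(members) == 1L) next
      ws <- unique(c(rem$front[members], rem$back[members]))
      expect_true(all(freq[as.character(ws)] %% 2L == 1L))
    }
  }
})

test_that("greedy cover builds maximal paths; all-odd graphs need |W_odd|/2", {
  single <- greedy_cover(nodes_df(c(2L, 5L)))
  expect_equal(single$size, 1L)
  expect_equal(single$paths[[1L]], 1L)
  chain <- greedy_cover(nodes_df(c(1L, 2L), c(2L, 3L), c(3L, 4L)))
  expect_equal(chain$size, 1L)
  # random graphs whose simplified weights all have odd frequency
  set.seed(104)
  found <- 0L
  for (rep in 1:200) {
    m <- sample(1:8, 1)
    nodes <- gen_endpoint_nodes(m, n_weights = sample(2:6, 1), seed = 300 + rep)
    eps <- preprocess_nodes(nodes)$endpoints
    freq <- table(c(eps$front, eps$back))
    if (any(freq %% 2L == 0L)) next
    found <- found + 1L
    gc_ <- greedy_cover(nodes)
    expect_equal(gc_$size, as.integer(sum(freq %% 2L == 1L) / 2L))
  }
  expect_gte(found, 10L)
})

test_that("min_cover matches the exhaustive optimum and the parity formula", {
  empty <- min_cover(data.frame(id = integer(0), front = integer(0),
                                back = integer(0)))
  expect_equal(empty$size, 0L)
  set.seed(105)
  for (rep in 1:100) {
    m <- sample(0:7, 1)
    nodes <- gen_endpoint_nodes(m, n_weights = sample(1:6, 1), seed = 400 + rep)
    mc <- min_cover(nodes)
    expect_equal(mc$size, oracle_min_cover_size(nodes))
    expect_equal(mc$size, theorem1_size(nodes))
    # odd-frequency weights of the simplified graph come in pairs
    eps <- preprocess_nodes(nodes)$endpoints
    if (nrow(eps)) {
      freq <- table(c(eps$front, eps$back))
      expect_equal(sum(freq %% 2L == 1L) %% 2L, 0)
    }
  }
})

test_that("exhaustive oracles agree with literal enumeration on tiny inputs", {
  set.seed(106)
  for (rep in 1:15) {
    m <- sample(1:4, 1)
    nodes <- gen_endpoint_nodes(m, n_weights = sample(1:4, 1), seed = 500 + rep)
    expect_equal(oracle_min_cover_size(nodes), brute_min_cover_enum(nodes))
    coll <- gen_spss(m, len_range = c(8, 12), k = 6, p_change = 0.5,
                     max_weight = 3, seed = 600 + rep)
    expect_equal(oracle_min_runs(coll), brute_min_runs_enum(coll))
  }
  expect_error(oracle_min_cover_size(gen_endpoint_nodes(9, 3, 1)), "too large")
  expect_error(oracle_min_runs(gen_spss(9, k = 7, seed = 1)), "too large")
})

test_that("covers translate to the documented signed permutations", {
  expect_equal(cover_to_permutation(list(c(1L, -3L, 4L, 2L))),
               c(1L, 4L, -2L, 3L))
  expect_equal(cover_to_permutation(list(c(2L, -3L, 4L), 1L)),
               c(4L, 1L, -2L, 3L))
  expect_equal(cover_to_permutation(list(1L)), 1L)
  expect_error(cover_to_permutation(list(c(1L, 2L), 2L)), "exactly once")
  # inverse notation: position -> signed id
  pi <- c(1L, 4L, -2L, 3L)
  expect_equal(inverse_permutation(pi), c(1L, -3L, 4L, 2L))
  expect_equal(abs(inverse_permutation(inverse_permutation(pi))), abs(pi))
})

test_that("apply_permutation preserves content and realises the run identity", {
  coll <- gen_spss(5, len_range = c(9, 16), k = 6, p_change = 0.4,
                   max_weight = 4, seed = 107)
  m <- length(coll)
  expect_equal(apply_permutation(coll, seq_len(m))$strings, coll$strings)
  # all-negative identity: every string reverse-complemented in place
  flipped <- apply_permutation(coll, -seq_len(m))
  for (i in seq_len(m)) {
    expect_equal(flipped$strings[[i]]$seq,
                 reverse_complement(coll$strings[[i]]$seq))
    expect_equal(flipped$strings[[i]]$weights, rev(coll$strings[[i]]$weights))
  }
  pairs_of <- function(cc) {
    sort(unlist(lapply(cc$strings, function(s) {
      paste(canonical_kmer(kmer_stream(s$seq, cc$k))$kmer, s$weights)
    })))
  }
  expect_equal(pairs_of(flipped), pairs_of(coll))
  # run identity r = R - m + |C| on random collections
  set.seed(108)
  for (rep in 1:60) {
    coll <- gen_spss(m = sample(1:9, 1), len_range = c(8, 15), k = 6,
                     p_change = runif(1, 0.1, 0.9),
                     max_weight = sample(2:5, 1), seed = 700 + rep)
    rb <- count_runs(coll)
    res <- minimize_runs(coll)
    check_cover_valid(res$cover, coll)
    ra <- count_runs(res$coll)
    expect_equal(ra$r, rb$R - length(coll) + res$cover$size)
    expect_equal(pairs_of(res$coll), pairs_of(coll))
    # queries answered identically before and after permuting
    if (rep <= 5L) {
      d1 <- build_dictionary(coll)
      d2 <- build_dictionary(res$coll)
      qs <- unlist(lapply(coll$strings, function(s) kmer_stream(s$seq, 6L)))
      expect_equal(kmer_lookup(d2, qs)$weight, kmer_lookup(d1, qs)$weight)
    }
  }
})

test_that("count_runs separates per-string, total, and glued counts", {
  coll <- make_coll(list(c(2L, 2L, 3L)), k = 5L)
  cr <- count_runs(coll)
  expect_equal(cr$per_string, 2L)
  expect_equal(cr$R, 2L)
  expect_equal(cr$r, 2L)
  coll2 <- make_coll(list(c(1L, 4L), c(4L, 4L, 2L)), k = 5L)
  cr2 <- count_runs(coll2)
  expect_equal(cr2$R, 4L)
  expect_equal(cr2$r, 3L)  # junction 4|4 glues one run
  set.seed(109)
  for (rep in 1:20) {
    coll <- gen_spss(m = sample(1:6, 1), len_range = c(8, 14), k = 6,
                     p_change = 0.5, max_weight = 3, seed = 800 + rep)
    cr <- count_runs(coll)
    glue <- 0L
    for (i in seq_len(length(coll) - 1L)) {
      a <- coll$strings[[i]]$weights
      b <- coll$strings[[i + 1L]]$weights
      if (a[length(a)] == b[1L]) glue <- glue + 1L
    }
    expect_equal(cr$r, cr$R - glue)
  }
})

test_that("components agree with an independent graph library", {
  disjoint <- nodes_df(c(1L, 2L), c(5L, 6L))
  expect_equal(endpoint_components(disjoint), c(1L, 2L))
  chained <- nodes_df(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  expect_equal(endpoint_components(chained), c(1L, 1L, 1L))
  set.seed(110)
  for (rep in 1:30) {
    m <- sample(1:20, 1)
    nodes <- gen_endpoint_nodes(m, n_weights = sample(1:8, 1), seed = 900 + rep)
    comp <- endpoint_components(nodes)
    ed <- data.frame(
      from = rep(paste0("n", seq_len(m)), 2L),
      to = c(paste0("w", nodes$front), paste0("w", nodes$back))
    )
    g <- igraph::graph_from_data_frame(ed, directed = FALSE)
    memb <- igraph::components(g)$membership[paste0("n", seq_len(m))]
    # same partition, up to label names
    expect_equal(length(unique(comp)), length(unique(memb)))
    expect_true(all(tapply(memb, comp, function(v) length(unique(v))) == 1L))
  }
})

test_that("min_cover scales close to linearly in the number of nodes", {
  t_small <- system.time(
    min_cover(gen_endpoint_nodes(4000, n_weights = 500, seed = 1))
  )[["elapsed"]]
  t_large <- system.time(
    min_cover(gen_endpoint_nodes(16000, n_weights = 2000, seed = 1))
  )[["elapsed"]]
  # 4x the nodes; allow a wide margin over the ideal 4x for timer noise
  expect_lt(t_large, max(0.5, 25 * max(t_small, 0.02)))
})
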