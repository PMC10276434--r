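# Run minimisation via minimum path cover of the end-point weight graph.
#
# Only the first and last k-mer weight of each string (its end-point
# weights) decide whether runs can be glued at string junctions, so the
# collection is modelled as a graph with one node per string, labelled
# with its two end-points. A node-disjoint cover of this graph by
# oriented paths (each consecutive pair glued on a shared weight) yields
# a signed permutation of the strings, and the concatenated run count
# after permuting is R - m + |C|, with R the total per-string run count
# and |C| the number of paths. Minimising the run count is therefore
# minimising |C|.
#
# The optimal cover is computed in linear time in three phases:
#   preprocess   collapse all duplicate end-point pairs (chains built by
#                the parity argument) so no (x,x) node remains and every
#                pair occurs at most twice;
#   merge-even   repeatedly merge two nodes incident to the weight of
#                minimum even frequency (found in O(1) by the min-even
#                tracker) until every component is a single node or has
#                no even-frequency weight left;
#   greedy-cover grow maximal oriented paths from the remaining nodes;
#                with only odd-frequency weights left this uses exactly
#                |W_odd|/2 paths.
# The resulting cover has |C| = |C_even| + |W_odd|/2 paths, which is
# optimal (|C_even| = number of components whose weights all have even
# frequency).

## ---- reference node representation (recursive lists) -----------------

#' Create an end-point graph node
#'
#' The reference (list-based) node representation: a leaf stands for one
#' string, a merged node for an oriented path of strings. [min_cover()]
#' uses a flat pooled representation internally; this one is the simple
#' executable definition used in documentation and as a test oracle.
#'
#' @param id positive integer string id.
#' @param front,back the first and last k-mer weight of the string.
#' @param sign `+1` (keep) or `-1` (reverse complement).
#' @return object of class `endpoint_node`.
#' @export
endpoint_node <- function(id, front, back, sign = 1L) {
  stopifnot(sign %in% c(-1L, 1L))
  structure(
    list(id = as.integer(id), front = front, back = back,
         sign = as.integer(sign), children = NULL),
    class = "endpoint_node"
  )
}

#' Change the orientation of a node
#'
#' Swaps front and back and negates the sign; on a merged node the child
#' order is reversed and each child is flipped too, so the expansion is
#' reversed with all signs negated. Involutive.
#'
#' @param node an [endpoint_node()].
#' @return the flipped node.
#' @export
change_orientation <- function(node) {
  stopifnot(inherits(node, "endpoint_node"))
  out <- node
  out$front <- node$back
  out$back <- node$front
  out$sign <- -node$sign
  if (!is.null(node$children)) {
    out$children <- rev(lapply(node$children, change_orientation))
  }
  out
}

#' Merge two nodes on a shared end-point weight
#'
#' `u` is oriented so that `u$back == w` and `v` so that `v$front == w`;
#' the parent node has end-points `(u$front, v$back)` and expands to the
#' expansion of `u` followed by the expansion of `v`.
#'
#' @param u,v [endpoint_node()]s, each with an end-point equal to `w`.
#' @param w the weight merged on.
#' @return the merged parent node.
#' @export
merge_nodes <- function(u, v, w) {
  if (u$back != w) {
    if (u$front != w) stop("u has no end-point equal to w", call. = FALSE)
    u <- change_orientation(u)
  }
  if (v$front != w) {
    if (v$back != w) stop("v has no end-point equal to w", call. = FALSE)
    v <- change_orientation(v)
  }
  p <- endpoint_node(0L, u$front, v$back)
  p$children <- list(u, v)
  p
}

#' Expand a node to its signed string ids
#'
#' @param node an [endpoint_node()].
#' @return integer vector of signed ids, in path order.
#' @export
expand_node <- function(node) {
  stopifnot(inherits(node, "endpoint_node"))
  if (is.null(node$children)) return(node$sign * node$id)
  unlist(lapply(node$children, expand_node), use.names = FALSE)
}

## ---- graph construction over data frames ------------------------------

#' End-point weight graph nodes of a collection
#'
#' One node per string with `front` / `back` equal to the string's first
#' and last k-mer weight and sign `+1`, then normalised so that
#' `front <= back` (recording the flip in the sign).
#'
#' @param coll an [spss_collection()].
#' @return data.frame with columns `id`, `front`, `back`, `sign`.
#' @export
endpoint_nodes <- function(coll) {
  stopifnot(inherits(coll, "spss_collection"))
  m <- length(coll$strings)
  front <- vapply(coll$strings, function(s) s$weights[1L], integer(1L))
  back <- vapply(coll$strings, function(s) s$weights[length(s$weights)],
                 integer(1L))
  normalize_nodes(
    data.frame(id = seq_len(m), front = front, back = back,
               sign = rep(1L, m))
  )
}

#' Normalise end-point nodes
#'
#' Flips every node with `front > back` (swapping the two weights and
#' negating the sign) so that `front <= back` throughout.
#'
#' @param nodes data.frame with columns `id`, `front`, `back` and
#'   optionally `sign` (defaults to `+1`).
#' @return the normalised data.frame.
#' @export
normalize_nodes <- function(nodes) {
  stopifnot(is.data.frame(nodes), all(c("id", "front", "back") %in% names(nodes)))
  if (is.null(nodes$sign)) nodes$sign <- rep(1L, nrow(nodes))
  if (anyDuplicated(nodes$id)) stop("node ids must be distinct", call. = FALSE)
  flip <- nodes$front > nodes$back
  if (any(flip)) {
    tmp <- nodes$front[flip]
    nodes$front[flip] <- nodes$back[flip]
    nodes$back[flip] <- tmp
    nodes$sign[flip] <- -nodes$sign[flip]
  }
  nodes
}

#' Incidence sets of the end-point weights
#'
#' For every distinct weight `w`, `size` is the number of nodes with `w`
#' as an end-point (`|I_w|`) and `n` the number of times `w` occurs over
#' those nodes (`n(I_w)`; a node `(w, w)` counts twice).
#'
#' @param nodes data.frame of end-point nodes.
#' @return data.frame with columns `weight`, `n`, `size`, sorted by
#'   weight.
#' @export
incidence_sets <- function(nodes) {
  ws <- sort(unique(c(nodes$front, nodes$back)))
  n <- vapply(ws, function(w) {
    sum(nodes$front == w) + sum(nodes$back == w)
  }, integer(1L))
  size <- vapply(ws, function(w) {
    sum(nodes$front == w | nodes$back == w)
  }, integer(1L))
  data.frame(weight = ws, n = n, size = size)
}

#' Connected components of the end-point weight graph
#'
#' Two nodes are connected when they share an end-point weight.
#'
#' @param nodes data.frame of end-point nodes.
#' @return integer vector of component labels (1-based, dense, in order
#'   of first appearance), one per node.
#' @export
endpoint_components <- function(nodes) {
  m <- nrow(nodes)
  if (!m) return(integer(0L))
  ws <- unique(c(nodes$front, nodes$back))
  parent <- seq_along(ws)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  fi <- match(nodes$front, ws)
  bi <- match(nodes$back, ws)
  for (i in seq_len(m)) {
    ra <- find(fi[i]); rb <- find(bi[i])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(fi, find, integer(1L))
  match(roots, unique(roots))
}

## ---- pooled node engine -------------------------------------------------
## Flat arrays of nodes held in a closure (element writes on closure
## variables are in-place; the same writes through an environment would
## copy the whole vector on every assignment). Merged nodes reference
## their children by index; changing orientation is O(1) and lazy for
## children: a negative sign on a merged node means its expansion is
## reversed with all signs negated.
##
## On top of the node pool the closure keeps the algorithm state:
##   I   per-weight insertion-ordered incidence lists (intrusive linked
##       lists over the two membership weights of each node, with lazy
##       deletion), plus alive counts;
##   U   the queue of nodes not yet placed into a path.

.engine_new <- function(cap = 16L) {
  cap <- max(cap, 16L)
  fr <- integer(cap); bk <- integer(cap); sg <- integer(cap)
  nid <- integer(cap); lf <- integer(cap); rt <- integer(cap)
  alive <- logical(cap)
  pw1 <- integer(cap); pw2 <- integer(cap)   # membership weights in I (0 = not in I)
  nx1 <- integer(cap); nx2 <- integer(cap)   # per-weight list successors
  len <- 0L
  I <- new.env(hash = TRUE, parent = emptyenv())  # weight -> c(head, tail, alive count)
  uq <- integer(cap); u_head <- 1L; u_tail <- 0L

  grow <- function() {
    fr <<- c(fr, integer(length(fr))); bk <<- c(bk, integer(length(bk)))
    sg <<- c(sg, integer(length(sg))); nid <<- c(nid, integer(length(nid)))
    lf <<- c(lf, integer(length(lf))); rt <<- c(rt, integer(length(rt)))
    alive <<- c(alive, logical(length(alive)))
    pw1 <<- c(pw1, integer(length(pw1))); pw2 <<- c(pw2, integer(length(pw2)))
    nx1 <<- c(nx1, integer(length(nx1))); nx2 <<- c(nx2, integer(length(nx2)))
  }

  add <- function(f, b, s, id0, l = 0L, r = 0L) {
    if (len == length(fr)) grow()
    i <- len + 1L
    len <<- i
    fr[i] <<- f; bk[i] <<- b; sg[i] <<- s; nid[i] <<- id0
    lf[i] <<- l; rt[i] <<- r
    alive[i] <<- FALSE; pw1[i] <<- 0L; pw2[i] <<- 0L
    nx1[i] <<- 0L; nx2[i] <<- 0L
    i
  }

  flip <- function(i) {
    tmp <- fr[i]
    fr[i] <<- bk[i]; bk[i] <<- tmp
    sg[i] <<- -sg[i]
    invisible(i)
  }

  # merge on weight w: orient u.back = w and v.front = w, add parent
  merge <- function(u, v, w) {
    if (bk[u] != w) {
      if (fr[u] != w) stop("merge: u has no end-point w", call. = FALSE)
      flip(u)
    }
    if (fr[v] != w) {
      if (bk[v] != w) stop("merge: v has no end-point w", call. = FALSE)
      flip(v)
    }
    add(fr[u], bk[v], 1L, 0L, u, v)
  }

  ilist_append <- function(w, i) {
    key <- as.character(w)
    e <- I[[key]]
    if (is.null(e)) {
      I[[key]] <- c(i, i, 1L)
    } else {
      t <- e[2L]
      if (pw1[t] == w) nx1[t] <<- i else nx2[t] <<- i
      I[[key]] <- c(e[1L], i, e[3L] + 1L)
    }
  }

  insert <- function(i, in_I = TRUE) {
    alive[i] <<- TRUE
    if (u_tail == length(uq)) uq <<- c(uq, integer(length(uq)))
    u_tail <<- u_tail + 1L
    uq[u_tail] <<- i
    if (in_I) {
      a <- fr[i]; b <- bk[i]
      if (a == b) stop("internal: (x,x) node inserted into I", call. = FALSE)
      pw1[i] <<- a; pw2[i] <<- b
      ilist_append(a, i)
      ilist_append(b, i)
    }
    invisible(i)
  }

  erase <- function(i) {
    alive[i] <<- FALSE
    if (pw1[i] != 0L) {
      for (w in c(pw1[i], pw2[i])) {
        key <- as.character(w)
        e <- I[[key]]
        I[[key]] <- c(e[1L], e[2L], e[3L] - 1L)
      }
    }
    invisible(i)
  }

  icount <- function(w) {
    e <- I[[as.character(w)]]
    if (is.null(e)) 0L else e[3L]
  }

  # earliest-inserted alive node with end-point w, or 0L; does not erase
  ipop <- function(w) {
    key <- as.character(w)
    e <- I[[key]]
    if (is.null(e) || e[3L] == 0L) return(0L)
    h <- e[1L]
    while (h != 0L && !alive[h]) {
      h <- if (pw1[h] == w) nx1[h] else nx2[h]
    }
    I[[key]] <- c(h, e[2L], e[3L])
    h
  }

  upop <- function() {
    while (u_head <= u_tail && !alive[uq[u_head]]) u_head <<- u_head + 1L
    if (u_head > u_tail) 0L else uq[u_head]
  }

  # iterative expansion to signed leaf ids (explicit stack: merged
  # chains can be as deep as the number of strings)
  expand <- function(i) {
    out <- integer(16L); no <- 0L
    sn <- integer(64L); sf <- logical(64L)
    sp <- 1L; sn[1L] <- i; sf[1L] <- FALSE
    while (sp > 0L) {
      node <- sn[sp]; f <- sf[sp]; sp <- sp - 1L
      if (lf[node] == 0L) {
        if (no == length(out)) out <- c(out, integer(length(out)))
        no <- no + 1L
        out[no] <- if (f) -sg[node] * nid[node] else sg[node] * nid[node]
      } else {
        g <- xor(f, sg[node] < 0L)
        if (sp + 2L > length(sn)) {
          sn <- c(sn, integer(length(sn)))
          sf <- c(sf, logical(length(sf)))
        }
        # pushed in reverse of emit order; a flipped node emits its
        # right child (flipped) before its left child (flipped)
        if (!g) {
          sn[sp + 1L] <- rt[node]; sf[sp + 1L] <- FALSE
          sn[sp + 2L] <- lf[node]; sf[sp + 2L] <- FALSE
        } else {
          sn[sp + 1L] <- lf[node]; sf[sp + 1L] <- TRUE
          sn[sp + 2L] <- rt[node]; sf[sp + 2L] <- TRUE
        }
        sp <- sp + 2L
      }
    }
    out[seq_len(no)]
  }

  list(
    add = add, flip = flip, merge = merge,
    insert = insert, erase = erase,
    icount = icount, ipop = ipop, upop = upop,
    expand = expand,
    front = function(i) fr[i],
    back = function(i) bk[i],
    node_sign = function(i) sg[i],
    is_leaf = function(i) lf[i] == 0L,
    size = function() len,
    alive_nodes = function() which(alive[seq_len(len)]),
    iweights = function() as.integer(sort(as.numeric(ls(I))))
  )
}

## ---- preprocess -----------------------------------------------------------

# Collapse duplicate end-point pairs. Returns the engine and the root
# indices of the simplified nodes. Roots with front == back are complete
# components (their weight occurs nowhere else).
.preprocess_engine <- function(nodes) {
  nodes <- normalize_nodes(nodes)
  m <- nrow(nodes)
  eng <- .engine_new(4L * m + 8L)
  for (i in seq_len(m)) {
    eng$add(nodes$front[i], nodes$back[i], nodes$sign[i], nodes$id[i])
  }
  groups <- new.env(hash = TRUE, parent = emptyenv())
  keys <- paste(nodes$front, nodes$back, sep = ",")
  for (i in seq_len(m)) groups[[keys[i]]] <- c(groups[[keys[i]]], i)
  pairs <- unique(data.frame(x = nodes$front, y = nodes$back))
  pairs <- pairs[order(pairs$x, pairs$y), , drop = FALSE]
  roots <- integer(m); nr <- 0L
  push_root <- function(i) { nr <<- nr + 1L; roots[nr] <<- i }

  # (x,x) groups first, ascending x: chain on x, then attach to the
  # lexicographically smallest available partner pair containing x
  selfp <- pairs[pairs$x == pairs$y, , drop = FALSE]
  for (x in selfp$x) {
    key <- paste(x, x, sep = ",")
    idx <- groups[[key]]
    groups[[key]] <- NULL
    acc <- idx[1L]
    for (j in idx[-1L]) acc <- eng$merge(acc, j, x)
    partners <- pairs[(pairs$x == x | pairs$y == x) & pairs$x != pairs$y, ,
                      drop = FALSE]
    partner_key <- NULL
    for (pr in seq_len(nrow(partners))) {
      cand <- paste(partners$x[pr], partners$y[pr], sep = ",")
      if (length(groups[[cand]])) { partner_key <- cand; break }
    }
    if (is.null(partner_key)) {
      push_root(acc)  # complete (x,x) component
    } else {
      g <- groups[[partner_key]]
      comp <- eng$merge(acc, g[1L], x)
      if (eng$front(comp) > eng$back(comp)) eng$flip(comp)
      groups[[partner_key]] <- c(g[-1L], comp)
    }
  }

  # (x,y) groups, x < y, in sorted pair order: one chain if odd-sized,
  # a chain of all but one plus the untouched last node if even-sized
  mixp <- pairs[pairs$x != pairs$y, , drop = FALSE]
  for (pr in seq_len(nrow(mixp))) {
    key <- paste(mixp$x[pr], mixp$y[pr], sep = ",")
    idx <- groups[[key]]
    if (!length(idx)) next
    groups[[key]] <- NULL
    d <- length(idx)
    last <- if (d %% 2L == 0L) idx[d] else 0L
    upto <- if (d %% 2L == 0L) d - 1L else d
    acc <- idx[1L]
    if (upto > 1L) {
      for (j in idx[2:upto]) acc <- eng$merge(acc, j, eng$back(acc))
    }
    if (eng$front(acc) > eng$back(acc)) eng$flip(acc)
    push_root(acc)
    if (last != 0L) push_root(last)
  }
  list(eng = eng, roots = roots[seq_len(nr)])
}

#' Simplify an end-point graph by collapsing duplicate pairs
#'
#' All nodes with equal end-points `(x, x)` are chained into a single
#' node and attached to a partner `(x, y)` node when one exists; each
#' remaining duplicate set `E_{x,y}` is chained into one node when its
#' size is odd, or into a chain of all but one plus the untouched last
#' node when even. Afterwards no `(x, x)` node remains (except complete
#' single-node components) and every end-point pair occurs at most
#' twice.
#'
#' @param nodes data.frame of end-point nodes (`id`, `front`, `back`,
#'   optional `sign`).
#' @return object of class `endpoint_preprocess` with `$endpoints` (a
#'   data.frame of the simplified nodes' end-point pairs) and
#'   `$expansions` (list of signed-id vectors, one per simplified node).
#' @export
preprocess_nodes <- function(nodes) {
  pp <- .preprocess_engine(nodes)
  eps <- data.frame(
    front = vapply(pp$roots, pp$eng$front, integer(1L)),
    back = vapply(pp$roots, pp$eng$back, integer(1L))
  )
  structure(
    list(
      endpoints = eps,
      expansions = lapply(pp$roots, pp$eng$expand)
    ),
    class = "endpoint_preprocess"
  )
}

#' @export
print.endpoint_preprocess <- function(x, ...) {
  cat(
    "Simplified end-point graph:", nrow(x$endpoints), "nodes covering",
    sum(lengths(x$expansions)), "strings\n"
  )
  invisible(x)
}

## ---- merge-even ------------------------------------------------------------

# Insert preprocessed roots into the state and build the tracker over
# the even-frequency weights.
.state_prepare <- function(pp) {
  eng <- pp$eng
  for (i in pp$roots) eng$insert(i, in_I = eng$front(i) != eng$back(i))
  ws <- eng$iweights()
  cnts <- vapply(ws, eng$icount, integer(1L))
  even <- cnts %% 2L == 0L & cnts >= 2L
  min_even_tracker(ws[even], cnts[even])
}

# The even-frequency merging phase. tr is the min-even tracker over the
# even-frequency weights; its values mirror the alive incidence counts.
.merge_even_run <- function(eng, tr) {
  has_key <- function(x) !is.null(tr$P[[as.character(x)]])
  while (tracker_has_next(tr)) {
    wstar <- tracker_min_key(tr)
    u <- eng$ipop(wstar)
    if (u == 0L) stop("internal: empty incidence set for tracked weight",
                      call. = FALSE)
    eng$erase(u)
    v <- eng$ipop(wstar)
    if (v == 0L) stop("internal: singleton incidence set for tracked weight",
                      call. = FALSE)
    eng$erase(v)
    tracker_decrease(tr, wstar)
    p <- eng$merge(u, v, wstar)
    if (eng$front(p) == eng$back(p)) {
      x <- eng$front(p)
      q <- eng$ipop(x)
      if (q != 0L) {
        eng$erase(q)
        p2 <- eng$merge(p, q, x)
        eng$insert(p2, in_I = TRUE)
      } else {
        # the component is complete: the (x,x) node is kept for the
        # cover but x occurs nowhere else, so zero its frequency
        eng$insert(p, in_I = FALSE)
      }
      if (has_key(x)) tracker_decrease(tr, x)
    } else {
      eng$insert(p, in_I = TRUE)
    }
  }
  invisible(eng)
}

#' Run the even-frequency merging phase
#'
#' Exposed for inspection and testing; [min_cover()] runs it internally.
#' After this phase every connected component of the simplified graph is
#' either a single node or contains no weight of (nonzero) even
#' frequency.
#'
#' @param nodes data.frame of end-point nodes.
#' @return list with `endpoints` (data.frame of remaining nodes'
#'   end-point pairs) and `expansions` (signed-id vectors per remaining
#'   node).
#' @export
merge_even_nodes <- function(nodes) {
  pp <- .preprocess_engine(nodes)
  tr <- .state_prepare(pp)
  .merge_even_run(pp$eng, tr)
  alive <- pp$eng$alive_nodes()
  list(
    endpoints = data.frame(
      front = vapply(alive, pp$eng$front, integer(1L)),
      back = vapply(alive, pp$eng$back, integer(1L))
    ),
    expansions = lapply(alive, pp$eng$expand)
  )
}

## ---- greedy cover -----------------------------------------------------------

# Maximal-path greedy cover over the current state; returns a list of
# vectors of node indices (orientations already applied in the engine).
.greedy_run <- function(eng) {
  paths <- list()
  np <- 0L
  repeat {
    u <- eng$upop()
    if (u == 0L) break
    eng$erase(u)
    bpart <- integer(8L); nb <- 1L; bpart[1L] <- u
    fpart <- integer(4L); nf <- 0L
    first <- u; last <- u
    repeat {
      v <- eng$ipop(eng$back(last))
      if (v != 0L) {
        eng$erase(v)
        if (eng$front(v) != eng$back(last)) eng$flip(v)
        if (nb == length(bpart)) bpart <- c(bpart, integer(length(bpart)))
        nb <- nb + 1L
        bpart[nb] <- v
        last <- v
        next
      }
      v <- eng$ipop(eng$front(first))
      if (v != 0L) {
        eng$erase(v)
        if (eng$back(v) != eng$front(first)) eng$flip(v)
        if (nf == length(fpart)) fpart <- c(fpart, integer(length(fpart)))
        nf <- nf + 1L
        fpart[nf] <- v
        first <- v
        next
      }
      break
    }
    np <- np + 1L
    paths[[np]] <- c(rev(fpart[seq_len(nf)]), bpart[seq_len(nb)])
  }
  paths
}

.as_path_cover <- function(eng, raw_paths, m) {
  paths <- lapply(raw_paths, function(idx) {
    unlist(lapply(idx, eng$expand), use.names = FALSE)
  })
  structure(
    list(paths = paths, size = length(paths), m = m),
    class = "path_cover"
  )
}

#' Greedy maximal-path cover
#'
#' Starts a path from each not-yet-covered node and extends it greedily
#' (back end first) while some unused node matches one of its end-point
#' weights. On a simplified graph whose weights all have odd frequency
#' this produces exactly `|W_odd| / 2` paths, which is optimal there;
#' [min_cover()] should be used for the general case.
#'
#' @param nodes data.frame of end-point nodes.
#' @return a `path_cover` object (see [min_cover()]).
#' @export
greedy_cover <- function(nodes) {
  pp <- .preprocess_engine(nodes)
  eng <- pp$eng
  for (i in pp$roots) eng$insert(i, in_I = eng$front(i) != eng$back(i))
  raw <- .greedy_run(eng)
  .as_path_cover(eng, raw, nrow(nodes))
}

#' @export
print.path_cover <- function(x, ...) {
  cat("Path cover:", x$size, "paths over", x$m, "nodes\n")
  if (x$size && x$m <= 20L) {
    for (p in x$paths) {
      cat("  (", paste(sprintf("%+d", p), collapse = " -> "), ")\n", sep = "")
    }
  }
  invisible(x)
}

## ---- min-cover ----------------------------------------------------------------

#' Minimum-cardinality path cover of an end-point weight graph
#'
#' Computes an optimal cover in time linear in the number of nodes:
#' preprocess (collapse duplicate pairs), merge-even (driven by the
#' min-even tracker) and greedy-cover. The cover size equals
#' `|C_even| + |W_odd| / 2`, where `C_even` is the set of connected
#' components all of whose weights have even frequency and `W_odd` the
#' set of odd-frequency weights of the simplified graph.
#'
#' @param nodes data.frame of end-point nodes (`id`, `front`, `back`,
#'   optional `sign`), or an [spss_collection()] (its
#'   [endpoint_nodes()] are used).
#' @return object of class `path_cover`: `paths` is a list of signed-id
#'   vectors (each an oriented path, every input id appearing exactly
#'   once over all paths), `size` the number of paths, `m` the number of
#'   nodes.
#' @export
min_cover <- function(nodes) {
  if (inherits(nodes, "spss_collection")) nodes <- endpoint_nodes(nodes)
  m <- nrow(nodes)
  if (!m) {
    return(structure(list(paths = list(), size = 0L, m = 0L),
                     class = "path_cover"))
  }
  pp <- .preprocess_engine(nodes)
  tr <- .state_prepare(pp)
  .merge_even_run(pp$eng, tr)
  raw <- .greedy_run(pp$eng)
  .as_path_cover(pp$eng, raw, m)
}

## ---- cover -> permutation -> collection -----------------------------------------

#' Signed permutation from a path cover
#'
#' Walks the cover path by path, node by node, assigning consecutive
#' positions; `pi[id]` is the signed new position of string `id` (the
#' sign says whether the string must be reverse-complemented, with its
#' weights reversed).
#'
#' @param cover a `path_cover`, or a plain list of signed-id vectors.
#' @return integer vector `pi` indexed by string id.
#' @examples
#' cover_to_permutation(list(c(1L, -3L, 4L, 2L)))
#' # pi[1] = +1, pi[3] = -2, pi[4] = +3, pi[2] = +4
#' @export
cover_to_permutation <- function(cover) {
  paths <- if (inherits(cover, "path_cover")) cover$paths else cover
  ids <- unlist(paths, use.names = FALSE)
  m <- length(ids)
  if (!m) return(integer(0L))
  if (anyDuplicated(abs(ids)) || !setequal(abs(ids), seq_len(m))) {
    stop("cover must contain each id exactly once", call. = FALSE)
  }
  pi <- integer(m)
  pos <- 0L
  for (p in paths) {
    for (sid in p) {
      pos <- pos + 1L
      pi[abs(sid)] <- if (sid < 0L) -pos else pos
    }
  }
  pi
}

#' Invert a signed permutation
#'
#' Converts between the two notations: from `pi[id] = signed position`
#' to `q[position] = signed id` (and back, as the operation is its own
#' inverse).
#'
#' @param pi signed permutation vector.
#' @return the inverse notation.
#' @export
inverse_permutation <- function(pi) {
  q <- integer(length(pi))
  for (id in seq_along(pi)) {
    q[abs(pi[id])] <- if (pi[id] < 0L) -id else id
  }
  q
}

#' Apply a signed permutation to a collection
#'
#' String `id` is moved to position `abs(pi[id])`; when `pi[id] < 0` the
#' sequence is replaced by its reverse complement and its weights are
#' reversed. The multiset of (canonical k-mer, weight) pairs is
#' unchanged.
#'
#' @param coll an [spss_collection()].
#' @param pi signed permutation, as from [cover_to_permutation()].
#' @return the permuted [spss_collection()].
#' @export
apply_permutation <- function(coll, pi) {
  stopifnot(inherits(coll, "spss_collection"))
  m <- length(coll$strings)
  if (length(pi) != m || !setequal(abs(pi), seq_len(m))) {
    stop("pi must be a signed permutation of 1..m", call. = FALSE)
  }
  strings <- vector("list", m)
  for (id in seq_len(m)) {
    s <- coll$strings[[id]]
    if (pi[id] < 0L) {
      s <- list(seq = .rc_unchecked(s$seq), weights = rev(s$weights))
    }
    strings[[abs(pi[id])]] <- s
  }
  spss_collection(coll$k, strings, validate_spss = FALSE)
}

#' Minimise the number of weight runs of a collection
#'
#' Convenience wrapper: computes the optimal cover, converts it to a
#' signed permutation and applies it. The permuted collection has
#' exactly `R - m + |C|` concatenated runs.
#'
#' @param coll an [spss_collection()].
#' @return list with `coll` (the permuted collection), `pi`, `cover`.
#' @export
minimize_runs <- function(coll) {
  cover <- min_cover(coll)
  pi <- cover_to_permutation(cover)
  list(coll = apply_permutation(coll, pi), pi = pi, cover = cover)
}
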