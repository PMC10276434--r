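# The weighted k-mer dictionary: exact membership with rejection of
# alien k-mers, order-preserving hash codes 1..n, and weight retrieval
# through the run-length encoding. Codes are assigned by scanning the
# strings of the SPSS in collection order, k-mers left to right, so
# consecutive k-mers of a string receive consecutive codes -- the
# property that makes the weight sequence runs long.

#' Build a weighted dictionary from an SPSS collection
#'
#' @param coll an [spss_collection()]; its canonical k-mers must be
#'   pairwise distinct.
#' @return object of class `weighted_dictionary` with fields `k`, `n`,
#'   `m`, `index` (environment mapping canonical k-mer to hash code),
#'   `weights` (an `encoded_weights` object over the concatenated weight
#'   sequence), and `provenance` (per-code string id and offset).
#' @export
build_dictionary <- function(coll) {
  stopifnot(inherits(coll, "spss_collection"))
  k <- coll$k
  index <- new.env(hash = TRUE, parent = emptyenv())
  m <- length(coll$strings)
  n <- sum(vapply(coll$strings, function(s) length(s$weights), integer(1L)))
  prov_string <- integer(n)
  prov_offset <- integer(n)
  i <- 0L
  for (sid in seq_len(m)) {
    canon <- .canonical_stream(coll$strings[[sid]]$seq, k)
    for (off in seq_along(canon)) {
      g <- canon[[off]]
      if (!is.null(index[[g]])) {
        stop(
          "SPSS violation: canonical k-mer ", g,
          " occurs more than once; cannot build dictionary",
          call. = FALSE
        )
      }
      i <- i + 1L
      index[[g]] <- i
      prov_string[i] <- sid
      prov_offset[i] <- off
    }
  }
  W <- .flat_weights(coll)
  dict <- structure(
    list(
      k = k, n = n, m = m, index = index,
      weights = encode_weights(compute_runs(W)),
      provenance = data.frame(string = prov_string, offset = prov_offset)
    ),
    class = "weighted_dictionary"
  )
  # kept for serialisation: the index file stores the sequences and
  # rebuilds the associative map on load
  attr(dict, "source_seqs") <- lapply(coll$strings, `[[`, "seq")
  dict
}

#' @export
print.weighted_dictionary <- function(x, ...) {
  sp <- space_bits(x$weights)
  cat(
    "Weighted k-mer dictionary: k =", x$k, ", n =", x$n, "k-mers from",
    x$m, "strings;", length(x$weights$codes), "weight runs,",
    sprintf("%.3f", sp$total / x$n), "weight bits/k-mer\n"
  )
  invisible(x)
}

#' Query k-mers against a dictionary
#'
#' Each query is looked up in canonical form, so a k-mer and its reverse
#' complement give identical answers. Alien k-mers (valid length-k DNA
#' strings not in the index) get code 0 and weight `NA`; strings of the
#' wrong length or alphabet are an error, not an absence.
#'
#' @param dict a `weighted_dictionary`.
#' @param g character vector of query k-mers.
#' @return data.frame with columns `kmer`, `code` (0 when absent) and
#'   `weight` (`NA` when absent).
#' @export
kmer_lookup <- function(dict, g) {
  stopifnot(inherits(dict, "weighted_dictionary"))
  .check_dna(g, "query k-mer")
  if (length(g) && any(nchar(g) != dict$k)) {
    stop("query length must equal k = ", dict$k, call. = FALSE)
  }
  canon <- canonical_kmer(g)$kmer
  code <- vapply(canon, function(x) {
    v <- dict$index[[x]]
    if (is.null(v)) 0L else v
  }, integer(1L), USE.NAMES = FALSE)
  weight <- rep(NA_integer_, length(g))
  hit <- code > 0L
  if (any(hit)) weight[hit] <- lookup_weight(dict$weights, code[hit])
  data.frame(kmer = g, code = code, weight = weight, stringsAsFactors = FALSE)
}

## ---- serialisation ---------------------------------------------------
## Little-endian binary index file. Section layout:
##   magic "WKDICT01" (8 bytes)
##   k, n, m                    int32 x3
##   m string records           int32 length + ASCII bytes each
##   encoded weights:
##     r, |D|, n, max, code_width    int32 x5
##     D                             int32 x |D|
##     codes                         packed code_width-bit integers
##     L: r, universe, low_width     int32 x3
##        low bits                   packed low_width-bit integers
##        high bits                  packed bit vector (int32 bit count
##                                   then bytes, LSB-first)

.pack_bits <- function(bits) {
  # 0/1 integer vector -> raw, LSB-first within each byte
  nb <- length(bits)
  pad <- (8L - nb %% 8L) %% 8L
  b <- matrix(c(bits, integer(pad)), nrow = 8L)
  as.raw(colSums(b * 2L^(0:7)))
}

.unpack_bits <- function(raw, nbits) {
  bits <- as.integer(rawToBits(raw))
  bits[seq_len(nbits)]
}

.pack_fixed <- function(values, width) {
  # non-negative integers -> concatenated width-bit codes, LSB-first
  if (width == 0L || !length(values)) return(raw(0L))
  bits <- integer(length(values) * width)
  v <- values
  for (b in seq_len(width)) {
    bits[seq(b, by = width, length.out = length(values))] <- v %% 2L
    v <- v %/% 2L
  }
  .pack_bits(bits)
}

.unpack_fixed <- function(raw, width, count) {
  force(raw)  # raw may be a connection read that must happen regardless
  if (width == 0L) return(integer(count))
  bits <- .unpack_bits(raw, count * width)
  m <- matrix(bits, nrow = width)
  as.integer(colSums(m * 2L^(seq_len(width) - 1L)))
}

.write_int <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "little")

.read_int <- function(con, n = 1L) {
  v <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  if (length(v) != n) stop("corrupt index: unexpected end of file", call. = FALSE)
  v
}

.write_packed <- function(con, raw_vec) {
  .write_int(con, length(raw_vec))
  writeBin(raw_vec, con)
}

.read_packed <- function(con) {
  nb <- .read_int(con)
  v <- readBin(con, "raw", n = nb)
  if (length(v) != nb) stop("corrupt index: unexpected end of file", call. = FALSE)
  v
}

#' Save a dictionary index to disk
#'
#' The on-disk format is a little-endian binary layout with packed bit
#' sections, bit-exact across platforms.
#'
#' @param dict a `weighted_dictionary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_index <- function(dict, path) {
  stopifnot(inherits(dict, "weighted_dictionary"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("WKDICT01"), con)
  .write_int(con, c(dict$k, dict$n, dict$m))
  for (sid in seq_len(dict$m)) {
    s <- attr(dict, "source_seqs")[[sid]]
    .write_int(con, nchar(s))
    writeBin(charToRaw(s), con)
  }
  enc <- dict$weights
  .write_int(con, c(length(enc$codes), length(enc$D), enc$n, enc$max,
                    enc$code_width))
  .write_int(con, enc$D)
  .write_packed(con, .pack_fixed(enc$codes - 1L, enc$code_width))
  .write_int(con, c(enc$L$r, enc$L$universe, enc$L$low_width))
  .write_packed(con, .pack_fixed(enc$L$low, enc$L$low_width))
  .write_int(con, length(enc$L$high))
  .write_packed(con, .pack_bits(enc$L$high))
  invisible(path)
}

#' Load a dictionary index from disk
#'
#' @param path file written by [save_index()].
#' @return a `weighted_dictionary` answering all queries identically to
#'   the saved one.
#' @export
load_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (length(magic) != 8L || !identical(rawToChar(magic), "WKDICT01")) {
    stop("corrupt index: bad magic/version", call. = FALSE)
  }
  hdr <- .read_int(con, 3L)
  k <- hdr[1L]; n <- hdr[2L]; m <- hdr[3L]
  seqs <- character(m)
  for (sid in seq_len(m)) {
    len <- .read_int(con)
    b <- readBin(con, "raw", n = len)
    if (length(b) != len) stop("corrupt index: unexpected end of file", call. = FALSE)
    seqs[sid] <- rawToChar(b)
  }
  whdr <- .read_int(con, 5L)
  r <- whdr[1L]; nD <- whdr[2L]; wn <- whdr[3L]; wmax <- whdr[4L]
  code_width <- whdr[5L]
  D <- .read_int(con, nD)
  codes <- .unpack_fixed(.read_packed(con), code_width, r) + 1L
  lhdr <- .read_int(con, 3L)
  low <- .unpack_fixed(.read_packed(con), lhdr[3L], lhdr[1L])
  nhigh <- .read_int(con)
  high <- .unpack_bits(.read_packed(con), nhigh)
  L <- structure(
    list(r = lhdr[1L], universe = lhdr[2L], low_width = lhdr[3L],
         low = low, high = high, sel = which(high == 1L)),
    class = "elias_fano"
  )
  enc <- structure(
    list(D = D, code_width = code_width, codes = codes, L = L,
         n = wn, max = wmax),
    class = "encoded_weights"
  )
  # rebuild the associative map from the stored sequences
  index <- new.env(hash = TRUE, parent = emptyenv())
  prov_string <- integer(n)
  prov_offset <- integer(n)
  i <- 0L
  for (sid in seq_len(m)) {
    canon <- .canonical_stream(seqs[[sid]], k)
    for (off in seq_along(canon)) {
      i <- i + 1L
      index[[canon[[off]]]] <- i
      prov_string[i] <- sid
      prov_offset[i] <- off
    }
  }
  if (i != n) stop("corrupt index: k-mer count mismatch", call. = FALSE)
  dict <- structure(
    list(k = k, n = n, m = m, index = index, weights = enc,
         provenance = data.frame(string = prov_string, offset = prov_offset)),
    class = "weighted_dictionary"
  )
  attr(dict, "source_seqs") <- as.list(seqs)
  dict
}
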