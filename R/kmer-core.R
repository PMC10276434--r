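# Nucleotide and k-mer primitives shared by all modules.
#
# The alphabet is strictly {A,C,G,T}, uppercase. Lowercase or IUPAC
# ambiguity codes (including N) are rejected rather than silently
# normalised: the inputs this package consumes are spectrum-preserving
# string sets over the plain DNA alphabet, so anything else is a sign of
# a malformed file and should fail fast.

.check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || anyNA(x)) {
    stop(what, " must be a character vector without NAs", call. = FALSE)
  }
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(
      "invalid ", what, ": symbols outside {A,C,G,T} in ",
      dQuote(substr(x[bad][1L], 1L, 40L)),
      call. = FALSE
    )
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' Vectorised over `seq`. Only uppercase `A`, `C`, `G`, `T` are accepted;
#' any other symbol (including lowercase and `N`) is an error.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of the same length with each string reversed
#'   and base-complemented. The operation is an involution.
#' @examples
#' reverse_complement("ACG")  # "CGT"
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  comp <- chartr("ACGT", "TGCA", seq)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1L)
  )
}

# Same, without validation; for internal hot paths where the input has
# already been checked.
.rc_unchecked <- function(seq) {
  comp <- chartr("ACGT", "TGCA", seq)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1L)
  )
}

#' Canonical form of k-mers
#'
#' A k-mer and its reverse complement are treated as the same object; the
#' canonical representative is the lexicographically smaller of the two
#' orientations.
#'
#' @param g character vector of k-mers (all of the same length).
#' @return a data.frame with columns `kmer` (the canonical form) and
#'   `flipped` (`TRUE` when the input was not already canonical).
#' @examples
#' canonical_kmer(c("TTT", "ACG"))
#' @export
canonical_kmer <- function(g) {
  .check_dna(g, "k-mer")
  if (length(g) && length(unique(nchar(g))) > 1L) {
    stop("all k-mers must have the same length", call. = FALSE)
  }
  rc <- .rc_unchecked(g)
  flipped <- rc < g
  data.frame(
    kmer = ifelse(flipped, rc, g),
    flipped = flipped,
    stringsAsFactors = FALSE
  )
}

#' Enumerate the k-mers of a string
#'
#' Yields the `nchar(seq) - k + 1` consecutive k-mers of `seq` in
#' left-to-right order.
#'
#' @param seq a single DNA string.
#' @param k k-mer length, `>= 1`.
#' @return character vector of k-mers.
#' @examples
#' kmer_stream("ACGT", 3)  # "ACG" "CGT"
#' @export
kmer_stream <- function(seq, k) {
  stopifnot(length(seq) == 1L, is.numeric(k), k >= 1L)
  .check_dna(seq)
  n <- nchar(seq)
  if (n < k) {
    stop("sequence of length ", n, " is too short for k = ", k, call. = FALSE)
  }
  substring(seq, 1:(n - k + 1L), k:n)
}

# Canonical k-mers of a whole string, computed without per-k-mer reverse
# complementation: the reverse complements of the k-mers of `seq` are the
# k-mers of reverse_complement(seq), read right to left.
.canonical_stream <- function(seq, k) {
  n <- nchar(seq)
  fwd <- substring(seq, 1:(n - k + 1L), k:n)
  rcs <- .rc_unchecked(seq)
  rck <- rev(substring(rcs, 1:(n - k + 1L), k:n))
  ifelse(rck < fwd, rck, fwd)
}
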