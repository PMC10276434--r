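# Readers and writers for weighted SPSS files: FASTA where every record
# carries one abundance count per k-mer in its header. Two dialects:
#
#   bcalm-ab      header contains an `ab:Z:` tag followed by the
#                 space-separated counts (BCALM2 -all-abundance-counts
#                 convention), e.g. ">0 LN:i:36 ab:Z:2 2 3"
#   plain-counts  the header is exactly the space-separated counts,
#                 e.g. ">2 2 3"
#
# Reading goes through Biostrings::readBStringSet so line-wrapped records
# and gzip-compressed files are handled; the raw bytes are then validated
# against the strict {A,C,G,T} alphabet (no silent upcasing).

.spss_dialects <- c("bcalm-ab", "plain-counts")

.parse_counts <- function(header, dialect, record) {
  toks <- strsplit(trimws(header), "[ \t]+")[[1L]]
  if (dialect == "bcalm-ab") {
    hit <- grep("^ab:Z:", toks)
    if (length(hit) != 1L) {
      stop(
        "record ", record, ": expected exactly one ab:Z: tag in header ",
        dQuote(header), call. = FALSE
      )
    }
    first <- sub("^ab:Z:", "", toks[hit])
    rest <- toks[-seq_len(hit)]
    # counts run until the next colon-typed tag, if any
    stopat <- grep(":", rest)
    if (length(stopat)) rest <- rest[seq_len(stopat[1L] - 1L)]
    toks <- c(first, rest)
  }
  if (!length(toks) || !all(grepl("^[0-9]+$", toks))) {
    stop(
      "record ", record, ": malformed counts in header ", dQuote(header),
      call. = FALSE
    )
  }
  w <- as.integer(toks)
  if (any(w < 1L)) {
    stop("record ", record, ": weights must be >= 1", call. = FALSE)
  }
  w
}

#' Read a weighted SPSS collection from FASTA
#'
#' @param path FASTA file; `.gz` input is accepted.
#' @param k k-mer length (not stored in the files themselves).
#' @param dialect `"bcalm-ab"` or `"plain-counts"` (see package docs).
#' @param allow_duplicates downgrade the duplicate-canonical-k-mer error
#'   to a warning.
#' @return an [spss_collection()]; ids are assigned 1..m in file order.
#' @export
read_spss <- function(path, k, dialect = c("bcalm-ab", "plain-counts"),
                      allow_duplicates = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  seqs <- as.character(recs)
  headers <- names(recs)
  strings <- lapply(seq_along(seqs), function(i) {
    list(seq = seqs[[i]], weights = .parse_counts(headers[[i]], dialect, i))
  })
  spss_collection(k, strings, validate_spss = TRUE,
                  allow_duplicates = allow_duplicates)
}

#' Write a weighted SPSS collection to FASTA
#'
#' Sequences are emitted on a single line; `read_spss(write_spss(x))` is
#' the identity on valid collections.
#'
#' @param coll an [spss_collection()].
#' @param path output file.
#' @param dialect header dialect, as in [read_spss()].
#' @return `path`, invisibly.
#' @export
write_spss <- function(coll, path, dialect = c("bcalm-ab", "plain-counts")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(coll, "spss_collection"))
  lines <- character(2L * length(coll$strings))
  for (i in seq_along(coll$strings)) {
    s <- coll$strings[[i]]
    counts <- paste(s$weights, collapse = " ")
    header <- switch(
      dialect,
      "bcalm-ab" = paste0(">", i - 1L, " LN:i:", nchar(s$seq), " ab:Z:", counts),
      "plain-counts" = paste0(">", counts)
    )
    lines[2L * i - 1L] <- header
    lines[2L * i] <- s$seq
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
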