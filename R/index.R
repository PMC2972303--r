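#' Build an exact-match substring index over a read library
#'
#' Concatenates the reads with a separator sentinel (plus a distinct
#' terminal sentinel) and builds a suffix array over the concatenation.
#' Occurrence counting is then a binary search over the sorted suffixes, so
#' a one-time indexing cost buys fast subsequent exact-match queries. The
#' sentinels lie outside the read alphabet, so no pattern over
#' \{A,C,G,T,N\} can match across a read boundary.
#'
#' @param library a [read_library()]
#' @return object of class `exact_match_index`: `source_library_id`, `text`
#'   (concatenated reads + sentinels), `suffix_order` (1-based positions of
#'   lexicographically sorted suffixes), `read_boundaries` (positions of the
#'   separators), `n_reads`, `max_read_length`, `build_version`.
#' @examples
#' idx <- build_index(read_library(c("ACGTACGT", "TACG"), "demo"))
#' count_occurrences(idx, "ACG")  # 3
#' @export
build_index <- function(library) {
  if (!inherits(library, "read_library")) {
    stop("`library` must be a read_library object", call. = FALSE)
  }
  reads <- library$reads
  if (length(reads) == 0L) {
    stop("cannot index an empty read library", call. = FALSE)
  }
  text <- paste0(paste(reads, collapse = SEP_SENTINEL), END_SENTINEL)
  sa <- sa_build(text)
  boundaries <- cumsum(nchar(reads) + 1L)  # sentinel positions
  structure(
    list(
      source_library_id = library$library_id,
      text = text,
      suffix_order = sa,
      read_boundaries = boundaries,
      n_reads = length(reads),
      max_read_length = max(nchar(reads)),
      build_version = INDEX_FORMAT_VERSION
    ),
    class = "exact_match_index"
  )
}

#' @export
print.exact_match_index <- function(x, ...) {
  cat(sprintf(
    "exact_match_index for '%s': %d reads, text length %d, format v%d\n",
    x$source_library_id, x$n_reads, nchar(x$text), x$build_version))
  invisible(x)
}

#' Count exact occurrences of a pattern in an indexed library
#'
#' Counts (read, offset) pairs: occurrences are summed with multiplicity
#' across duplicate reads, and overlapping occurrences within one read each
#' count. This is "the number of times the tile occurs in the dataset", not
#' the number of reads containing it.
#'
#' @param index an `exact_match_index`
#' @param pattern single non-empty string over \{A,C,G,T,N\} (lowercase and
#'   U accepted and normalised)
#' @param revcomp if `TRUE`, return a named vector with both the forward
#'   count and the count of the reverse complement (reported separately,
#'   never summed).
#' @return non-negative integer count (or named length-2 vector when
#'   `revcomp = TRUE`)
#' @export
count_occurrences <- function(index, pattern, revcomp = FALSE) {
  stopifnot(inherits(index, "exact_match_index"))
  if (length(pattern) != 1L || is.na(pattern) || !nzchar(pattern)) {
    stop("pattern must be a single non-empty string", call. = FALSE)
  }
  pattern <- normalize_seq(pattern)
  check_alphabet(pattern, what = "pattern")
  fwd <- sa_count(index$text, index$suffix_order, pattern)
  if (!isTRUE(revcomp)) return(fwd)
  rc <- reverse_complement(pattern)
  c(forward = fwd, revcomp = sa_count(index$text, index$suffix_order, rc))
}

#' Reverse complement of a DNA string (N maps to N)
#' @param x character vector of sequences
#' @return character vector
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

INDEX_FORMAT_VERSION <- 1L
INDEX_MAGIC <- "RTIDX"

#' Persist / restore an exact-match index
#'
#' `.rtidx` is a little-endian binary layout: magic "RTIDX", format version
#' (int32), library id (int32 length + bytes), alphabet string, text (int32
#' length + bytes), suffix order (int32 length + int32 values). A restored
#' index answers every count query identically to the original; corruption
#' and version mismatches raise errors rather than silent misreads.
#'
#' @param index an `exact_match_index`
#' @param path file path (conventionally `*.rtidx`)
#' @return `save_index`: `path`, invisibly. `load_index`: the index.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "exact_match_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(INDEX_MAGIC), con)
  writeBin(index$build_version, con, size = 4L, endian = "little")
  write_lenstr <- function(s) {
    r <- charToRaw(s)
    writeBin(length(r), con, size = 4L, endian = "little")
    writeBin(r, con)
  }
  write_lenstr(index$source_library_id)
  write_lenstr(paste(READ_ALPHABET, collapse = ""))
  write_lenstr(index$text)
  writeBin(length(index$suffix_order), con, size = 4L, endian = "little")
  writeBin(index$suffix_order, con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", n = nchar(INDEX_MAGIC)))
  if (!identical(magic, INDEX_MAGIC)) {
    stop("not a readtiler index: bad magic bytes in ", path, call. = FALSE)
  }
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(version) != 1L || version != INDEX_FORMAT_VERSION) {
    stop(sprintf("unsupported index format version %s (expected %d)",
                 paste(version, collapse = ""), INDEX_FORMAT_VERSION),
         call. = FALSE)
  }
  read_lenstr <- function(what) {
    n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(n) != 1L || is.na(n) || n < 0L) {
      stop("corrupted index file (", what, " length): ", path, call. = FALSE)
    }
    r <- readBin(con, "raw", n = n)
    if (length(r) != n) {
      stop("corrupted/truncated index file (", what, "): ", path, call. = FALSE)
    }
    rawToChar(r)
  }
  lib_id <- read_lenstr("library id")
  alphabet <- read_lenstr("alphabet")
  if (!identical(alphabet, paste(READ_ALPHABET, collapse = ""))) {
    stop("index built over unsupported alphabet: ", alphabet, call. = FALSE)
  }
  text <- read_lenstr("text")
  n_sa <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(n_sa) != 1L || is.na(n_sa) || n_sa != nchar(text)) {
    stop("corrupted index file (suffix order length): ", path, call. = FALSE)
  }
  sa <- readBin(con, "integer", n = n_sa, size = 4L, endian = "little")
  if (length(sa) != n_sa || anyNA(sa) || any(sa < 1L | sa > nchar(text)) ||
      anyDuplicated(sa) > 0L) {
    stop("corrupted/truncated index file (suffix order): ", path, call. = FALSE)
  }
  reads <- strsplit(sub(paste0("\\", END_SENTINEL, "$"), "",
                        gsub(END_SENTINEL, "", text, fixed = TRUE)),
                    SEP_SENTINEL, fixed = TRUE)[[1L]]
  structure(
    list(
      source_library_id = lib_id,
      text = text,
      suffix_order = sa,
      read_boundaries = cumsum(nchar(reads) + 1L),
      n_reads = length(reads),
      max_read_length = max(nchar(reads)),
      build_version = version
    ),
    class = "exact_match_index"
  )
}
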