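#' Construct a short-read library
#'
#' A read library is an ordered multiset of read sequences over
#' \{A,C,G,T,N\}: duplicate reads are preserved because multiplicity encodes
#' abundance in sequencing data. Sequences are uppercased and U is
#' transliterated to T on ingestion, so RNA-alphabet input (e.g. miRBase
#' precursors) can be matched against DNA reads.
#'
#' @param reads character vector of read sequences (may contain duplicates).
#' @param library_id single string identifying the library.
#' @param metadata optional catalog entry (a one-row data.frame, see
#'   [load_catalog()]) or list carried along for reporting.
#' @param drop_n if `TRUE`, reads containing 'N' are removed before
#'   validation (default `FALSE`; 'N' is otherwise an ordinary literal
#'   symbol).
#' @param allow_empty permit a library with zero reads (simulator output
#'   with zero planted copies); such a library cannot be indexed.
#' @return an object of class `read_library` with elements `library_id`,
#'   `reads`, `metadata`.
#' @examples
#' lib <- read_library(c("ACGTACGT", "TACG"), "demo")
#' length(lib$reads)
#' @export
read_library <- function(reads, library_id = "library", metadata = NULL,
                         drop_n = FALSE, allow_empty = FALSE) {
  if (!is.character(reads)) stop("`reads` must be a character vector", call. = FALSE)
  reads <- normalize_seq(reads)
  if (isTRUE(drop_n)) reads <- reads[!grepl("N", reads, fixed = TRUE)]
  if (length(reads) == 0L && !isTRUE(allow_empty)) {
    stop("read library is empty", call. = FALSE)
  }
  if (any(!nzchar(reads))) {
    stop(sprintf("read %d is empty", which(!nzchar(reads))[1L]), call. = FALSE)
  }
  check_alphabet(reads, what = "read")
  structure(
    list(library_id = as.character(library_id)[1L], reads = reads,
         metadata = metadata),
    class = "read_library"
  )
}

#' @export
print.read_library <- function(x, ...) {
  if (length(x$reads) == 0L) {
    cat(sprintf("read_library '%s': 0 reads\n", x$library_id))
  } else {
    cat(sprintf("read_library '%s': %d reads (lengths %d-%d), %d unique\n",
                x$library_id, length(x$reads), min(nchar(x$reads)),
                max(nchar(x$reads)), length(unique(x$reads))))
  }
  invisible(x)
}

#' Read a library from FASTA/FASTQ
#'
#' Convenience wrapper around [read_sequences()] + [read_library()].
#'
#' @inheritParams read_sequences
#' @inheritParams read_library
#' @return a `read_library`
#' @export
read_library_file <- function(path, library_id = NULL, format = "auto",
                              drop_n = FALSE, metadata = NULL) {
  recs <- read_sequences(path, format = format)
  if (is.null(library_id)) {
    library_id <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "", basename(path))
  }
  read_library(recs$sequence, library_id = library_id, metadata = metadata,
               drop_n = drop_n)
}
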