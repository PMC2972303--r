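#' Read sequences from FASTA or FASTQ
#'
#' FASTA parsing (plain or gzip) is delegated to Biostrings; FASTQ (plain
#' or gzip) is parsed with structural validation so malformed records are
#' reported with their line number (including quality strings whose length
#' differs from the sequence). Sequences are uppercased with U -> T; ids
#' are the header up to the first whitespace.
#'
#' @param path input file
#' @param format `"fasta"`, `"fastq"` or `"auto"` (sniff the first
#'   non-empty character: `>` = FASTA, `@` = FASTQ)
#' @return data.frame with columns `id`, `sequence`, in file order
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    con <- gzfile(path, "r")
    first <- ""
    repeat {
      ln <- readLines(con, n = 1L)
      if (length(ln) == 0L) break
      ln <- trimws(ln)
      if (nzchar(ln)) { first <- substr(ln, 1L, 1L); break }
    }
    close(con)
    format <- switch(first, ">" = "fasta", "@" = "fastq",
                     stop("cannot detect format of ", path,
                          ": first record starts with '", first, "'",
                          call. = FALSE))
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
    ids <- sub("\\s.*$", "", names(set))
    seqs <- normalize_seq(as.character(set))
  } else {
    recs <- parse_fastq(path)
    ids <- recs$id
    seqs <- normalize_seq(recs$sequence)
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' @noRd
parse_fastq <- function(path) {
  lines <- readLines(gzfile(path))
  keep <- nzchar(trimws(lines))
  # trailing blank lines tolerated; interior structure must be 4-line records
  lines <- lines[seq_len(max(which(keep), 0L))]
  if (length(lines) == 0L) stop("no records in ", path, call. = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record at line %d in %s",
                 (length(lines) %/% 4L) * 4L + 1L, path), call. = FALSE)
  }
  at <- seq(1L, length(lines), by = 4L)
  hdr <- lines[at]
  seqs <- lines[at + 1L]
  plus <- lines[at + 2L]
  quals <- lines[at + 3L]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0L) {
    stop(sprintf("malformed FASTQ header at line %d (expected '@...')",
                 at[bad_hdr[1L]]), call. = FALSE)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0L) {
    stop(sprintf("malformed FASTQ separator at line %d (expected '+')",
                 at[bad_plus[1L]] + 2L), call. = FALSE)
  }
  bad_q <- which(nchar(quals) != nchar(seqs))
  if (length(bad_q) > 0L) {
    i <- bad_q[1L]
    stop(sprintf(
      "FASTQ quality length %d != sequence length %d at line %d (record '%s')",
      nchar(quals[i]), nchar(seqs[i]), at[i] + 3L, sub("^@", "", hdr[i])),
      call. = FALSE)
  }
  data.frame(id = sub("\\s.*$", "", sub("^@", "", hdr)), sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write a tile profile to TSV (and optionally bedGraph)
#'
#' The TSV carries one row per query position with both coordinate
#' conventions in labelled columns (`pos0` 0-based, `pos1` 1-based), the
#' tile sequence and starts count at positions where a tile begins (empty
#' beyond position n-k+1), and the coverage at every position. Zeros are
#' written, never omitted: gaps in coverage are signal (absent isoform
#' exons, unexpressed precursor segments). A commented header records the
#' parameters, so [read_profile()] reconstructs starts and coverage
#' exactly.
#'
#' @param profile a `tile_profile`
#' @param tsv_path output TSV path
#' @param bedgraph_path optional bedGraph output of the coverage vector in
#'   the query's own coordinates (0-based half-open, maximal runs of equal
#'   coverage, zero runs included)
#' @return invisibly, `tsv_path`
#' @export
write_profile <- function(profile, tsv_path, bedgraph_path = NULL) {
  stopifnot(inherits(profile, "tile_profile"))
  n <- profile$n
  k <- profile$k
  tiles <- make_tiles(profile$query, k)
  starts_col <- rep(NA_integer_, n)
  starts_col[seq_along(profile$starts)] <- profile$starts
  tile_col <- rep("", n)
  tile_col[tiles$start] <- tiles$tile
  df <- data.frame(
    query_id = profile$query_id,
    pos0 = seq_len(n) - 1L,
    pos1 = seq_len(n),
    tile_sequence = tile_col,
    starts_count = starts_col,
    coverage_at_position = profile$coverage,
    stringsAsFactors = FALSE
  )
  con <- file(tsv_path, "w")
  writeLines(sprintf("# readtiler profile\tquery_id=%s\tn=%d\tk=%d",
                     profile$query_id, n, k), con)
  close(con)
  suppressWarnings(
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE, na = "")
  )
  if (!is.null(bedgraph_path)) {
    write_bedgraph(profile, bedgraph_path)
  }
  invisible(tsv_path)
}

#' @rdname write_profile
#' @param path bedGraph output path
#' @export
write_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "tile_profile"))
  r <- rle(profile$coverage)
  ends <- cumsum(r$lengths)
  starts0 <- ends - r$lengths  # 0-based half-open
  lines <- c(sprintf("track type=bedGraph name=\"%s\"", profile$query_id),
             sprintf("%s\t%d\t%d\t%d", profile$query_id, starts0, ends,
                     r$values))
  writeLines(lines, path)
  invisible(path)
}

#' Reconstruct a tile profile from its TSV export
#'
#' @param tsv_path a file written by [write_profile()]
#' @return a `tile_profile` (query sequence reassembled from the tile
#'   column plus the final tile's tail)
#' @export
read_profile <- function(tsv_path) {
  hdr <- readLines(tsv_path, n = 1L)
  if (!startsWith(hdr, "# readtiler profile")) {
    stop("not a readtiler profile TSV: ", tsv_path, call. = FALSE)
  }
  fields <- strsplit(hdr, "\t")[[1L]]
  get <- function(key) {
    v <- grep(paste0("^", key, "="), fields, value = TRUE)
    sub(paste0("^", key, "="), "", v[1L])
  }
  k <- as.integer(get("k"))
  n <- as.integer(get("n"))
  df <- utils::read.delim(tsv_path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c(tile_sequence = "character"))
  n_tiles <- n - k + 1L
  starts <- as.integer(df$starts_count[seq_len(n_tiles)])
  last_tile <- df$tile_sequence[n_tiles]
  query <- paste0(paste(substr(df$tile_sequence[seq_len(n_tiles)], 1L, 1L),
                        collapse = ""),
                  substr(last_tile, 2L, k))
  structure(
    list(query_id = df$query_id[1L], query = query, n = n, k = k,
         starts = starts,
         coverage = as.integer(df$coverage_at_position)),
    class = "tile_profile"
  )
}
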