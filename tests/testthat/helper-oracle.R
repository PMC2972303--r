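# Independent oracle: per-read overlapping-substring scan, summed over the
# read multiset. Deliberately naive; never touches the suffix array path.
naive_count <- function(reads, pattern) {
  sum(vapply(reads, function(rd) {
    n <- nchar(rd)
    m <- nchar(pattern)
    if (m > n) return(0L)
    starts <- seq_len(n - m + 1L)
    sum(substring(rd, starts, starts + m - 1L) == pattern)
  }, integer(1L), USE.NAMES = FALSE))
}

# Oracle for the suffix ordering: materialise every suffix and sort.
naive_suffix_order <- function(text) {
  n <- nchar(text)
  suffixes <- substring(text, seq_len(n), n)
  order(method = "radix", suffixes)
}

random_reads <- function(n_reads, len_range = c(5L, 40L),
                         alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n_reads), function(i) {
    len <- sample(seq(len_range[1L], len_range[2L]), 1L)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1L))
}

# A pattern drawn either at random or as a substring of a random read, so
# that nonzero counts are exercised.
random_pattern <- function(reads, len_range = c(1L, 25L)) {
  len <- sample(seq(len_range[1L], len_range[2L]), 1L)
  if (stats::runif(1) < 0.5) {
    rd <- sample(reads, 1L)
    if (nchar(rd) >= len) {
      s <- sample(nchar(rd) - len + 1L, 1L)
      return(substr(rd, s, s + len - 1L))
    }
  }
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Construct a tile_profile directly from a starts vector (for tests that
# specify profiles analytically rather than via an index).
manual_profile <- function(starts, k, n, query = strrep("A", n),
                           query_id = "manual") {
  structure(
    list(query_id = query_id, query = query, n = as.integer(n),
         k = as.integer(k), starts = as.integer(starts),
         coverage = compute_coverage(starts, k, n)),
    class = "tile_profile"
  )
}
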