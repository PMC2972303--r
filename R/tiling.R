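#' Decompose a query into k-mer tiles
#'
#' A query of length n yields the n - k + 1 substrings of length k taken at
#' every start position (step 1).
#'
#' @param query single sequence string
#' @param k tile size, `1 <= k <= nchar(query)`
#' @return data.frame with columns `start` (1-based tile start) and `tile`
#' @examples
#' make_tiles("ACGTT", 3)
#' @export
make_tiles <- function(query, k) {
  query <- normalize_seq(query)
  n <- nchar(query)
  k <- check_tile_size(k, n)
  starts <- seq_len(n - k + 1L)
  data.frame(start = starts,
             tile = substring(query, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' @noRd
check_tile_size <- function(k, n) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k <= 0L) {
    stop("tile size k must be a single positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (k > n) {
    stop(sprintf("tile size k = %d exceeds query length n = %d", k, n),
         call. = FALSE)
  }
  k
}

#' Profile a query against an indexed read library
#'
#' The query is tiled into all k-mers; each tile is looked up in the
#' exact-match index and its occurrence count recorded at its start
#' position (the *starts* view, `N_i`). The *coverage* view sums, at each
#' query position, the counts of every tile overlapping that position.
#' Tile size is the user's central sensitivity/specificity control: small
#' tiles match short read fragments (sensitive), large tiles demand long
#' exact matches (specific), and tiles longer than every read necessarily
#' score zero.
#'
#' @inheritParams count_occurrences
#' @inheritParams make_tiles
#' @param query_id identifier stored in the profile (plot/export label)
#' @param revcomp additionally count each tile's reverse complement into a
#'   separate `starts_revcomp` vector (never summed into `starts`)
#' @param skip_n if `TRUE`, tiles containing 'N' are not looked up and get
#'   `NA` ("not evaluated") in `starts`; by default they are searched
#'   literally.
#' @return object of class `tile_profile`: `query_id`, `query`, `n`, `k`,
#'   `starts` (length n-k+1), `coverage` (length n), optionally
#'   `starts_revcomp`.
#' @examples
#' idx <- build_index(read_library(c("ACGTT", "CGTTA"), "demo"))
#' tile_query(idx, "ACGTT", k = 3)$starts  # 1 2 2
#' @export
tile_query <- function(index, query, k, query_id = "query", revcomp = FALSE,
                       skip_n = FALSE) {
  stopifnot(inherits(index, "exact_match_index"))
  query <- normalize_seq(query)
  check_alphabet(query, what = "query")
  tiles <- make_tiles(query, k)
  k <- as.integer(k)
  n <- nchar(query)
  eval_mask <- if (isTRUE(skip_n)) !grepl("N", tiles$tile, fixed = TRUE)
               else rep(TRUE, nrow(tiles))
  starts <- rep(NA_integer_, nrow(tiles))
  starts[eval_mask] <- sa_count_many(index$text, index$suffix_order,
                                     tiles$tile[eval_mask])
  prof <- list(query_id = query_id, query = query, n = n, k = k,
               starts = starts,
               coverage = compute_coverage(starts, k, n))
  if (isTRUE(revcomp)) {
    rc <- rep(NA_integer_, nrow(tiles))
    rc[eval_mask] <- sa_count_many(index$text, index$suffix_order,
                                   reverse_complement(tiles$tile[eval_mask]))
    prof$starts_revcomp <- rc
  }
  structure(prof, class = "tile_profile")
}

#' Coverage view from a starts vector
#'
#' `coverage[j]` is the sum of `starts[i]` over every tile start i whose
#' tile covers position j, i.e. `max(1, j-k+1) <= i <= min(j, n-k+1)`.
#' Each tile therefore contributes its count to exactly k positions, so
#' `sum(coverage) == k * sum(starts)`; with k = 1 coverage equals starts.
#' `NA` starts (skipped tiles) are treated as zero contribution.
#'
#' @param starts integer vector of length n - k + 1
#' @param k tile size used to produce `starts`
#' @param n query length
#' @return integer vector of length n
#' @examples
#' compute_coverage(c(2, 0, 1), k = 2, n = 4)  # 2 2 1 1
#' @export
compute_coverage <- function(starts, k, n) {
  k <- as.integer(k)[1L]
  n <- as.integer(n)[1L]
  if (length(starts) != n - k + 1L) {
    stop(sprintf("length(starts) = %d but n - k + 1 = %d",
                 length(starts), n - k + 1L), call. = FALSE)
  }
  s <- ifelse(is.na(starts), 0L, as.integer(starts))
  # difference-array accumulation: add starts[i] on [i, i+k-1]
  d <- numeric(n + 1L)
  idx <- seq_along(s)
  d[idx] <- d[idx] + s
  d2 <- numeric(n + 1L)
  d2[idx + k] <- s
  cov <- cumsum(d - d2)[seq_len(n)]
  as.integer(round(cov))
}

#' @export
print.tile_profile <- function(x, ...) {
  cat(sprintf(
    "tile_profile '%s': n = %d, k = %d, total hits = %d, max coverage = %d\n",
    x$query_id, x$n, x$k, sum(x$starts, na.rm = TRUE), max(x$coverage)))
  invisible(x)
}

#' Starts/coverage panels for a tile profile
#'
#' Two aligned histogram panels (starts on top, coverage below) with
#' optional mature/star interval tracks under the axis.
#'
#' @param x a `tile_profile`
#' @param record optional `mirna_record` whose mature/star intervals are
#'   drawn as tracks
#' @param ... passed to [graphics::barplot()]
#' @return invisibly, `x`
#' @export
plot.tile_profile <- function(x, record = NULL, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(op))
  pad <- c(ifelse(is.na(x$starts), 0L, x$starts), rep(0L, x$k - 1L))
  draw <- function(v, main) {
    graphics::barplot(v, names.arg = NULL, space = 0, border = NA,
                      col = "grey30", main = main, xlab = "position",
                      ylab = "hits", ...)
    if (!is.null(record)) {
      usr <- graphics::par("usr")
      y0 <- usr[3] - 0.06 * (usr[4] - usr[3])
      for (iv in seq_len(nrow(record$mature))) {
        graphics::segments(record$mature$start[iv] - 1, y0,
                           record$mature$end[iv], y0,
                           col = "firebrick", lwd = 4, xpd = NA)
      }
      for (iv in seq_len(nrow(record$star))) {
        graphics::segments(record$star$start[iv] - 1, y0,
                           record$star$end[iv], y0,
                           col = "steelblue", lwd = 4, xpd = NA)
      }
    }
  }
  draw(pad, sprintf("%s - starts (k = %d)", x$query_id, x$k))
  draw(x$coverage, sprintf("%s - coverage", x$query_id))
  invisible(x)
}
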