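#' Random reference sequence
#'
#' Uniform i.i.d. sequence over \{A,C,G,T\}, deterministic per seed. When
#' `unique_k` is given, references containing a repeated k-mer are rejected
#' and resampled so that planted-recovery tests are exact: with all k-mers
#' distinct, a planted read's k-mers occur nowhere else on the reference.
#'
#' @param length reference length (>= 1)
#' @param seed integer seed; fully determines the output
#' @param unique_k if non-NULL, require all k-mers of this size distinct
#' @param max_tries resampling bound before giving up
#' @return single sequence string
#' @export
random_reference <- function(length, seed, unique_k = NULL, max_tries = 100L) {
  stopifnot(length >= 1)
  withr::with_seed(seed, {
    for (i in seq_len(max_tries)) {
      ref <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                   collapse = "")
      if (is.null(unique_k)) return(ref)
      kmers <- substring(ref, seq_len(length - unique_k + 1L),
                         seq_len(length - unique_k + 1L) + unique_k - 1L)
      if (anyDuplicated(kmers) == 0L) return(ref)
    }
  })
  stop(sprintf(
    "could not draw a reference of length %d with distinct %d-mers in %d tries; try a larger unique_k",
    length, unique_k, max_tries), call. = FALSE)
}

#' Specification of a planted synthetic read library
#'
#' Describes a library with analytically known tile profiles: for each
#' planted interval on the reference, the library receives `copies` exact
#' copies of every `read_length`-mer that fits fully inside the interval.
#' Optional background reads are drawn from an independent random sequence
#' and rejected if they share any `guard_k`-mer with the reference, so they
#' cannot contribute hits to reference tiles of size >= `guard_k`.
#'
#' @param reference reference sequence (use [random_reference()] with
#'   `unique_k` for exact-recovery work)
#' @param plants list of plants, each a list/vector with `start`, `end`
#'   (1-based inclusive interval on the reference), `read_length`,
#'   `copies`
#' @param background_n number of background reads (default 0)
#' @param background_lengths lengths sampled (uniformly) for background
#'   reads; default 18:28, the sRNA-seq size range
#' @param seed integer; fully determines the generated library
#' @param guard_k background reads are guaranteed free of reference
#'   k-mers for k >= guard_k (default 12)
#' @param error_rate optional per-base substitution rate applied to planted
#'   reads (default 0 = error-free; exact-recovery guarantees only hold
#'   at 0)
#' @return object of class `planted_spec`
#' @export
planted_spec <- function(reference, plants, background_n = 0L,
                         background_lengths = 18:28, seed = 1L,
                         guard_k = 12L, error_rate = 0) {
  reference <- normalize_seq(reference)
  n <- nchar(reference)
  plants <- lapply(plants, function(p) {
    p <- as.list(p)
    stopifnot(all(c("start", "end", "read_length", "copies") %in% names(p)))
    p[c("start", "end", "read_length", "copies")] <-
      lapply(p[c("start", "end", "read_length", "copies")], as.integer)
    if (p$start < 1L || p$end > n || p$start > p$end) {
      stop(sprintf("planted interval [%d, %d] outside reference of length %d",
                   p$start, p$end, n), call. = FALSE)
    }
    if (p$read_length > p$end - p$start + 1L) {
      stop(sprintf("read_length %d exceeds planted interval length %d",
                   p$read_length, p$end - p$start + 1L), call. = FALSE)
    }
    p
  })
  structure(
    list(reference = reference, plants = plants,
         background_n = as.integer(background_n),
         background_lengths = as.integer(background_lengths),
         seed = as.integer(seed), guard_k = as.integer(guard_k),
         error_rate = error_rate),
    class = "planted_spec"
  )
}

#' Generate the read library a planted spec describes
#'
#' @param spec a [planted_spec()]
#' @param library_id identifier for the generated library
#' @return list with `library` (a [read_library()]; errors if the spec
#'   yields zero reads) and `spec`; the analytic starts vector for any
#'   admissible k comes from [planted_truth()]
#' @export
generate_library <- function(spec, library_id = "planted") {
  stopifnot(inherits(spec, "planted_spec"))
  ref <- spec$reference
  planted <- unlist(lapply(spec$plants, function(p) {
    if (p$copies == 0L) return(character(0))
    starts <- seq.int(p$start, p$end - p$read_length + 1L)
    rep(substring(ref, starts, starts + p$read_length - 1L), each = p$copies)
  }))
  withr::with_seed(spec$seed, {
    if (spec$error_rate > 0 && length(planted) > 0L) {
      planted <- vapply(planted, mutate_read, character(1L),
                        rate = spec$error_rate, USE.NAMES = FALSE)
    }
    background <- draw_background(spec, ref)
  })
  reads <- c(planted, background)
  list(library = read_library(reads, library_id = library_id,
                              allow_empty = TRUE),
       spec = spec)
}

#' @noRd
draw_background <- function(spec, ref) {
  if (spec$background_n == 0L) return(character(0))
  # background source sequence independent of the reference
  ref_kmers <- function(s, k) {
    m <- nchar(s) - k + 1L
    if (m < 1L) character(0) else substring(s, seq_len(m), seq_len(m) + k - 1L)
  }
  forbidden <- unique(ref_kmers(ref, spec$guard_k))
  out <- character(spec$background_n)
  for (i in seq_len(spec$background_n)) {
    for (try in 1:200) {
      len <- sample(spec$background_lengths, 1L)
      rd <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
      if (!any(ref_kmers(rd, spec$guard_k) %in% forbidden)) break
      if (try == 200L) stop("could not draw a non-colliding background read",
                            call. = FALSE)
    }
    out[i] <- rd
  }
  out
}

#' @noRd
mutate_read <- function(read, rate) {
  chars <- strsplit(read, "")[[1L]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(c0) {
      sample(setdiff(c("A", "C", "G", "T"), c0), 1L)
    }, character(1L))
  }
  paste(chars, collapse = "")
}

#' Analytic starts vector for a planted spec
#'
#' For an error-free planted library on a repeat-free reference with
#' non-colliding background, the k-tile starting at reference position i
#' occurs once in each planted read that fully contains it. A read planted
#' at start s (length L) contains the tile iff s <= i <= s + L - k, so
#'
#'   `starts[i] = sum over plants of copies * #\{planted starts s : s <= i <= s + L - k\}`.
#'
#' Valid for `guard_k <= k <= read_length` of each plant.
#'
#' @param spec a [planted_spec()]
#' @param k tile size
#' @return integer vector of length `nchar(reference) - k + 1`
#' @export
planted_truth <- function(spec, k) {
  stopifnot(inherits(spec, "planted_spec"))
  n <- nchar(spec$reference)
  k <- check_tile_size(k, n)
  pos <- seq_len(n - k + 1L)
  truth <- integer(length(pos))
  for (p in spec$plants) {
    if (p$copies == 0L || k > p$read_length) next
    s_min <- p$start
    s_max <- p$end - p$read_length + 1L
    lo <- pmax(s_min, pos - (p$read_length - k))
    hi <- pmin(s_max, pos)
    truth <- truth + p$copies * pmax(0L, hi - lo + 1L)
  }
  truth
}

#' Write a planted library to FASTQ with its ground truth
#'
#' Reads get constant placeholder qualities ('I'), since qualities are
#' ignored downstream. The truth TSV holds the analytic starts vector at
#' each requested tile size.
#'
#' @param gen result of [generate_library()]
#' @param fastq_path output FASTQ path
#' @param truth_path optional output TSV of analytic starts
#' @param truth_k tile sizes to tabulate in the truth TSV
#' @return invisibly, `fastq_path`
#' @export
write_planted_library <- function(gen, fastq_path, truth_path = NULL,
                                  truth_k = NULL) {
  reads <- gen$library$reads
  lines <- as.vector(rbind(
    sprintf("@%s_read_%d", gen$library$library_id, seq_along(reads)),
    reads, "+", strrep("I", nchar(reads))))
  writeLines(lines, fastq_path)
  if (!is.null(truth_path)) {
    if (is.null(truth_k)) {
      truth_k <- min(vapply(gen$spec$plants, function(p) p$read_length,
                            integer(1L)))
    }
    tab <- do.call(rbind, lapply(truth_k, function(k) {
      tr <- planted_truth(gen$spec, k)
      data.frame(k = k, position = seq_along(tr), starts = tr)
    }))
    utils::write.table(tab, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fastq_path)
}

#' Synthetic miRNA expression fixtures
#'
#' Builds a random repeat-free precursor hairpin with annotated mature and
#' star arms plus a planted read library exhibiting either expression
#' pattern of interest:
#' * `"canonical"` — reads only from the mature arm (abundant) and the star
#'   arm (sparse), the asymmetric two-block profile of a genuine miRNA;
#' * `"uniform"` — reads spread evenly across the whole hairpin, the
#'   tRNA/snoRNA-like pattern that the mis-annotation screen flags.
#'
#' @param type expression pattern to emulate
#' @param seed integer; determines the precursor and library
#' @param precursor_length hairpin length in nt
#' @param mature,star arm intervals (1-based inclusive `c(start, end)`)
#' @param mature_copies,star_copies read depth per planted position in the
#'   canonical pattern
#' @param background_n background reads added to the library
#' @return list with `record` (a [mirna_record()]), `library` (a
#'   [read_library()]) and `spec` (the [planted_spec()])
#' @export
mirna_fixture <- function(type = c("canonical", "uniform"), seed = 42L,
                          precursor_length = 72L, mature = c(6L, 27L),
                          star = c(42L, 63L), mature_copies = 50L,
                          star_copies = 10L, background_n = 0L) {
  type <- match.arg(type)
  ref <- random_reference(precursor_length, seed, unique_k = 12L)
  plants <- if (type == "canonical") {
    list(list(start = mature[1L], end = mature[2L],
              read_length = mature[2L] - mature[1L] + 1L,
              copies = mature_copies),
         list(start = star[1L], end = star[2L],
              read_length = star[2L] - star[1L] + 1L,
              copies = star_copies))
  } else {
    list(list(start = 1L, end = precursor_length, read_length = 21L,
              copies = 2L))
  }
  spec <- planted_spec(ref, plants, background_n = background_n, seed = seed)
  gen <- generate_library(spec, library_id = sprintf("%s_fixture", type))
  record <- mirna_record(sprintf("syn-mir-%s", type), ref,
                         mature = mature, star = star, species = "synthetic")
  list(record = record, library = gen$library, spec = spec)
}
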