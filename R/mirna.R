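#' Construct a miRNA precursor record
#'
#' A precursor (pre-miRNA hairpin) with its annotated mature and star arm
#' intervals. On transcription the hairpin is processed to an ~22 nt
#' duplex: the *mature* strand is the biologically active one, the *star*
#' strand its (typically degraded) complement. Records with two mature
#' sequences (5p/3p) simply carry two mature intervals.
#'
#' Intervals are 1-based and inclusive on the precursor. RNA-alphabet
#' precursors are stored as DNA (U -> T).
#'
#' @param mirna_id miRBase-style identifier, e.g. "mmu-mir-712"
#' @param precursor precursor sequence (RNA or DNA alphabet)
#' @param mature,star intervals: a `data.frame(start, end)`, a numeric
#'   `c(start, end)`, or a list of such pairs; `star` may be empty
#' @param species species tag (free text)
#' @return object of class `mirna_record`
#' @examples
#' mirna_record("xxx-mir-1", strrep("ACGT", 15),
#'              mature = c(6, 27), star = c(34, 55))
#' @export
mirna_record <- function(mirna_id, precursor, mature, star = NULL,
                         species = NA_character_) {
  precursor <- normalize_seq(precursor)
  check_alphabet(precursor, what = "precursor")
  n <- nchar(precursor)
  mature <- as_intervals(mature, n, "mature", mirna_id)
  star <- as_intervals(star, n, "star", mirna_id)
  if (nrow(mature) == 0L) {
    stop(sprintf("%s: at least one mature interval is required", mirna_id),
         call. = FALSE)
  }
  if (intervals_overlap(mature, star)) {
    stop(sprintf("%s: mature and star intervals overlap", mirna_id),
         call. = FALSE)
  }
  structure(
    list(mirna_id = as.character(mirna_id)[1L], species = species,
         precursor = precursor, mature = mature, star = star),
    class = "mirna_record"
  )
}

#' @noRd
as_intervals <- function(x, n, what, id) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  if (is.numeric(x)) x <- list(x)
  if (is.data.frame(x)) {
    iv <- data.frame(start = as.integer(x$start), end = as.integer(x$end))
  } else {
    iv <- do.call(rbind, lapply(x, function(p) {
      data.frame(start = as.integer(p[[1L]]), end = as.integer(p[[2L]]))
    }))
  }
  bad <- iv$start < 1L | iv$end > n | iv$start > iv$end
  if (any(bad)) {
    stop(sprintf("%s: %s interval [%d, %d] outside precursor of length %d",
                 id, what, iv$start[which(bad)[1L]], iv$end[which(bad)[1L]], n),
         call. = FALSE)
  }
  iv[order(iv$start), , drop = FALSE]
}

#' @noRd
intervals_overlap <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(FALSE)
  for (i in seq_len(nrow(a))) {
    if (any(a$start[i] <= b$end & b$start <= a$end[i])) return(TRUE)
  }
  FALSE
}

#' @export
print.mirna_record <- function(x, ...) {
  fmt <- function(iv) paste(sprintf("[%d,%d]", iv$start, iv$end), collapse = " ")
  cat(sprintf("mirna_record %s (%s): precursor %d nt, mature %s, star %s\n",
              x$mirna_id, x$species, nchar(x$precursor),
              fmt(x$mature),
              if (nrow(x$star)) fmt(x$star) else "-"))
  invisible(x)
}

#' Arm-wise sums of a precursor tile profile
#'
#' Sums the starts vector over tile-start positions assigned to each arm:
#' a tile belongs to an arm iff its start position lies inside the arm's
#' interval. `N_m` is the mature-arm sum (all mature intervals pooled),
#' `N_s` the star-arm sum, `total` the sum over all tile starts.
#'
#' Tile starts only exist at positions 1 .. n-k+1, so arm positions within
#' k-1 of the precursor 3' end contribute no terms; this edge effect
#' follows from indexing by tile start and is intentional.
#'
#' @param profile a [tile_query()] profile computed on `record$precursor`
#' @param record a [mirna_record()]
#' @return named list `N_m`, `N_s`, `total` (integers)
#' @export
arm_sums <- function(profile, record) {
  stopifnot(inherits(profile, "tile_profile"), inherits(record, "mirna_record"))
  if (profile$n != nchar(record$precursor)) {
    stop(sprintf("profile length %d does not match precursor length %d for %s",
                 profile$n, nchar(record$precursor), record$mirna_id),
         call. = FALSE)
  }
  s <- ifelse(is.na(profile$starts), 0L, profile$starts)
  pos <- seq_along(s)  # tile-start positions 1 .. n-k+1
  in_any <- function(iv) {
    if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
    Reduce(`|`, lapply(seq_len(nrow(iv)),
                       function(i) pos >= iv$start[i] & pos <= iv$end[i]))
  }
  list(N_m = sum(s[in_any(record$mature)]),
       N_s = sum(s[in_any(record$star)]),
       total = sum(s))
}

#' Mis-annotation screen for a miRNA precursor profile
#'
#' A canonically expressed precursor concentrates nearly all its sRNA-seq
#' signal on the annotated mature and star arms. If the arm total falls
#' below `threshold` (default 95%) of the whole-precursor total,
#'
#'   `N_m + N_s < threshold * sum(N_i)`   (strict inequality),
#'
#' the precursor is flagged as potentially mis-annotated: a spread-out,
#' tRNA/snoRNA-like profile is evidence the annotation may describe some
#' other non-coding RNA. The published operating point is tile size 20 with
#' threshold 0.95. A zero-total profile (precursor not expressed) is
#' reported as indeterminate (`flagged = NA`), never flagged: absence of
#' expression is not evidence of mis-annotation.
#'
#' @inheritParams arm_sums
#' @param threshold arm-fraction decision threshold in (0, 1]
#' @return object of class `annotation_assessment`: `mirna_id`, `k`, `N_m`,
#'   `N_s`, `total`, `arm_fraction`, `flagged`, `threshold`
#' @export
assess_annotation <- function(profile, record, threshold = 0.95) {
  if (length(threshold) != 1L || is.na(threshold) || threshold <= 0 ||
      threshold > 1) {
    stop("threshold must be a single value in (0, 1]", call. = FALSE)
  }
  sums <- arm_sums(profile, record)
  arm <- sums$N_m + sums$N_s
  if (sums$total > 0L) {
    arm_fraction <- arm / sums$total
    flagged <- arm < threshold * sums$total
  } else {
    arm_fraction <- NA_real_
    flagged <- NA  # indeterminate
  }
  structure(
    list(mirna_id = record$mirna_id, k = profile$k,
         N_m = sums$N_m, N_s = sums$N_s, total = sums$total,
         arm_fraction = arm_fraction, flagged = flagged,
         threshold = threshold),
    class = "annotation_assessment"
  )
}

#' @export
print.annotation_assessment <- function(x, ...) {
  cat(sprintf(
    "annotation_assessment %s (k = %d): N_m = %d, N_s = %d, total = %d\n",
    x$mirna_id, x$k, x$N_m, x$N_s, x$total))
  cat(sprintf("  arm fraction = %s, threshold = %g -> %s\n",
              ifelse(is.na(x$arm_fraction), "NA (no hits)",
                     sprintf("%.4f", x$arm_fraction)),
              x$threshold,
              if (is.na(x$flagged)) "indeterminate"
              else if (x$flagged) "FLAGGED (potentially mis-annotated)"
              else "canonical"))
  invisible(x)
}

#' Per-library miRNA summary report
#'
#' Profiles every precursor against one library index and reports, per
#' miRNA: total precursor hits, mature hits, star hits, arm fraction and
#' the mis-annotation flag. Characterises the miRNA spectrum represented
#' in a library.
#'
#' @inheritParams count_occurrences
#' @param records list of [mirna_record()]s
#' @param k tile size (the published screen uses 20)
#' @param threshold passed to [assess_annotation()]
#' @return data.frame, one row per miRNA, sorted by `total` descending with
#'   ties broken by `mirna_id`; precursors shorter than k get
#'   `evaluated = FALSE` and NA counts rather than an error.
#' @export
mirna_summary <- function(index, records, k = 20, threshold = 0.95) {
  stopifnot(inherits(index, "exact_match_index"))
  if (inherits(records, "mirna_record")) records <- list(records)
  rows <- lapply(records, function(rec) {
    if (nchar(rec$precursor) < k) {
      return(data.frame(mirna_id = rec$mirna_id, evaluated = FALSE,
                        total = NA_integer_, mature_hits = NA_integer_,
                        star_hits = NA_integer_, arm_fraction = NA_real_,
                        flagged = NA, stringsAsFactors = FALSE))
    }
    prof <- tile_query(index, rec$precursor, k, query_id = rec$mirna_id)
    a <- assess_annotation(prof, rec, threshold = threshold)
    data.frame(mirna_id = a$mirna_id, evaluated = TRUE, total = a$total,
               mature_hits = a$N_m, star_hits = a$N_s,
               arm_fraction = a$arm_fraction, flagged = a$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$total), -1L, out$total), out$mirna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Libraries in which a miRNA is expressed
#'
#' Screens a collection of library indexes for expression of one miRNA:
#' a library qualifies when its mature-arm hit sum `N_m` reaches
#' `min_hits` (default 1; the notion of "expressed" has no canonical hit
#' count, so the cutoff is exposed).
#'
#' @param indexes named list of `exact_match_index` objects
#'   (names = library ids; unnamed lists fall back to each index's
#'   `source_library_id`)
#' @param record a [mirna_record()]
#' @param k tile size
#' @param min_hits minimum mature-arm hits to call the miRNA expressed
#' @return data.frame with `library_id` and `mature_hits`, sorted by
#'   `mature_hits` descending, ties broken by `library_id`
#' @export
libraries_expressing <- function(indexes, record, k = 20, min_hits = 1) {
  if (min_hits < 1) stop("min_hits must be >= 1", call. = FALSE)
  if (length(indexes) == 0L) {
    return(data.frame(library_id = character(0), mature_hits = integer(0)))
  }
  ids <- names(indexes)
  if (is.null(ids)) {
    ids <- vapply(indexes, function(x) x$source_library_id, character(1L))
  }
  nm <- vapply(indexes, function(idx) {
    prof <- tile_query(idx, record$precursor, k, query_id = record$mirna_id)
    arm_sums(prof, record)$N_m
  }, numeric(1L))
  keep <- nm >= min_hits
  out <- data.frame(library_id = ids[keep], mature_hits = as.integer(nm[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mature_hits, out$library_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read miRNA records from a TSV
#'
#' Expected columns: `mirna_id`, `species`, `precursor_seq`,
#' `mature_intervals`, `star_intervals`; interval columns hold
#' comma-separated `start-end` pairs, 1-based inclusive (e.g. `"6-27"` or
#' `"6-27,40-61"`); an empty string means no intervals.
#'
#' @param path TSV file path
#' @return list of [mirna_record()]s
#' @export
read_mirna_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  need <- c("mirna_id", "species", "precursor_seq", "mature_intervals",
            "star_intervals")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("miRNA TSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    mirna_record(df$mirna_id[i], df$precursor_seq[i],
                 mature = parse_intervals(df$mature_intervals[i]),
                 star = parse_intervals(df$star_intervals[i]),
                 species = df$species[i])
  })
}

#' Read miRNA records from a precursor FASTA plus interval TSV
#'
#' The FASTA holds precursor sequences keyed by id; the TSV has columns
#' `mirna_id`, `arm` (`mature` or `star`), `start`, `end` (1-based
#' inclusive), one row per interval.
#'
#' @param fasta_path precursor FASTA
#' @param intervals_path interval TSV
#' @param species species tag applied to all records
#' @return list of [mirna_record()]s
#' @export
read_mirna_fasta <- function(fasta_path, intervals_path,
                             species = NA_character_) {
  seqs <- read_sequences(fasta_path, format = "fasta")
  iv <- utils::read.delim(intervals_path, stringsAsFactors = FALSE,
                          comment.char = "#")
  bad_arm <- setdiff(unique(iv$arm), c("mature", "star"))
  if (length(bad_arm) > 0L) {
    stop("interval TSV has unknown arm value(s): ",
         paste(bad_arm, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(seqs)), function(i) {
    id <- seqs$id[i]
    sub <- iv[iv$mirna_id == id, , drop = FALSE]
    mk <- function(arm) {
      s <- sub[sub$arm == arm, c("start", "end"), drop = FALSE]
      if (nrow(s) == 0L) NULL else s
    }
    mirna_record(id, seqs$sequence[i], mature = mk("mature"),
                 star = mk("star"), species = species)
  })
}

#' @noRd
parse_intervals <- function(s) {
  s <- trimws(s)
  if (is.na(s) || !nzchar(s)) return(NULL)
  pairs <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  bad <- vapply(pairs, length, integer(1L)) != 2L
  if (any(bad)) stop("malformed interval string: '", s, "'", call. = FALSE)
  lapply(pairs, function(p) as.integer(p))
}
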