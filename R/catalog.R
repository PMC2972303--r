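EXPERIMENT_TYPES <- c("Genomic DNA", "ChIP-Seq", "RNA-Seq", "sRNA-Seq")

#' Load a library-metadata catalog
#'
#' A local, file-backed catalog of sequencing libraries with a controlled
#' vocabulary: each entry records the organism, the experiment type (one of
#' `"Genomic DNA"`, `"ChIP-Seq"`, `"RNA-Seq"`, `"sRNA-Seq"`), the tissue
#' (free text: "Heart", "Lung", "Stem-cell", ...), whether a prebuilt
#' `.rtidx` index exists and where. Accepted as TSV (header: library_id,
#' organism, experiment_type, tissue, indexed, index_path) or a JSON array
#' of objects with the same fields.
#'
#' @param path TSV or JSON catalog file
#' @param check_index_paths verify that `index_path` exists for every entry
#'   with `indexed = TRUE` (default `TRUE`; error names the row)
#' @return data.frame of catalog entries, input order preserved
#' @export
load_catalog <- function(path, check_index_paths = TRUE) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  first <- readChar(path, nchars = 1L, useBytes = TRUE)
  df <- if (identical(first, "[")) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  }
  need <- c("library_id", "organism", "experiment_type", "tissue", "indexed")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("catalog is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"index_path" %in% names(df)) df$index_path <- NA_character_
  df$index_path <- as.character(df$index_path)
  df$indexed <- as.logical(df$indexed)
  bad <- !df$experiment_type %in% EXPERIMENT_TYPES
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "catalog row %d (library '%s'): experiment_type '%s' is not one of %s",
      i, df$library_id[i], df$experiment_type[i],
      paste(EXPERIMENT_TYPES, collapse = ", ")), call. = FALSE)
  }
  if (isTRUE(check_index_paths)) {
    path_ok <- !is.na(df$index_path) & nzchar(df$index_path)
    path_ok[path_ok] <- file.exists(df$index_path[path_ok])
    flagged <- which(df$indexed & !path_ok)
    if (length(flagged) > 0L) {
      i <- flagged[1L]
      stop(sprintf(
        "catalog row %d (library '%s'): indexed = TRUE but index_path '%s' does not exist",
        i, df$library_id[i],
        ifelse(is.na(df$index_path[i]), "", df$index_path[i])), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Filter a catalog by controlled-vocabulary fields
#'
#' Conjunctive filter: every provided criterion must match; omitted
#' criteria match everything. Matching is case-insensitive and exact on the
#' controlled fields; `substring = TRUE` relaxes the free-text `tissue`
#' match to case-insensitive substring containment. Input order is
#' preserved, and filtering is idempotent and order-insensitive across
#' criteria.
#'
#' @param entries data.frame from [load_catalog()]
#' @param organism,experiment_type,tissue optional filter values
#' @param substring use substring matching for `tissue`
#' @return filtered data.frame
#' @examples
#' \dontrun{
#' filter_catalog(cat, organism = "M. musculus", experiment_type = "sRNA-Seq")
#' }
#' @export
filter_catalog <- function(entries, organism = NULL, experiment_type = NULL,
                           tissue = NULL, substring = FALSE) {
  keep <- rep(TRUE, nrow(entries))
  eq <- function(col, val) tolower(col) == tolower(val)
  if (!is.null(organism)) keep <- keep & eq(entries$organism, organism)
  if (!is.null(experiment_type)) {
    keep <- keep & eq(entries$experiment_type, experiment_type)
  }
  if (!is.null(tissue)) {
    keep <- keep & if (isTRUE(substring)) {
      grepl(tolower(tissue), tolower(entries$tissue), fixed = TRUE)
    } else {
      eq(entries$tissue, tissue)
    }
  }
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
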