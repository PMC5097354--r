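# Sample sheets and reference sets: the multiplex design.

#' Construct a sample sheet
#'
#' A sample sheet describes the multiplex design: each sample's identifier
#' and its (i5, i7) index pair, optionally with the id of its expected
#' amplicon reference. Index pairs must be unique across samples; all i5
#' indices must share one length, and likewise all i7 indices.
#'
#' @param samples A data.frame with columns `sample_id`, `i5`, `i7` and
#'   optionally `reference_id` (defaults to `sample_id`).
#' @return A `sample_sheet` (a validated data.frame).
#' @export
sample_sheet <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "i5", "i7") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  samples$i5 <- toupper(as.character(samples$i5))
  samples$i7 <- toupper(as.character(samples$i7))
  if (is.null(samples$reference_id)) samples$reference_id <- samples$sample_id
  samples$reference_id <- as.character(samples$reference_id)
  if (nrow(samples) == 0L) stop("sample sheet has no samples")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in sheet")
  if (!all(grepl("^[ACGT]+$", c(samples$i5, samples$i7)))) {
    stop("index sequences must be over the alphabet {A,C,G,T}")
  }
  if (length(unique(nchar(samples$i5))) != 1L ||
      length(unique(nchar(samples$i7))) != 1L) {
    stop("all i5 indices must share one length, and likewise all i7 indices")
  }
  pair <- paste(samples$i5, samples$i7)
  if (anyDuplicated(pair)) {
    stop("duplicate (i5, i7) pair in sheet: ", pair[duplicated(pair)][1])
  }
  out <- samples[, c("sample_id", "i5", "i7", "reference_id")]
  rownames(out) <- NULL
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Read a sample sheet from TSV or CSV
#'
#' The delimiter is chosen by extension (`.csv` is comma-separated,
#' everything else tab-separated). Required columns: `sample_id`, `i5`,
#' `i7`; optional `reference_id`.
#'
#' @param path Path to the sheet.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    read.delim(path, stringsAsFactors = FALSE)
  }
  sample_sheet(df)
}

#' Construct a reference set
#'
#' The expected amplicon sequence for each sample. Stores the minimum
#' pairwise edit distance among references; sequence assignment is only
#' unambiguous when that separation exceeds twice the allowed edit
#' distance (the assignment default of 4 edits asks for separation > 8;
#' well-designed amplicon panels are separated much further, e.g. by at
#' least 14 edits).
#'
#' @param ids Character vector of reference ids (matching the sheet's
#'   `reference_id` column).
#' @param sequences Character vector of reference sequences.
#' @param max_edit Allowed assignment edit distance used for the
#'   separation warning (default 4).
#' @return A `reference_set`: data.frame with columns `reference_id`,
#'   `sequence`, and attribute `min_pairwise_edit`.
#' @export
reference_set <- function(ids, sequences, max_edit = 4L) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  stopifnot(length(ids) == length(sequences), length(ids) >= 1L)
  if (anyDuplicated(ids)) stop("duplicate reference ids")
  min_edit <- NA_integer_
  if (length(sequences) > 1L) {
    cmb <- utils::combn(length(sequences), 2L)
    big_band <- max(nchar(sequences))
    d <- .levenshtein_c(sequences[cmb[1, ]], sequences[cmb[2, ]], big_band)
    min_edit <- min(d)
    if (min_edit <= 2L * max_edit) {
      warning(sprintf(
        "minimum pairwise reference edit distance is %d; distances <= %d allow ambiguous assignment at max_edit = %d",
        min_edit, 2L * max_edit, max_edit))
    }
  }
  out <- data.frame(reference_id = ids, sequence = sequences,
                    stringsAsFactors = FALSE)
  attr(out, "min_pairwise_edit") <- min_edit
  class(out) <- c("reference_set", "data.frame")
  out
}

#' Read references from a FASTA file
#'
#' @param path FASTA path (plain or gzipped).
#' @param max_edit Passed to [reference_set()].
#' @return A [reference_set()].
#' @export
read_references <- function(path, max_edit = 4L) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  reference_set(sub("\\s.*$", "", names(x)), as.character(x),
                max_edit = max_edit)
}

#' Validate a sample sheet against the index-matching tolerance
#'
#' Computes the full i5 x i5 and i7 x i7 hamming-distance matrices and
#' warns about every pair of distinct indices whose distance is at most
#' `2 * max_mismatch`: such pairs can both sit within `max_mismatch` of one
#' observed read, making the match ambiguous (or, worse, silently wrong at
#' distance `<= max_mismatch`).
#'
#' @param sheet A [sample_sheet()].
#' @param max_mismatch Allowed per-index mismatches during demultiplexing
#'   (default 1).
#' @return A list with `warnings` (character vector, possibly empty),
#'   `i5_hamming` and `i7_hamming` (named square integer matrices).
#' @export
validate_samplesheet <- function(sheet, max_mismatch = 1L) {
  stopifnot(inherits(sheet, "sample_sheet"))
  ham_matrix <- function(idx) {
    u <- unique(idx)
    m <- matrix(0L, length(u), length(u), dimnames = list(u, u))
    if (length(u) > 1L) {
      cmb <- utils::combn(length(u), 2L)
      d <- .hamming_c(u[cmb[1, ]], u[cmb[2, ]])
      for (j in seq_len(ncol(cmb))) {
        m[cmb[1, j], cmb[2, j]] <- m[cmb[2, j], cmb[1, j]] <- d[j]
      }
    }
    m
  }
  warn_close <- function(m, side) {
    out <- character(0)
    if (nrow(m) > 1L) {
      for (a in seq_len(nrow(m) - 1L)) for (b in seq(a + 1L, ncol(m))) {
        if (m[a, b] <= 2L * max_mismatch) {
          out <- c(out, sprintf(
            "%s indices %s and %s are at hamming distance %d <= %d; matches can be ambiguous or wrong at max_mismatch = %d",
            side, rownames(m)[a], colnames(m)[b], m[a, b], 2L * max_mismatch,
            max_mismatch))
        }
      }
    }
    out
  }
  i5m <- ham_matrix(sheet$i5)
  i7m <- ham_matrix(sheet$i7)
  warnings <- c(warn_close(i5m, "i5"), warn_close(i7m, "i7"))
  list(warnings = warnings, i5_hamming = i5m, i7_hamming = i7m)
}

#' Write a sample sheet to TSV
#' @param sheet A [sample_sheet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
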