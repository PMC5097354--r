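# Index matching and sequence assignment (bcl2fastq-compatible demultiplexing).

#' Hamming distance between equal-length sequences
#'
#' Counts differing positions. An `N` differs from every base, including
#' another `N`: an uncalled base never supports a match.
#'
#' @param a,b Character vectors of equal-length sequences (recycled
#'   elementwise if one is length 1).
#' @return Integer vector of distances.
#' @examples
#' hamming("ACGTAAGG", "ACGTAAGG")  # 0
#' hamming("ANGT", "AAGT")          # 1
#' @export
hamming <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (length(a) == 1L) a <- rep(a, length(b))
  if (length(b) == 1L) b <- rep(b, length(a))
  .hamming_c(a, b)
}

#' Banded Levenshtein (edit) distance
#'
#' Full-string unit-cost edit distance (substitutions, insertions,
#' deletions), computed in a diagonal band of half-width `band`. Distances
#' greater than `band` are reported as `band + 1`. `N` mismatches every
#' base, as in [hamming()].
#'
#' @param a,b Character vectors of sequences (recycled if length 1).
#' @param band Band half-width; defaults to the longer sequence length
#'   (exact, unbanded distance).
#' @return Integer vector of distances, capped at `band + 1`.
#' @export
edit_distance <- function(a, b, band = NULL) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (length(a) == 1L) a <- rep(a, length(b))
  if (length(b) == 1L) b <- rep(b, length(a))
  if (is.null(band)) band <- max(nchar(c(a, b)), 0L)
  .levenshtein_c(a, b, as.integer(band))
}

# Decode the integer codes of the C++ matchers.
.code_status <- function(code) {
  ifelse(code > 0L, "unique", ifelse(code == 0L, "none", "ambiguous"))
}

#' Match index reads against the expected index set
#'
#' bcl2fastq-style index matching: an observed index read matches an
#' expected index when their hamming distance is at most `max_mismatch`
#' (default 1, the bcl2fastq default). An `N` in the read counts as a
#' mismatch at that position. If two or more expected indices are within
#' reach the match is `"ambiguous"`; if none is, `"none"`. With
#' `max_mismatch = 0` this reduces to exact string lookup.
#'
#' @param observed Character vector of observed index reads.
#' @param expected Character vector of expected index sequences (all one
#'   length, equal to the observed read length).
#' @param max_mismatch Maximum allowed mismatches per index.
#' @return A data.frame with columns `index` (the matched expected index,
#'   `NA` when none/ambiguous) and `status`
#'   (`"unique"`, `"none"` or `"ambiguous"`).
#' @export
match_index <- function(observed, expected, max_mismatch = 1L) {
  observed <- toupper(as.character(observed))
  expected <- toupper(as.character(expected))
  code <- .match_index_c(observed, expected, as.integer(max_mismatch))
  data.frame(
    index = ifelse(code > 0L, expected[pmax(code, 1L)], NA_character_),
    status = .code_status(code),
    stringsAsFactors = FALSE
  )
}

#' Assign sequence reads to their nearest expected reference
#'
#' Computes the banded full-string Levenshtein distance from each read to
#' every reference and returns the unique nearest reference within
#' `max_edit` (default 4) edits — substitutions, insertions and deletions
#' all count. A tie at the minimum distance is `"ambiguous"`; no reference
#' within reach is `"none"`.
#'
#' @param reads Character vector of read sequences (non-empty).
#' @param refs A [reference_set()].
#' @param max_edit Maximum allowed edit distance.
#' @return A data.frame with columns `reference_id` (`NA` when
#'   none/ambiguous), `distance` (capped at `max_edit + 1`) and `status`.
#' @export
assign_sequence <- function(reads, refs, max_edit = 4L) {
  stopifnot(inherits(refs, "reference_set"))
  reads <- toupper(as.character(reads))
  m <- .assign_sequence_c(reads, refs$sequence, as.integer(max_edit))
  code <- m[, 1]
  data.frame(
    reference_id = ifelse(code > 0L, refs$reference_id[pmax(code, 1L)],
                          NA_character_),
    distance = m[, 2],
    status = .code_status(code),
    stringsAsFactors = FALSE
  )
}

#' Demultiplex read triplets against a multiplex design
#'
#' For every triplet, matches the i5 and i7 index reads against the
#' sheet's index sets ([match_index()]) and assigns the sequence read to
#' its nearest expected reference ([assign_sequence()]). The three
#' decisions are made independently — no step's outcome influences
#' another's — and each segment's mean error probability is recorded for
#' downstream quality filtering.
#'
#' @param triplets A `triplet_set` from [read_triplets()] (or the
#'   simulator).
#' @param sheet A [sample_sheet()].
#' @param refs A [reference_set()].
#' @param max_mismatch Allowed mismatches per index (default 1).
#' @param max_edit Allowed sequence edit distance (default 4).
#' @return A `triplet_assignment` data.frame with one row per triplet:
#'   `id`, matched `i5`/`i7` (expected index or `NA`) with `i5_status`/
#'   `i7_status`, `ref_sample` (the sample whose reference matched, `NA`
#'   otherwise) with `ref_status` and `ref_distance`, and the segment mean
#'   error probabilities `seq_mean_p`, `i5_mean_p`, `i7_mean_p`.
#' @export
demultiplex <- function(triplets, sheet, refs, max_mismatch = 1L,
                        max_edit = 4L) {
  stopifnot(is.data.frame(triplets), inherits(sheet, "sample_sheet"),
            inherits(refs, "reference_set"))
  i5_set <- unique(sheet$i5)
  i7_set <- unique(sheet$i7)
  m5 <- match_index(triplets$i5_bases, i5_set, max_mismatch)
  m7 <- match_index(triplets$i7_bases, i7_set, max_mismatch)
  sq <- assign_sequence(triplets$seq_bases, refs, max_edit)
  ref_sample <- sheet$sample_id[match(sq$reference_id, sheet$reference_id)]
  out <- data.frame(
    id = triplets$id,
    i5 = m5$index, i5_status = m5$status,
    i7 = m7$index, i7_status = m7$status,
    ref_sample = ref_sample, ref_status = sq$status,
    ref_distance = sq$distance,
    seq_mean_p = mean_error_prob_many(triplets$seq_quals),
    i5_mean_p = mean_error_prob_many(triplets$i5_quals),
    i7_mean_p = mean_error_prob_many(triplets$i7_quals),
    stringsAsFactors = FALSE
  )
  class(out) <- c("triplet_assignment", "data.frame")
  attr(out, "max_mismatch") <- as.integer(max_mismatch)
  attr(out, "max_edit") <- as.integer(max_edit)
  out
}
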