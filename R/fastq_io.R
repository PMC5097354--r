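# FASTQ triplet I/O and Phred <-> error-probability conversion.
#
# Quality encoding is fixed to Phred+33 (Sanger / Illumina 1.8+). Other
# offsets are rejected, never auto-detected: every modern Illumina deliverable
# is Phred+33 and a silent misdetection corrupts every downstream probability.

PHRED_OFFSET <- 33L
PHRED_MAX <- 93L

#' Convert a Phred quality score to an error probability
#'
#' Applies the Phred relation p = 10^(-Q/10), so Q20 corresponds to a 1%
#' chance that the base call is wrong and Q26 to 0.25%.
#'
#' @param q Integer vector of Phred quality scores, all `>= 0`.
#' @return Numeric vector of per-base error probabilities in `(0, 1]`.
#' @seealso [error_prob_to_q()] for the inverse, [mean_error_prob()] for
#'   whole-read averages.
#' @examples
#' q_to_error_prob(c(0, 20, 26, 40))
#' @export
q_to_error_prob <- function(q) {
  q <- as.numeric(q)
  if (anyNA(q) || any(q < 0)) {
    stop("Phred scores must be non-negative and non-missing")
  }
  10^(-q / 10)
}

#' Convert an error probability to the Phred scale
#'
#' @param p Numeric vector of probabilities in `(0, 1]`.
#' @return Numeric vector `-10 * log10(p)` (not rounded).
#' @export
error_prob_to_q <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("error probabilities must lie in (0, 1]")
  }
  -10 * log10(p)
}

# Phred+33 string -> integer quality vector, validating the legal range.
phred_to_int <- function(quals) {
  q <- utf8ToInt(quals) - PHRED_OFFSET
  if (length(q) && (min(q) < 0L || max(q) > PHRED_MAX)) {
    stop("quality characters outside the Phred+33 range [0, 93]; ",
         "only Sanger/Illumina 1.8+ encoding is supported")
  }
  q
}

int_to_phred <- function(q) {
  if (length(q) == 0L) return("")
  intToUtf8(as.integer(q) + PHRED_OFFSET)
}

#' Mean error probability of a read segment
#'
#' Averages per-base error probabilities `10^(-Q/10)` across a read. This is
#' the probability-domain average used for quality filtering; the equivalent
#' "average quality" reported to users is `-10 * log10(mean p)`. Averaging
#' the Q values themselves (the Illumina convention in some summaries)
#' systematically understates the error rate of reads with mixed quality;
#' it is available via `domain = "q"` for sensitivity analysis.
#'
#' @param quals A single Phred+33-encoded quality string, or an integer
#'   vector of Phred scores. Must be non-empty.
#' @param domain `"probability"` (default) averages per-base error
#'   probabilities; `"q"` averages the Q values first and converts the mean
#'   Q to a probability.
#' @return A single error probability in `(0, 1]`.
#' @examples
#' mean_error_prob(rep(26L, 8))          # 10^-2.6 ~ 0.0025
#' mean_error_prob(c(20L, 30L))          # (0.01 + 0.001) / 2
#' @export
mean_error_prob <- function(quals, domain = c("probability", "q")) {
  domain <- match.arg(domain)
  if (is.character(quals)) {
    stopifnot(length(quals) == 1L)
    quals <- phred_to_int(quals)
  }
  if (length(quals) == 0L) stop("cannot average qualities of an empty read")
  if (any(quals < 0)) stop("Phred scores must be non-negative")
  if (domain == "probability") {
    mean(10^(-quals / 10))
  } else {
    10^(-mean(quals) / 10)
  }
}

# Vectorized over many quality strings; used on whole-run columns.
mean_error_prob_many <- function(qual_strings, domain = "probability") {
  vapply(qual_strings, mean_error_prob, numeric(1), domain = domain,
         USE.NAMES = FALSE)
}

# Cluster identity: read-id token before the first whitespace, with a
# trailing /1, /2 or /3 mate suffix stripped (common FASTQ dialects).
cluster_id <- function(read_id) {
  sub("/[123]$", "", sub("\\s.*$", "", read_id))
}

# Read one FASTQ file (plain or gzip by extension) into a data.frame with
# columns id, bases, quals. Biostrings does the parsing and validates the
# 4-line structure.
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
  )
  df <- data.frame(
    id = if (length(x)) names(x) else character(0),
    bases = as.character(x),
    quals = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  # validate the quality range once per file
  if (nrow(df)) invisible(phred_to_int(paste(df$quals, collapse = "")))
  df
}

#' Read a synchronized triplet of FASTQ files
#'
#' Loads the sequence read (R1) and the two index reads (i7 = I1, i5 = I2)
#' of a dual-indexed run, as produced by bcl2fastq with
#' `--create-fastq-for-index-reads`: all three files carry the same clusters
#' in the same order. Gzip-compressed files are accepted by extension.
#' Cluster identity is the read-id token before the first whitespace (any
#' `/1`, `/2`, `/3` suffix stripped); any disagreement across the three
#' files is a hard error naming the first offending record.
#'
#' @param r1_path,i7_path,i5_path Paths to the sequence, i7-index and
#'   i5-index FASTQ files (Phred+33).
#' @return A `triplet_set`: a data.frame with one row per cluster and
#'   columns `id`, `seq_bases`, `seq_quals`, `i5_bases`, `i5_quals`,
#'   `i7_bases`, `i7_quals`.
#' @export
read_triplets <- function(r1_path, i7_path, i5_path) {
  r1 <- read_fastq(r1_path)
  i7 <- read_fastq(i7_path)
  i5 <- read_fastq(i5_path)
  n <- c(nrow(r1), nrow(i7), nrow(i5))
  if (length(unique(n)) != 1L) {
    stop(sprintf(
      "record counts differ across the triplet files: R1=%d, I1(i7)=%d, I2(i5)=%d",
      n[1], n[2], n[3]))
  }
  ids <- cluster_id(r1$id)
  for (other in list(c("I1(i7)", "i7"), c("I2(i5)", "i5"))) {
    oth <- if (other[2] == "i7") i7 else i5
    oid <- cluster_id(oth$id)
    bad <- which(oid != ids)
    if (length(bad)) {
      stop(sprintf(
        "desynchronized FASTQ streams: record %d is '%s' in R1 but '%s' in %s",
        bad[1], ids[bad[1]], oid[bad[1]], other[1]))
    }
  }
  out <- data.frame(
    id = ids,
    seq_bases = toupper(r1$bases), seq_quals = r1$quals,
    i5_bases = toupper(i5$bases), i5_quals = i5$quals,
    i7_bases = toupper(i7$bases), i7_quals = i7$quals,
    stringsAsFactors = FALSE
  )
  class(out) <- c("triplet_set", "data.frame")
  out
}

#' Write read records to a FASTQ file
#'
#' @param records A data.frame with columns `id`, `bases`, `quals`
#'   (Phred+33 quality strings, same length as `bases`).
#' @param path Output path; a `.gz` extension triggers gzip compression.
#' @return The number of records written, invisibly.
#' @details Round-tripping through [read_triplets()]/`write_fastq()`
#'   preserves bases and quality strings exactly, including `N` bases and
#'   the extreme quality symbols `!` (Q0) and `~` (Q93).
#' @export
write_fastq <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("id", "bases", "quals") %in% names(records)))
  if (any(nchar(records$bases) != nchar(records$quals))) {
    stop("bases and quals must have equal length in every record")
  }
  if (any(!nzchar(records$id))) stop("read ids must be non-empty")
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(records$bases),
    Biostrings::PhredQuality(records$quals)
  )
  names(x) <- records$id
  compress <- grepl("\\.gz$", path)
  Biostrings::writeQualityScaledXStringSet(x, path, compress = compress)
  invisible(nrow(records))
}
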