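# Quality filtering of triplets and threshold sweeps.
#
# Thresholds are expressed on the familiar Phred-equivalent scale and
# converted internally to bounds on the mean per-base error probability: a
# segment passes threshold Q when its mean error probability is at most
# 10^(-Q/10) (boundary inclusive, so "average quality >= Q" passes).
# Filtering happens after demultiplexing and classification, so a single
# pass over the run supports every threshold of a sweep.

FILTER_STRATEGIES <- c("SEQUENCE_ONLY", "INDEX_ONLY", "ALL_READS")

# Which segments a strategy inspects.
.strategy_segments <- function(strategy) {
  strategy <- match.arg(toupper(strategy), FILTER_STRATEGIES)
  switch(strategy,
         SEQUENCE_ONLY = "seq_mean_p",
         INDEX_ONLY = c("i5_mean_p", "i7_mean_p"),
         ALL_READS = c("seq_mean_p", "i5_mean_p", "i7_mean_p"))
}

#' Does each triplet pass a quality filter?
#'
#' A triplet passes when every read segment selected by the strategy has a
#' mean error probability at most `10^(-q_thresh/10)`:
#' `SEQUENCE_ONLY` inspects the sequence read, `INDEX_ONLY` requires
#' *both* index reads to pass, `ALL_READS` requires all three. At
#' `q_thresh = 0` everything passes (every probability is `<= 1`).
#'
#' @param x A `triplet_assignment`/`classified_triplets` (which already
#'   carry segment mean error probabilities), or a `triplet_set` of raw
#'   reads (probabilities are computed on the fly).
#' @param strategy One of `"SEQUENCE_ONLY"`, `"INDEX_ONLY"`,
#'   `"ALL_READS"`.
#' @param q_thresh Phred-equivalent threshold, `>= 0`.
#' @return Logical vector, one element per triplet.
#' @export
passes_filter <- function(x, strategy, q_thresh) {
  stopifnot(length(q_thresh) == 1L, q_thresh >= 0)
  segs <- .strategy_segments(strategy)
  if (!all(segs %in% names(x))) {
    # raw triplet_set: derive the mean error probabilities
    stopifnot(all(c("seq_quals", "i5_quals", "i7_quals") %in% names(x)))
    x <- data.frame(
      seq_mean_p = mean_error_prob_many(x$seq_quals),
      i5_mean_p = mean_error_prob_many(x$i5_quals),
      i7_mean_p = mean_error_prob_many(x$i7_quals)
    )
  }
  bound <- 10^(-q_thresh / 10)
  pass <- rep(TRUE, nrow(x))
  for (s in segs) pass <- pass & x[[s]] <= bound
  pass
}

#' Sweep quality thresholds over a classified run
#'
#' Demultiplexes and classifies once (or reuses a supplied
#' `classified_triplets`), then evaluates the filter at every threshold:
#' reads retained, surviving counts per taxonomy label, and the summed
#' negative-control epsilon among survivors. The resulting curve is the
#' basis for [choose_threshold()].
#'
#' @param x A `triplet_set` (raw run) or a `classified_triplets` already
#'   produced with the same sheet and references.
#' @param sheet A [sample_sheet()].
#' @param refs A [reference_set()]; ignored when `x` is already
#'   classified.
#' @param strategy Filter strategy, see [passes_filter()].
#' @param thresholds Ascending Phred-equivalent thresholds (default
#'   `0:40`, step 1).
#' @param max_mismatch,max_edit Demultiplexing parameters, used only when
#'   `x` is a raw `triplet_set`.
#' @return A `sweep_curve` data.frame with one row per threshold:
#'   `q_thresh`, `reads_retained`, `frac_retained`, one `n_<label>` column
#'   per taxonomy label, and `epsilon_sum`. The `strategy` is kept as an
#'   attribute.
#' @export
sweep_thresholds <- function(x, sheet, refs = NULL, strategy = "INDEX_ONLY",
                             thresholds = 0:40, max_mismatch = 1L,
                             max_edit = 4L) {
  if (length(thresholds) == 0L) stop("empty threshold list")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  if (inherits(x, "classified_triplets")) {
    classified <- x
  } else {
    stopifnot(!is.null(refs))
    classified <- classify_triplets(
      demultiplex(x, sheet, refs, max_mismatch, max_edit), sheet)
  }
  ctrl <- enumerate_control_pairs(sheet)
  n_total <- nrow(classified)
  rows <- lapply(thresholds, function(q) {
    keep <- passes_filter(classified, strategy, q)
    kept <- classified[keep, , drop = FALSE]
    cnt <- table(factor(kept$label, levels = CLASS_LABELS))
    eps <- estimate_epsilon(count_index_pairs(kept), ctrl)$total
    cbind(
      data.frame(q_thresh = q, reads_retained = sum(keep),
                 frac_retained = if (n_total > 0) sum(keep) / n_total else NA_real_),
      as.data.frame(setNames(as.list(as.numeric(cnt)),
                             paste0("n_", tolower(names(cnt))))),
      data.frame(epsilon_sum = eps)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_curve", "data.frame")
  attr(out, "strategy") <- toupper(strategy)
  attr(out, "n_total") <- n_total
  out
}

#' Choose the quality threshold from a sweep curve
#'
#' Returns the smallest threshold whose surviving control-pair epsilon is
#' at most `max_epsilon_fraction` of the unfiltered epsilon — the point
#' that removes the targeted share of misassignments while discarding the
#' fewest reads. When no threshold attains the target, the
#' epsilon-minimizing threshold is returned instead (ties broken toward
#' more retained reads, then toward the smaller threshold) with a
#' warning. When the unfiltered epsilon is already zero there is nothing
#' to remove and the smallest threshold is returned.
#'
#' @param curve A `sweep_curve` from [sweep_thresholds()].
#' @param max_epsilon_fraction Target fraction of the unfiltered epsilon
#'   allowed to survive (default 0.1).
#' @return The chosen threshold (numeric scalar) with attributes
#'   `frac_retained` and `epsilon_sum` at that threshold.
#' @export
choose_threshold <- function(curve, max_epsilon_fraction = 0.1) {
  stopifnot(inherits(curve, "sweep_curve"), nrow(curve) > 0,
            max_epsilon_fraction >= 0)
  eps0 <- curve$epsilon_sum[curve$q_thresh == min(curve$q_thresh)][1]
  pick <- function(i) {
    structure(curve$q_thresh[i],
              frac_retained = curve$frac_retained[i],
              epsilon_sum = curve$epsilon_sum[i])
  }
  if (eps0 == 0) return(pick(1L))
  ok <- which(curve$epsilon_sum / eps0 <= max_epsilon_fraction)
  if (length(ok)) return(pick(ok[1L]))
  warning("no threshold attains the epsilon target; ",
          "returning the epsilon-minimizing threshold")
  minimizers <- which(curve$epsilon_sum == min(curve$epsilon_sum))
  best <- minimizers[order(-curve$frac_retained[minimizers],
                           curve$q_thresh[minimizers])][1L]
  pick(best)
}

#' Write a sweep curve to TSV
#' @param curve A `sweep_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_curve <- function(curve, path) {
  write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
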