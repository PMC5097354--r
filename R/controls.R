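# Negative-control index pairs and the epsilon misassignment estimate.
#
# Under unique dual indexing, a single wrong index lands a read on an
# (i5, i7) combination that no sample was given. Every such "missing" pair
# is a built-in negative control: in the absence of misassignment it should
# receive zero reads, so its read count estimates the amount of cross-talk
# without needing control samples or even knowledge of the amplicons.

#' Enumerate the negative-control index pairs of a design
#'
#' All (i5, i7) combinations whose components each occur somewhere in the
#' sheet but which, as a pair, are assigned to no sample. A fully unique
#' dual-indexed design of n samples yields n^2 - n control pairs (e.g. 182
#' for 14 samples).
#'
#' @param sheet A [sample_sheet()].
#' @return A data.frame with columns `i5`, `i7`, one row per control pair
#'   (zero rows when every combination is used).
#' @export
enumerate_control_pairs <- function(sheet) {
  stopifnot(inherits(sheet, "sample_sheet"))
  combos <- expand.grid(i5 = unique(sheet$i5), i7 = unique(sheet$i7),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  used <- paste(sheet$i5, sheet$i7)
  out <- combos[!(paste(combos$i5, combos$i7) %in% used), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count reads per uniquely matched (i5, i7) index pair
#'
#' Tallies every read whose two index reads each matched uniquely,
#' regardless of where its sequence read mapped — this is the quantity the
#' control pairs observe.
#'
#' @param assignment A `triplet_assignment` (or `classified_triplets`).
#' @return A data.frame `i5`, `i7`, `n`.
#' @export
count_index_pairs <- function(assignment) {
  keep <- assignment$i5_status == "unique" & assignment$i7_status == "unique"
  if (!any(keep)) {
    return(data.frame(i5 = character(0), i7 = character(0), n = integer(0)))
  }
  agg <- as.data.frame(table(i5 = assignment$i5[keep],
                             i7 = assignment$i7[keep]),
                       responseName = "n", stringsAsFactors = FALSE)
  agg <- agg[agg$n > 0, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Estimate misassignment counts from negative-control pairs
#'
#' For each control pair, epsilon is the number of reads whose matched
#' index pair equals that pair; the sum over all control pairs is the
#' misassignment signal tracked during threshold sweeps. Pairs with no
#' reads report an explicit 0.
#'
#' @param pair_counts Data.frame `i5`, `i7`, `n` as from
#'   [count_index_pairs()].
#' @param control_pairs Data.frame `i5`, `i7` from
#'   [enumerate_control_pairs()].
#' @return A list with `per_pair` (data.frame `i5`, `i7`, `epsilon`) and
#'   `total` (summed epsilon; 0 for an empty control list).
#' @export
estimate_epsilon <- function(pair_counts, control_pairs) {
  stopifnot(is.data.frame(pair_counts), is.data.frame(control_pairs))
  if (nrow(control_pairs) == 0L) {
    return(list(per_pair = data.frame(i5 = character(0), i7 = character(0),
                                      epsilon = numeric(0)),
                total = 0))
  }
  key_counts <- paste(pair_counts$i5, pair_counts$i7)
  key_ctrl <- paste(control_pairs$i5, control_pairs$i7)
  idx <- match(key_ctrl, key_counts)
  eps <- as.numeric(ifelse(is.na(idx), 0, pair_counts$n[idx]))
  per_pair <- data.frame(i5 = control_pairs$i5, i7 = control_pairs$i7,
                         epsilon = eps, stringsAsFactors = FALSE)
  list(per_pair = per_pair, total = sum(eps))
}
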