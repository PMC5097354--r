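# Misassignment taxonomy and cross-talk rates.
#
# A demultiplexed triplet names three things: an i5 index, an i7 index, and
# (via the sequence read) a sample of origin. Agreement of all three is a
# correct read; disagreement patterns define the taxonomy below. The sequence
# read acts as the truth anchor for index misassignments because each
# sample's amplicon is unique and far (in edit distance) from every other.

CLASS_LABELS <- c("CORRECT", "INDEX_MIS_I5", "INDEX_MIS_I7", "SEQ_MIS",
                  "MULTI_MIS", "UNASSIGNED")

#' Classify demultiplexed triplets into the misassignment taxonomy
#'
#' Every triplet receives exactly one label:
#'
#' * `UNASSIGNED` — any step failed to match uniquely (none or ambiguous);
#' * `CORRECT` — the (i5, i7) pair belongs to a sample on the sheet and
#'   the sequence matched that same sample's reference;
#' * `SEQ_MIS` — the index pair belongs to a sample but the sequence
#'   matched a *different* sample's reference (sequence misassignment);
#' * `INDEX_MIS_I5` / `INDEX_MIS_I7` — exactly one index disagrees with
#'   the sample implied by the other two steps (index misassignment);
#' * `MULTI_MIS` — two or more steps disagree and the index pair is not on
#'   the sheet.
#'
#' @param assignment A `triplet_assignment` from [demultiplex()].
#' @param sheet The same [sample_sheet()] used for demultiplexing.
#' @return The assignment with an added `label` factor column (levels as
#'   above); class `classified_triplets`.
#' @export
classify_triplets <- function(assignment, sheet) {
  stopifnot(inherits(assignment, "triplet_assignment"),
            inherits(sheet, "sample_sheet"))
  ok5 <- is.na(assignment$i5) | assignment$i5 %in% sheet$i5
  ok7 <- is.na(assignment$i7) | assignment$i7 %in% sheet$i7
  oks <- is.na(assignment$ref_sample) | assignment$ref_sample %in% sheet$sample_id
  if (!all(ok5 & ok7 & oks)) {
    stop("assignment references indices or samples absent from the sheet")
  }
  unassigned <- assignment$i5_status != "unique" |
    assignment$i7_status != "unique" | assignment$ref_status != "unique"
  if (any(!unassigned & is.na(assignment$ref_sample))) {
    stop("assignment contains references that no sheet sample claims")
  }

  pair_key <- paste(assignment$i5, assignment$i7)
  sheet_key <- paste(sheet$i5, sheet$i7)
  pair_sample <- sheet$sample_id[match(pair_key, sheet_key)]  # NA if pair unused

  s_ref <- match(assignment$ref_sample, sheet$sample_id)
  i5_of_ref <- sheet$i5[s_ref]
  i7_of_ref <- sheet$i7[s_ref]

  yes <- function(cond) !is.na(cond) & cond   # NA (unassigned rows) -> FALSE
  pair_known <- !is.na(pair_sample)
  label <- rep("MULTI_MIS", nrow(assignment))
  label[yes(pair_known & pair_sample == assignment$ref_sample)] <- "CORRECT"
  label[yes(pair_known & pair_sample != assignment$ref_sample)] <- "SEQ_MIS"
  label[yes(!pair_known & assignment$i7 == i7_of_ref &
              assignment$i5 != i5_of_ref)] <- "INDEX_MIS_I5"
  label[yes(!pair_known & assignment$i5 == i5_of_ref &
              assignment$i7 != i7_of_ref)] <- "INDEX_MIS_I7"
  label[unassigned] <- "UNASSIGNED"

  assignment$label <- factor(label, levels = CLASS_LABELS)
  class(assignment) <- c("classified_triplets", class(assignment))
  assignment
}

#' Cross-talk rates from classification counts
#'
#' @param counts Named numeric vector (or table) of read counts per
#'   taxonomy label; missing labels count as zero.
#' @return A list with elements `seq_mis_rate` (sequence misassignments
#'   over reads whose index pair is on the sheet, i.e. `SEQ_MIS /
#'   (CORRECT + SEQ_MIS)`), `index_mis_rate` (`(INDEX_MIS_I5 +
#'   INDEX_MIS_I7)` over all reads mapped to a known reference, i.e. all
#'   non-`UNASSIGNED` reads), `overall_incorrect_rate` (all misassigned
#'   labels over all non-`UNASSIGNED` reads), and `undefined` — a character
#'   vector naming rates whose denominator was zero (those rates are `NA`,
#'   never silently 0).
#' @examples
#' compute_rates(c(CORRECT = 9990, SEQ_MIS = 10))  # seq_mis_rate 0.001
#' @export
compute_rates <- function(counts) {
  cnt <- setNames(numeric(length(CLASS_LABELS)), CLASS_LABELS)
  counts <- unlist(as.list(counts))
  bad <- setdiff(names(counts), CLASS_LABELS)
  if (length(bad)) stop("unknown classification labels: ",
                        paste(bad, collapse = ", "))
  cnt[names(counts)] <- counts
  mis_idx <- cnt[["INDEX_MIS_I5"]] + cnt[["INDEX_MIS_I7"]]
  mapped_pair <- cnt[["CORRECT"]] + cnt[["SEQ_MIS"]]
  mapped_ref <- sum(cnt) - cnt[["UNASSIGNED"]]
  undefined <- character(0)
  rate <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(NA_real_)
    }
    num / den
  }
  list(
    seq_mis_rate = rate(cnt[["SEQ_MIS"]], mapped_pair, "seq_mis_rate"),
    index_mis_rate = rate(mis_idx, mapped_ref, "index_mis_rate"),
    overall_incorrect_rate = rate(
      cnt[["SEQ_MIS"]] + mis_idx + cnt[["MULTI_MIS"]], mapped_ref,
      "overall_incorrect_rate"),
    undefined = undefined
  )
}

#' Full cross-talk report for a classified run
#'
#' Aggregates a classified run into label counts, pooled rates,
#' per-sample rates (by the sample the sequence read anchors to), counts
#' per observed (i5, i7, reference-sample) triplet, and the
#' negative-control estimates of [estimate_epsilon()].
#'
#' @param classified A `classified_triplets` from [classify_triplets()].
#' @param sheet The [sample_sheet()] used.
#' @return A `crosstalk_report` list: `counts` (named vector over labels),
#'   `rates` (see [compute_rates()]), `per_sample` (data.frame of rates by
#'   anchoring sample), `triplet_counts` (data.frame `i5`, `i7`,
#'   `ref_sample`, `label`, `n`), `control` (list `per_pair`, `total` from
#'   [estimate_epsilon()]), and `n_total`.
#' @export
crosstalk_report <- function(classified, sheet) {
  stopifnot(inherits(classified, "classified_triplets"))
  counts <- table(classified$label)
  counts <- setNames(as.numeric(counts), names(counts))
  stopifnot(sum(counts) == nrow(classified))

  tc <- as.data.frame(
    table(i5 = addNA(factor(classified$i5)),
          i7 = addNA(factor(classified$i7)),
          ref_sample = addNA(factor(classified$ref_sample)),
          label = classified$label),
    responseName = "n", stringsAsFactors = FALSE
  )
  tc <- tc[tc$n > 0, , drop = FALSE]
  rownames(tc) <- NULL

  per_sample <- do.call(rbind, lapply(sheet$sample_id, function(s) {
    sub <- classified$label[!is.na(classified$ref_sample) &
                              classified$ref_sample == s]
    r <- compute_rates(table(sub))
    data.frame(sample_id = s, n_mapped = length(sub),
               seq_mis_rate = r$seq_mis_rate,
               index_mis_rate = r$index_mis_rate,
               overall_incorrect_rate = r$overall_incorrect_rate,
               stringsAsFactors = FALSE)
  }))

  control <- estimate_epsilon(count_index_pairs(classified),
                              enumerate_control_pairs(sheet))
  out <- list(counts = counts, rates = compute_rates(counts),
              per_sample = per_sample, triplet_counts = tc,
              control = control, n_total = nrow(classified))
  class(out) <- "crosstalk_report"
  out
}

#' @export
print.crosstalk_report <- function(x, ...) {
  cat("Cross-talk report over", x$n_total, "triplets\n")
  cat("  counts:\n")
  for (l in names(x$counts)) cat(sprintf("    %-12s %10d\n", l, as.integer(x$counts[[l]])))
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f%%", 100 * v)
  cat("  sequence misassignment rate:", pct(x$rates$seq_mis_rate), "\n")
  cat("  index misassignment rate:   ", pct(x$rates$index_mis_rate), "\n")
  cat("  overall incorrect rate:     ", pct(x$rates$overall_incorrect_rate), "\n")
  cat("  control pairs:", nrow(x$control$per_pair),
      " summed epsilon:", x$control$total, "\n")
  invisible(x)
}

#' Serialize a cross-talk report
#'
#' Writes the per-triplet counts as TSV and the summary (counts, rates,
#' control-pair epsilon table) as JSON.
#'
#' @param report A [crosstalk_report()].
#' @param tsv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, the report.
#' @export
write_crosstalk_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "crosstalk_report"))
  if (!is.null(tsv_path)) {
    write.table(report$triplet_counts, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_total = report$n_total,
           counts = as.list(report$counts),
           rates = report$rates[c("seq_mis_rate", "index_mis_rate",
                                  "overall_incorrect_rate")],
           epsilon_total = report$control$total,
           epsilon_per_pair = report$control$per_pair),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}
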