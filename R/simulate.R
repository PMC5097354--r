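# Synthetic multiplexed-run simulator with ground truth.
#
# The simulator emulates the statistical structure the analysis relies on:
# a unique dual-indexed design whose indices and amplicons are well
# separated in sequence space; rare, distance-independent misassignment
# events; and the quality signature of misassigned reads — the misassigned
# read step carries low quality scores across its whole length, while
# sequence misassignments are low quality in all three steps. Per-base
# substitution errors are coupled to the quality scores: each base is
# misread with exactly the probability its Phred score claims.

SIM_MIN_INDEX_HAMMING <- 3L
SIM_MIN_REF_EDIT <- 14L
SIM_BASES <- c("A", "C", "G", "T")

#' Configure a simulated multiplexed run
#'
#' Defaults mirror the study design this package targets: 14 samples with
#' unique 8-bp i5 and i7 indices (pairwise hamming distance at least 3),
#' 51-cycle single-end sequence reads separated by an edit distance of at
#' least 14, roughly 100,000 triplets in total, and per-read misassignment
#' probabilities at the magnitudes observed on a real lane (0.08% per
#' index side, 0.09% for sequence misassignment, about 0.25% combined).
#'
#' @param n_samples Number of multiplexed samples.
#' @param index_length Index length in bases.
#' @param read_length Sequence read length in cycles (`>= 14` so the
#'   reference-separation invariant is attainable).
#' @param reads_per_sample Triplets emitted per sample.
#' @param p_index_mis_i5,p_index_mis_i7,p_seq_mis Per-read probabilities
#'   of the three misassignment events; their sum must stay below 1.
#' @param q_high_mean,q_low_mean Segment-mean Phred quality for correct
#'   vs misassigned read steps.
#' @param q_sd Standard deviation of the segment-level quality draw.
#' @param substitute Couple substitution errors to the quality scores
#'   (default `TRUE`). `FALSE` emits every base verbatim from its template
#'   — qualities are still drawn — which makes misassignment counts and
#'   control-pair epsilon exactly traceable to the injected events.
#' @param seed RNG seed (integer below 2^31).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 14L, index_length = 8L, read_length = 51L,
                       reads_per_sample = 7143L,
                       p_index_mis_i5 = 8e-4, p_index_mis_i7 = 8e-4,
                       p_seq_mis = 9e-4,
                       q_high_mean = 35, q_low_mean = 15, q_sd = 3,
                       substitute = TRUE, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              index_length = as.integer(index_length),
              read_length = as.integer(read_length),
              reads_per_sample = as.integer(reads_per_sample),
              p_index_mis_i5 = p_index_mis_i5,
              p_index_mis_i7 = p_index_mis_i7,
              p_seq_mis = p_seq_mis,
              q_high_mean = q_high_mean, q_low_mean = q_low_mean,
              q_sd = q_sd, substitute = isTRUE(substitute),
              seed = as.integer(seed))
  probs <- c(cfg$p_index_mis_i5, cfg$p_index_mis_i7, cfg$p_seq_mis)
  if (any(probs < 0) || any(probs > 1) || sum(probs) >= 1) {
    stop("misassignment probabilities must lie in [0,1] and sum below 1")
  }
  stopifnot(cfg$n_samples >= 1, cfg$index_length >= 1,
            cfg$read_length >= SIM_MIN_REF_EDIT, cfg$reads_per_sample >= 1,
            cfg$q_sd >= 0, cfg$q_high_mean >= 0, cfg$q_low_mean >= 0)
  if (is.na(cfg$seed)) stop("seed must be a finite integer below 2^31")
  class(cfg) <- "sim_config"
  cfg
}

# Rejection-sample n sequences of given length whose pairwise distance
# (dist_fun) is at least min_dist; bounded attempts.
.sample_separated <- function(n, length, min_dist, dist_fun,
                              max_attempts = 1000L * n, what = "sequence") {
  out <- character(0)
  attempts <- 0L
  while (length(out) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "could not generate %d %ss of length %d with pairwise separation >= %d",
        n, what, length, min_dist))
    }
    cand <- paste(SIM_BASES[sample.int(4L, length, replace = TRUE)],
                  collapse = "")
    if (length(out) == 0L ||
        min(dist_fun(rep(cand, length(out)), out)) >= min_dist) {
      out <- c(out, cand)
    }
  }
  out
}

#' Generate a well-separated multiplex design
#'
#' Draws random unique dual indices (pairwise hamming distance at least 3
#' within each index side) and random amplicon references (pairwise edit
#' distance at least 14) by rejection sampling. Deterministic given the
#' config seed; errors out if the separation is unattainable for the
#' requested lengths and counts (e.g. hundreds of samples on 4-bp
#' indices).
#'
#' @param config A [sim_config()].
#' @return A list with `sheet` (a [sample_sheet()]) and `refs` (a
#'   [reference_set()]).
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  i5 <- .sample_separated(config$n_samples, config$index_length,
                          SIM_MIN_INDEX_HAMMING, .hamming_c, what = "i5 index")
  i7 <- .sample_separated(config$n_samples, config$index_length,
                          SIM_MIN_INDEX_HAMMING, .hamming_c, what = "i7 index")
  refs <- .sample_separated(
    config$n_samples, config$read_length, SIM_MIN_REF_EDIT,
    function(a, b) .levenshtein_c(a, b, config$read_length),
    what = "reference")
  ids <- sprintf("S%02d", seq_len(config$n_samples))
  list(
    sheet = sample_sheet(data.frame(sample_id = ids, i5 = i5, i7 = i7,
                                    reference_id = ids,
                                    stringsAsFactors = FALSE)),
    refs = reference_set(ids, refs)
  )
}

# Draw one read segment for all n reads at once: a per-read segment mean
# quality (low or high regime), per-base jitter, then quality-coupled
# substitutions into the template bases.
.sim_segment <- function(templates, low, q_low_mean, q_high_mean, q_sd,
                         substitute = TRUE) {
  n <- length(templates)
  L <- nchar(templates[1])
  mean_q <- rnorm(n, ifelse(low, q_low_mean, q_high_mean), q_sd)
  mean_q <- pmin(pmax(mean_q, 2), 41)
  Q <- round(mean_q + matrix(rnorm(n * L, 0, 1), n, L))
  Q <- pmin(pmax(Q, 2), 41)
  base_mat <- matrix(unlist(strsplit(templates, "", fixed = TRUE)),
                     nrow = n, byrow = TRUE)
  perr <- 10^(-Q / 10)
  err <- matrix(substitute & (runif(n * L) < perr), n, L)
  n_err <- sum(err)
  if (n_err > 0L) {
    cur <- match(base_mat[err], SIM_BASES)
    shift <- floor(runif(n_err) * 3) + 1  # uniform over the 3 alternatives
    base_mat[err] <- SIM_BASES[((cur - 1 + shift) %% 4) + 1]
  }
  qlookup <- vapply(0:41, function(q) intToUtf8(q + 33L), character(1))
  list(
    bases = do.call(paste0, as.data.frame(base_mat, stringsAsFactors = FALSE)),
    quals = do.call(paste0, as.data.frame(matrix(qlookup[Q + 1], n, L),
                                          stringsAsFactors = FALSE))
  )
}

#' Simulate a multiplexed sequencing run
#'
#' Emits `n_samples * reads_per_sample` triplets. Each read draws a label
#' by the configured probabilities: correct reads take all three segments
#' from their own sample with high-quality scores; an index-misassigned
#' read takes the affected index from a uniformly chosen other sample and
#' gives that segment low-quality scores; a sequence-misassigned read
#' takes its sequence from another sample and is low quality in all three
#' segments. Segment qualities are a clamped normal segment mean (range
#' [2, 41], the Illumina RTA binning extremes) plus unit per-base jitter;
#' every base is then substituted to one of the 3 alternative bases with
#' probability `10^(-Q/10)`. Identical seeds give byte-identical output.
#'
#' @param config A [sim_config()].
#' @param design A design from [generate_design()] (regenerated from the
#'   config when omitted); supply your own to simulate a custom sheet.
#' @param dir Output directory; when non-`NULL`, writes `r1.fastq`,
#'   `i7.fastq`, `i5.fastq`, `truth.tsv`, `samplesheet.tsv` and
#'   `references.fasta` there.
#' @return A list: `triplets` (in-memory `triplet_set`), `truth`
#'   (data.frame `id`, `origin_sample`, `label`, `foreign_sample`),
#'   `sheet`, `refs`, and `paths` (named file paths, or `NULL`).
#' @export
simulate_run <- function(config, design = NULL, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(design)) design <- generate_design(config)
  sheet <- design$sheet
  refs <- design$refs
  stopifnot(nrow(sheet) == config$n_samples)
  set.seed(config$seed + 1L)

  n <- config$n_samples * config$reads_per_sample
  origin <- rep(seq_len(config$n_samples), each = config$reads_per_sample)

  u <- runif(n)
  p5 <- config$p_index_mis_i5
  p7 <- config$p_index_mis_i7
  ps <- config$p_seq_mis
  label <- rep("CORRECT", n)
  label[u < p5 + p7 + ps] <- "SEQ_MIS"
  label[u < p5 + p7] <- "INDEX_MIS_I7"
  label[u < p5] <- "INDEX_MIS_I5"

  # foreign sample for misassigned segments (uniform over the others);
  # drawn for every read so the draw count is fixed, used only when needed
  foreign <- 1L + floor(runif(n) * (config$n_samples - 1L))
  foreign <- foreign + (foreign >= origin)
  if (config$n_samples == 1L) foreign <- origin  # degenerate single-sample run

  is_mis <- label != "CORRECT"
  seq_src <- ifelse(label == "SEQ_MIS", foreign, origin)
  i5_src <- ifelse(label == "INDEX_MIS_I5", foreign, origin)
  i7_src <- ifelse(label == "INDEX_MIS_I7", foreign, origin)
  seq_low <- label == "SEQ_MIS"
  i5_low <- label %in% c("INDEX_MIS_I5", "SEQ_MIS")
  i7_low <- label %in% c("INDEX_MIS_I7", "SEQ_MIS")

  seq_seg <- .sim_segment(refs$sequence[seq_src], seq_low,
                          config$q_low_mean, config$q_high_mean, config$q_sd,
                          config$substitute)
  i5_seg <- .sim_segment(sheet$i5[i5_src], i5_low,
                         config$q_low_mean, config$q_high_mean, config$q_sd,
                         config$substitute)
  i7_seg <- .sim_segment(sheet$i7[i7_src], i7_low,
                         config$q_low_mean, config$q_high_mean, config$q_sd,
                         config$substitute)

  ids <- sprintf("sim%07d", seq_len(n))
  triplets <- data.frame(
    id = ids,
    seq_bases = seq_seg$bases, seq_quals = seq_seg$quals,
    i5_bases = i5_seg$bases, i5_quals = i5_seg$quals,
    i7_bases = i7_seg$bases, i7_quals = i7_seg$quals,
    stringsAsFactors = FALSE
  )
  class(triplets) <- c("triplet_set", "data.frame")
  truth <- data.frame(
    id = ids,
    origin_sample = sheet$sample_id[origin],
    label = label,
    foreign_sample = ifelse(is_mis, sheet$sample_id[foreign], NA_character_),
    stringsAsFactors = FALSE
  )

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(r1 = file.path(dir, "r1.fastq"),
               i7 = file.path(dir, "i7.fastq"),
               i5 = file.path(dir, "i5.fastq"),
               truth = file.path(dir, "truth.tsv"),
               samplesheet = file.path(dir, "samplesheet.tsv"),
               references = file.path(dir, "references.fasta"))
    write_fastq(data.frame(id = ids, bases = triplets$seq_bases,
                           quals = triplets$seq_quals), paths[["r1"]])
    write_fastq(data.frame(id = ids, bases = triplets$i7_bases,
                           quals = triplets$i7_quals), paths[["i7"]])
    write_fastq(data.frame(id = ids, bases = triplets$i5_bases,
                           quals = triplets$i5_quals), paths[["i5"]])
    write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_sample_sheet(sheet, paths[["samplesheet"]])
    fa <- Biostrings::DNAStringSet(refs$sequence)
    names(fa) <- refs$reference_id
    Biostrings::writeXStringSet(fa, paths[["references"]])
  }
  list(triplets = triplets, truth = truth, sheet = sheet, refs = refs,
       paths = paths)
}
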