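# Theoretical index-misassignment model under independent substitutions.
#
# If misread bases were the cause of index misassignment, the rate of
# crossover from index A to an index B at hamming distance d would fall
# geometrically with d (each extra difference costs another factor ~ p/3).
# Observed misassignment rates do not decay this way, which is the evidence
# that misreads are not the mechanism. The model here makes that comparison
# quantitative.

#' Define an independent-substitution index error model
#'
#' Each of the `L` index bases is misread independently with probability
#' `p`, landing uniformly on one of the 3 alternative bases. An observed
#' index read is accepted by an expected index when their hamming distance
#' is at most `k` mismatches (mirroring [match_index()]).
#'
#' @param p Per-base substitution probability in `[0, 1]`.
#' @param L Index length in bases (`>= 1`).
#' @param k Allowed mismatches (`>= 0`).
#' @return A `theoretical_model` list.
#' @export
theoretical_model <- function(p, L, k = 1L) {
  stopifnot(length(p) == 1L, p >= 0, p <= 1,
            length(L) == 1L, L >= 1, length(k) == 1L, k >= 0)
  structure(list(p = as.numeric(p), L = as.integer(L), k = as.integer(k)),
            class = "theoretical_model")
}

#' Theoretical probability of misassignment to a specific wrong index
#'
#' Closed-form probability that an index transmitted as A is matched to a
#' specific wrong index B at hamming distance `d`, under the
#' independent-substitution model. The sum runs over the number of
#' differing positions that are "repaired" toward B (each costs `p/3`),
#' the differing positions substituted to some third base, and the
#' agreeing positions misread (each costs `p`), subject to the `<= k`
#' mismatch acceptance rule.
#'
#' By default the event is conditioned on both acceptance by B *and*
#' rejection by the true index A (hamming to A greater than `k`), which is
#' when the read actually switches identity; `condition_on_true_reject =
#' FALSE` gives the simpler "accepted by B" probability. At `d = 0` the
#' two coincide and the function returns the self-match probability
#' `1 - P(> k errors)`.
#'
#' @param model A [theoretical_model()].
#' @param d Hamming distance between A and B, `0 <= d <= L` (vectorized).
#' @param condition_on_true_reject Require the read to also miss the true
#'   index (default `TRUE`).
#' @return Numeric vector of probabilities.
#' @export
theoretical_misassignment_rate <- function(model, d,
                                           condition_on_true_reject = TRUE) {
  stopifnot(inherits(model, "theoretical_model"))
  d <- as.integer(d)
  if (any(d < 0) || any(d > model$L)) stop("'d' must lie in [0, L]")
  vapply(d, function(di) {
    .theory_rate_one(model$p, model$L, model$k, di, condition_on_true_reject)
  }, numeric(1))
}

.theory_rate_one <- function(p, L, k, d, condition_on_true_reject) {
  if (d == 0L) {
    # B is A itself: probability the read is accepted by its own index
    return(pbinom(k, L, p))
  }
  # Differing positions (d of them): stay at A's base (match A, mismatch B)
  # w.p. 1-p; flip to B's base (mismatch A, match B) w.p. p/3; flip to a
  # third base (mismatch both) w.p. 2p/3. Agreeing positions (L-d): misread
  # (mismatch both) w.p. p.
  tot <- 0
  for (a in 0:d) for (b in 0:(d - a)) {
    cc <- d - a - b
    w_diff <- choose(d, a) * choose(d - a, b) *
      (1 - p)^a * (p / 3)^b * (2 * p / 3)^cc
    if (w_diff == 0 && p > 0) next
    for (j in 0:(L - d)) {
      hB <- a + cc + j
      hA <- b + cc + j
      if (hB > k) next
      if (condition_on_true_reject && hA <= k) next
      tot <- tot + w_diff * dbinom(j, L - d, p)
    }
  }
  tot
}

#' Leading-order probability of crossing between indices by misreads alone
#'
#' To convert one index into another at hamming distance `d`, at least `d`
#' specific positions must each be misread; to leading order in `p` that
#' probability is `p^d`. At a 1% per-base error rate (Q20) and the minimum
#' three differences of a well-separated index set this is `10^-6`; for
#' both indices of a unique dual pair to be misread it is the square,
#' `10^-12` — far below what one read in ten million could produce, which
#' is why misreads cannot explain observed cross-talk.
#'
#' @param p Per-base substitution probability.
#' @param d Number of positions that must be misread.
#' @param both Square the result, for the two-index (unique dual) case.
#' @return Numeric probability `p^d` (or its square).
#' @export
misread_crossover_approx <- function(p, d, both = FALSE) {
  stopifnot(p >= 0, p <= 1, d >= 0)
  out <- p^d
  if (both) out <- out^2
  out
}

#' Exact binomial tail for sequence-read crossover
#'
#' Probability of at least `n_subs` substitutions among `n_cycles`
#' independently misread bases at per-base error `p` — the chance a
#' sequence read crosses the edit-distance gap to another sample's
#' amplicon by misreads alone. For 17 or more substitutions in 51 cycles
#' at 1% this is about 1.3e-21.
#'
#' @param n_cycles Read length.
#' @param n_subs Minimum number of substitutions.
#' @param p Per-base error probability.
#' @return `P(X >= n_subs)`, `X ~ Binomial(n_cycles, p)`.
#' @export
substitution_tail_prob <- function(n_cycles, n_subs, p) {
  stopifnot(n_cycles >= 1, n_subs >= 0, p >= 0, p <= 1)
  pbinom(n_subs - 1, n_cycles, p, lower.tail = FALSE)
}

#' Observed vs theoretical misassignment rate by index hamming distance
#'
#' For each index side (i5, i7) and every ordered pair (anchoring sample,
#' foreign index), computes the observed rate of reads anchored to the
#' sample (by their sequence read) that carried the foreign index, and
#' groups these rates by the hamming distance between the sample's own
#' index and the foreign one. The theoretical column is the
#' independent-substitution prediction at the same distance.
#'
#' @param model A [theoretical_model()].
#' @param sheet A [sample_sheet()].
#' @param classified A `classified_triplets` from [classify_triplets()].
#' @param condition_on_true_reject Passed to
#'   [theoretical_misassignment_rate()].
#' @return A data.frame with columns `d`, `n_pairs` (ordered
#'   sample-x-foreign-index pairs at that distance), `observed_rate`
#'   (mean over those pairs), `theoretical_rate`.
#' @export
rate_vs_distance_table <- function(model, sheet, classified,
                                   condition_on_true_reject = TRUE) {
  stopifnot(inherits(model, "theoretical_model"),
            inherits(sheet, "sample_sheet"),
            inherits(classified, "classified_triplets"))
  rows <- list()
  for (side in c("i5", "i7")) {
    own <- sheet[[side]]
    lab <- if (side == "i5") "INDEX_MIS_I5" else "INDEX_MIS_I7"
    for (s in seq_len(nrow(sheet))) {
      anchored <- !is.na(classified$ref_sample) &
        classified$ref_sample == sheet$sample_id[s]
      n_anchor <- sum(anchored)
      foreign <- setdiff(unique(own), own[s])
      for (f in foreign) {
        d <- hamming(own[s], f)
        n_mis <- sum(anchored & classified$label == lab &
                       !is.na(classified[[side]]) & classified[[side]] == f)
        rows[[length(rows) + 1L]] <- data.frame(
          d = d, rate = if (n_anchor > 0) n_mis / n_anchor else NA_real_)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(d = integer(0), n_pairs = integer(0),
                      observed_rate = numeric(0), theoretical_rate = numeric(0)))
  }
  all_rows <- do.call(rbind, rows)
  ds <- sort(unique(all_rows$d))
  out <- data.frame(
    d = ds,
    n_pairs = vapply(ds, function(x) sum(all_rows$d == x), integer(1)),
    observed_rate = vapply(ds, function(x) {
      mean(all_rows$rate[all_rows$d == x], na.rm = TRUE)
    }, numeric(1)),
    theoretical_rate = theoretical_misassignment_rate(
      model, ds, condition_on_true_reject)
  )
  out
}
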