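# Shared fixtures and independent oracles, all built in code.

# Uniform-quality Phred+33 string of length n.
qstr <- function(q, n) strrep(intToUtf8(q + 33L), n)

# A small hand-written unique dual-indexed design: 3 samples, 8-bp indices
# with pairwise hamming distance >= 3 on each side.
tiny_sheet <- function() {
  sample_sheet(data.frame(
    sample_id = c("S1", "S2", "S3"),
    i5 = c("AAAAAAAA", "CCCCAAAA", "GGGGGGGG"),
    i7 = c("TTTTTTTT", "AAAATTTT", "CCCCCCCC"),
    stringsAsFactors = FALSE
  ))
}

# Matching references: fixed aperiodic 51-mers, pairwise edit distance >= 27.
tiny_refs <- function() {
  reference_set(
    c("S1", "S2", "S3"),
    c("GAGATACGGATCTATAGCTGTCCAGCGAGCTAGGGATGTCATTCGCGCTAC",
      "GTCACGGGTATGTTAGTACTGACTGTTGAACTACAGCAATTTAACGCAGCA",
      "CGCCCCGGGCGCCGTTGAGACGCCGCACATGGGAACCACGGCTGTGAAATG")
  )
}

# One triplet row in the raw triplet_set layout.
make_triplet <- function(id, seq_bases, i5_bases, i7_bases,
                         seq_q = 35L, i5_q = 35L, i7_q = 35L) {
  out <- data.frame(
    id = id,
    seq_bases = seq_bases, seq_quals = qstr(seq_q, nchar(seq_bases)),
    i5_bases = i5_bases, i5_quals = qstr(i5_q, nchar(i5_bases)),
    i7_bases = i7_bases, i7_quals = qstr(i7_q, nchar(i7_bases)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("triplet_set", "data.frame")
  out
}

rbind_triplets <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("triplet_set", "data.frame")
  out
}

# Construct a triplet_assignment row directly (for taxonomy tests).
assignment_row <- function(i5, i7, ref_sample,
                           i5_status = if (is.na(i5)) "none" else "unique",
                           i7_status = if (is.na(i7)) "none" else "unique",
                           ref_status = if (is.na(ref_sample)) "none" else "unique",
                           mean_p = 0.001) {
  data.frame(id = "r", i5 = i5, i5_status = i5_status,
             i7 = i7, i7_status = i7_status,
             ref_sample = ref_sample, ref_status = ref_status,
             ref_distance = 0L,
             seq_mean_p = mean_p, i5_mean_p = mean_p, i7_mean_p = mean_p,
             stringsAsFactors = FALSE)
}

as_assignment <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("triplet_assignment", "data.frame")
  out
}

# Independent position-wise hamming oracle (R, no package code).
hamming_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv | av == "N" | bv == "N")
}

# Independent enumeration oracle for the substitution misassignment model:
# sums emission probabilities over all 4^L corrupted reads. At d = 0 the
# conditioned and unconditioned definitions coincide (self-match).
enum_misassignment_rate <- function(p, L, k, A, B, condition_on_true_reject) {
  bases <- c("A", "C", "G", "T")
  Av <- strsplit(A, "")[[1]]
  Bv <- strsplit(B, "")[[1]]
  grid <- as.matrix(do.call(expand.grid,
                            c(rep(list(bases), L),
                              list(KEEP.OUT.ATTRS = FALSE,
                                   stringsAsFactors = FALSE))))
  emit <- apply(grid, 1, function(x) prod(ifelse(x == Av, 1 - p, p / 3)))
  hB <- apply(grid, 1, function(x) sum(x != Bv))
  hA <- apply(grid, 1, function(x) sum(x != Av))
  accept <- hB <= k
  if (condition_on_true_reject && !identical(A, B)) accept <- accept & hA > k
  sum(emit[accept])
}

# Random DNA string helpers for property tests.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Apply k random edits (sub/ins/del) to a DNA string.
mutate_dna <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(k)) {
    op <- sample(3L, 1)
    pos <- sample(length(v), 1)
    if (op == 1L) v[pos] <- sample(bases, 1)
    else if (op == 2L && length(v) > 2L) v <- v[-pos]
    else v <- append(v, sample(bases, 1), after = pos)
  }
  paste(v, collapse = "")
}
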