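test_that("hamming counts differing positions with the N rule", {
  expect_identical(hamming("ACGTAAGG", "ACGTAAGG"), 0L)
  # the two indices of a deliberately unused pair, against each other
  expect_identical(hamming("ACGTAAGG", "GGCCAATT"),
                   hamming_oracle("ACGTAAGG", "GGCCAATT"))
  expect_identical(hamming("ANGT", "AAGT"), 1L)
  expect_identical(hamming("NNNN", "NNNN"), 4L)  # N never matches, even N
  expect_error(hamming("ACGT", "ACG"), "equal length")

  # vectorized against the position-wise oracle
  set.seed(101)
  for (i in 1:50) {
    a <- random_dna(12); b <- random_dna(12)
    expect_identical(hamming(a, b), hamming_oracle(a, b))
  }
})

test_that("banded edit distance agrees with the unbanded DP oracle", {
  set.seed(202)
  for (i in 1:200) {
    a <- random_dna(sample(5:60, 1))
    b <- mutate_dna(a, sample(0:12, 1))
    d0 <- as.integer(drop(utils::adist(a, b)))
    expect_identical(edit_distance(a, b, band = 10),
                     if (d0 <= 10) d0 else 11L)
  }
  # distances beyond the band are capped at band + 1
  expect_identical(edit_distance(strrep("A", 20), strrep("C", 20), band = 4),
                   5L)
})

test_that("match_index implements bcl2fastq-style mismatch tolerance", {
  exp_set <- c("AAAAAAAA", "CCCCAAAA", "GGGGGGGG")
  m <- match_index(c("AAAAAAAA",   # exact
                     "AAAAAAAT",   # one substitution from a unique index
                     "AANAAAAA",   # N counts as one mismatch
                     "TTTTTTTT"),  # nothing within reach
                   exp_set)
  expect_identical(m$index, c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA", NA))
  expect_identical(m$status, c("unique", "unique", "unique", "none"))

  # within 1 of two expected indices -> ambiguous
  amb <- match_index("ACGG", c("ACGT", "ACGA"), max_mismatch = 1)
  expect_identical(amb$status, "ambiguous")
  expect_true(is.na(amb$index))

  # max_mismatch = 0 is exact lookup
  set.seed(7)
  obs <- c(exp_set, replicate(20, random_dna(8)))
  m0 <- match_index(obs, exp_set, max_mismatch = 0)
  expect_identical(m0$status == "unique", obs %in% exp_set)

  expect_error(match_index("ACG", exp_set), "length")
  expect_error(match_index("ACGTACGT", character(0)), "non-empty")
})

test_that("assign_sequence picks the unique nearest reference within 4 edits", {
  refs <- tiny_refs()
  r1 <- refs$sequence[1]
  expect_identical(assign_sequence(r1, refs),
                   data.frame(reference_id = "S1", distance = 0L,
                              status = "unique", stringsAsFactors = FALSE))

  # 5 substitutions (spread along the read) from the nearest reference -> none
  v <- strsplit(r1, "")[[1]]
  pos <- c(5L, 15L, 25L, 35L, 45L)
  v[pos] <- ifelse(v[pos] == "A", "C", "A")
  far <- paste(v, collapse = "")
  expect_identical(as.integer(drop(utils::adist(far, r1))), 5L)  # oracle
  expect_identical(assign_sequence(far, refs)$status, "none")
  # 4 substitutions is still within reach
  v[pos[1]] <- strsplit(r1, "")[[1]][pos[1]]
  expect_identical(assign_sequence(paste(v, collapse = ""), refs),
                   data.frame(reference_id = "S1", distance = 4L,
                              status = "unique", stringsAsFactors = FALSE))

  # equidistant tie -> ambiguous
  two <- reference_set(c("a", "b"), c("AAAAAAAAAAAAAAAAAAAA",
                                      "AAAAAAAAAAAAAATTTTTT"),
                       max_edit = 4L) |> suppressWarnings()
  tie <- assign_sequence("AAAAAAAAAAAAAAAAATTT", two)
  expect_identical(tie$status, "ambiguous")
  expect_true(is.na(tie$reference_id))

  expect_error(assign_sequence("", refs), "empty")
})

test_that("demultiplex fills the three matches independently", {
  sheet <- tiny_sheet(); refs <- tiny_refs()
  consistent <- make_triplet("t1", refs$sequence[1], sheet$i5[1], sheet$i7[1])
  foreign_i5 <- make_triplet("t2", refs$sequence[1], sheet$i5[2], sheet$i7[1])
  junk_seq <- make_triplet("t3", strrep("T", 51), sheet$i5[1], sheet$i7[1])
  asg <- demultiplex(rbind_triplets(consistent, foreign_i5, junk_seq),
                     sheet, refs)
  expect_identical(asg$i5, c(sheet$i5[1], sheet$i5[2], sheet$i5[1]))
  expect_identical(asg$i7, rep(sheet$i7[1], 3))
  expect_identical(asg$ref_sample, c("S1", "S1", NA))
  expect_identical(asg$ref_status, c("unique", "unique", "none"))
  # segment mean error probabilities recorded for every read
  expect_equal(asg$seq_mean_p, rep(10^-3.5, 3))

  # deterministic: same triplets, same output
  expect_identical(asg, demultiplex(rbind_triplets(consistent, foreign_i5,
                                                   junk_seq), sheet, refs))
})

test_that("a perfectly read index is never ambiguous on a valid sheet", {
  # sheet min index distance 3 > 2 * max_mismatch with max_mismatch = 1
  cfg <- sim_config(n_samples = 8, reads_per_sample = 1, seed = 31)
  sheet <- generate_design(cfg)$sheet
  m <- match_index(sheet$i5, sheet$i5, max_mismatch = 1)
  expect_true(all(m$status == "unique"))
  expect_identical(m$index, sheet$i5)
})

test_that("validate_samplesheet emits hamming matrices and collision warnings", {
  close_sheet <- sample_sheet(data.frame(
    sample_id = c("a", "b"), i5 = c("AAAAAAAA", "AATTAAAA"),  # distance 2
    i7 = c("CCCCCCCC", "GGGGGGGG"), stringsAsFactors = FALSE))
  v <- validate_samplesheet(close_sheet, max_mismatch = 1)
  expect_length(v$warnings, 1L)
  expect_match(v$warnings, "i5 .* distance 2")
  expect_identical(v$i5_hamming["AAAAAAAA", "AATTAAAA"], 2L)
  expect_identical(v$i5_hamming, t(v$i5_hamming))

  ok <- validate_samplesheet(tiny_sheet(), max_mismatch = 1)
  expect_length(ok$warnings, 0L)
  expect_identical(dim(ok$i5_hamming), c(3L, 3L))

  dup <- data.frame(sample_id = c("a", "b"), i5 = "AAAA", i7 = "CCCC")
  expect_error(sample_sheet(dup), "duplicate \\(i5, i7\\) pair")
})
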