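test_that("the taxonomy labels each disagreement pattern correctly", {
  sheet <- tiny_sheet()
  s <- function(k) sheet[k, ]
  asg <- as_assignment(
    assignment_row(s(1)$i5, s(1)$i7, "S1"),            # all consistent
    assignment_row(s(1)$i5, s(1)$i7, "S2"),            # pair ok, foreign seq
    assignment_row(s(2)$i5, s(1)$i7, "S1"),            # single wrong i5
    assignment_row(s(1)$i5, s(3)$i7, "S1"),            # single wrong i7
    assignment_row(s(2)$i5, s(3)$i7, "S1"),            # two wrong steps
    assignment_row(NA, s(1)$i7, "S1"),                 # i5 unmatched
    assignment_row(s(1)$i5, s(1)$i7, "S1",
                   i7_status = "ambiguous")            # ambiguous i7
  )
  cl <- classify_triplets(asg, sheet)
  expect_identical(as.character(cl$label),
                   c("CORRECT", "SEQ_MIS", "INDEX_MIS_I5", "INDEX_MIS_I7",
                     "MULTI_MIS", "UNASSIGNED", "UNASSIGNED"))

  # a full foreign pair with a foreign sequence reads as SEQ_MIS from the
  # pair's perspective (the pair is on the sheet, the sequence is not its own)
  swapped <- classify_triplets(
    as_assignment(assignment_row(s(2)$i5, s(2)$i7, "S1")), sheet)
  expect_identical(as.character(swapped$label), "SEQ_MIS")

  # indices absent from the sheet are a contract violation
  expect_error(
    classify_triplets(as_assignment(assignment_row("TGCATGCA", s(1)$i7, "S1")),
                      sheet),
    "absent from the sheet")
})

test_that("classification is exhaustive and conserves the triplet count", {
  sheet <- tiny_sheet()
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    rows <- lapply(seq_len(n), function(i) {
      st <- sample(c("unique", "none", "ambiguous"), 3, replace = TRUE,
                   prob = c(0.8, 0.1, 0.1))
      assignment_row(
        if (st[1] == "unique") sample(sheet$i5, 1) else NA_character_,
        if (st[2] == "unique") sample(sheet$i7, 1) else NA_character_,
        if (st[3] == "unique") sample(sheet$sample_id, 1) else NA_character_,
        i5_status = st[1], i7_status = st[2], ref_status = st[3])
    })
    cl <- classify_triplets(do.call(as_assignment, rows), sheet)
    expect_false(anyNA(cl$label))
    expect_identical(sum(table(cl$label)), n)
  }
})

test_that("compute_rates uses the taxonomy's denominators", {
  r <- compute_rates(c(CORRECT = 9990, SEQ_MIS = 10))
  expect_equal(r$seq_mis_rate, 0.001)
  expect_identical(r$undefined, character(0))

  clean <- compute_rates(c(CORRECT = 500))
  expect_identical(clean$seq_mis_rate, 0)
  expect_identical(clean$index_mis_rate, 0)
  expect_identical(clean$overall_incorrect_rate, 0)

  # zero denominators are flagged, not reported as 0
  empty <- compute_rates(c(CORRECT = 0))
  expect_true(all(is.na(c(empty$seq_mis_rate, empty$index_mis_rate,
                          empty$overall_incorrect_rate))))
  expect_setequal(empty$undefined, c("seq_mis_rate", "index_mis_rate",
                                     "overall_incorrect_rate"))

  mixed <- compute_rates(c(CORRECT = 960, SEQ_MIS = 10, INDEX_MIS_I5 = 12,
                           INDEX_MIS_I7 = 8, MULTI_MIS = 2, UNASSIGNED = 100))
  expect_equal(mixed$seq_mis_rate, 10 / 970)
  expect_equal(mixed$index_mis_rate, 20 / 992)
  expect_equal(mixed$overall_incorrect_rate, 32 / 992)

  expect_error(compute_rates(c(BOGUS = 1)), "unknown classification label")
})

test_that("crosstalk_report aggregates counts, rates and controls", {
  sheet <- tiny_sheet(); refs <- tiny_refs()
  tr <- rbind_triplets(
    make_triplet("a", refs$sequence[1], sheet$i5[1], sheet$i7[1]),
    make_triplet("b", refs$sequence[1], sheet$i5[1], sheet$i7[1]),
    make_triplet("c", refs$sequence[2], sheet$i5[1], sheet$i7[1]),   # seq mis
    make_triplet("d", refs$sequence[1], sheet$i5[3], sheet$i7[1]))   # i5 mis
  cl <- classify_triplets(demultiplex(tr, sheet, refs), sheet)
  rep <- crosstalk_report(cl, sheet)
  expect_identical(sum(rep$counts), 4)
  expect_equal(rep$rates$seq_mis_rate, 1 / 3)
  expect_equal(rep$rates$index_mis_rate, 1 / 4)
  # the i5-misassigned read landed on control pair (i5_3, i7_1)
  expect_identical(rep$control$total, 1)
  hit <- rep$control$per_pair
  expect_identical(hit$epsilon[hit$i5 == sheet$i5[3] &
                                 hit$i7 == sheet$i7[1]], 1)
  # per-sample rates anchor on the sequence read's sample
  s1 <- rep$per_sample[rep$per_sample$sample_id == "S1", ]
  expect_identical(s1$n_mapped, 3L)

  # serialization round trip of the machine-readable summary
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_crosstalk_report(rep, tsv, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$rates$seq_mis_rate, 1 / 3)
  expect_identical(parsed$n_total, 4L)
  expect_identical(nrow(read.delim(tsv)), nrow(rep$triplet_counts))
})
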