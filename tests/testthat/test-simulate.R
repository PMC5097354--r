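test_that("generate_design meets the separation invariants deterministically", {
  cfg <- sim_config(n_samples = 14, reads_per_sample = 1, seed = 9)
  d <- generate_design(cfg)
  pairwise_min <- function(x, f) {
    cmb <- utils::combn(length(x), 2)
    min(f(x[cmb[1, ]], x[cmb[2, ]]))
  }
  expect_gte(pairwise_min(d$sheet$i5, hamming), 3)
  expect_gte(pairwise_min(d$sheet$i7, hamming), 3)
  expect_gte(pairwise_min(d$refs$sequence, function(a, b)
    edit_distance(a, b)), 14)
  expect_gte(attr(d$refs, "min_pairwise_edit"), 14)
  expect_identical(nchar(d$sheet$i5), rep(8L, 14))
  expect_identical(nchar(d$refs$sequence), rep(51L, 14))

  # same seed, same design
  expect_identical(d, generate_design(cfg))
  # different seed, different design
  expect_false(identical(
    d$sheet$i5, generate_design(sim_config(n_samples = 14,
                                           reads_per_sample = 1,
                                           seed = 10))$sheet$i5))

  # pigeonhole: hundreds of samples cannot be separated on 4-bp indices
  expect_error(
    generate_design(sim_config(n_samples = 300, index_length = 4,
                               reads_per_sample = 1, seed = 1)),
    "could not generate")
})

test_that("simulation is deterministic and byte-identical given a seed", {
  cfg <- sim_config(n_samples = 3, reads_per_sample = 300, seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_run(cfg, dir = d1)
  r2 <- simulate_run(cfg, dir = d2)
  expect_identical(r1$triplets, r2$triplets)
  expect_identical(r1$truth, r2$truth)
  for (f in c("r1.fastq", "i7.fastq", "i5.fastq")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
  # the files round-trip into the in-memory triplets
  back <- read_triplets(file.path(d1, "r1.fastq"), file.path(d1, "i7.fastq"),
                        file.path(d1, "i5.fastq"))
  expect_equal(as.data.frame(back), as.data.frame(r1$triplets))
})

test_that("a clean run classifies 100% CORRECT with zero epsilon", {
  cfg <- sim_config(n_samples = 3, reads_per_sample = 400,
                    p_index_mis_i5 = 0, p_index_mis_i7 = 0, p_seq_mis = 0,
                    q_high_mean = 41, seed = 13)
  run <- simulate_run(cfg)
  rep <- crosstalk_report(
    classify_triplets(demultiplex(run$triplets, run$sheet, run$refs),
                      run$sheet), run$sheet)
  expect_identical(rep$counts[["CORRECT"]], 1200)
  expect_identical(rep$rates$overall_incorrect_rate, 0)
  expect_identical(rep$control$total, 0)
  expect_true(all(run$truth$label == "CORRECT"))
})

test_that("injected event counts follow the configured binomial rates", {
  n <- 20000L
  cfg <- sim_config(n_samples = 4, reads_per_sample = n %/% 4L,
                    p_index_mis_i5 = 0.002, p_index_mis_i7 = 0,
                    p_seq_mis = 0, seed = 101)
  run <- simulate_run(cfg)
  k <- sum(run$truth$label == "INDEX_MIS_I5")
  expected <- n * 0.002
  expect_lt(abs(k - expected), 3 * sqrt(expected * (1 - 0.002)))
  # misassigned reads take their foreign segment from a different sample
  mis <- run$truth[run$truth$label != "CORRECT", ]
  expect_true(all(mis$foreign_sample != mis$origin_sample))
})

test_that("epsilon equals the injected index swaps when substitution is off", {
  cfg <- sim_config(n_samples = 5, reads_per_sample = 1000,
                    p_index_mis_i5 = 0.01, p_index_mis_i7 = 0.01,
                    p_seq_mis = 0.005, substitute = FALSE, seed = 19)
  run <- simulate_run(cfg)
  cl <- classify_triplets(demultiplex(run$triplets, run$sheet, run$refs),
                          run$sheet)
  rep <- crosstalk_report(cl, run$sheet)
  truth_tab <- table(run$truth$label)
  # with verbatim bases, classification reproduces the ground truth exactly
  for (lab in names(truth_tab)) {
    expect_identical(rep$counts[[lab]], as.numeric(truth_tab[[lab]]))
  }
  # every index swap lands on a control pair in a unique dual design
  n_swaps <- sum(run$truth$label %in% c("INDEX_MIS_I5", "INDEX_MIS_I7"))
  expect_identical(rep$control$total, as.numeric(n_swaps))
})

test_that("misassigned read steps carry low quality scores", {
  cfg <- sim_config(n_samples = 4, reads_per_sample = 2500,
                    p_index_mis_i5 = 0.02, p_seq_mis = 0.02, seed = 23)
  run <- simulate_run(cfg)
  asg <- demultiplex(run$triplets, run$sheet, run$refs)
  avg_q <- function(p) -10 * log10(p)
  i5mis <- run$truth$label == "INDEX_MIS_I5"
  seqmis <- run$truth$label == "SEQ_MIS"
  correct <- run$truth$label == "CORRECT"
  # the misassigned step is low quality; untouched steps stay high
  expect_lt(mean(avg_q(asg$i5_mean_p[i5mis])), 22)
  expect_gt(mean(avg_q(asg$seq_mean_p[i5mis])), 28)
  expect_gt(mean(avg_q(asg$i5_mean_p[correct])), 28)
  # sequence misassignments are low quality in all three steps
  expect_lt(mean(avg_q(asg$seq_mean_p[seqmis])), 22)
  expect_lt(mean(avg_q(asg$i5_mean_p[seqmis])), 22)
  expect_lt(mean(avg_q(asg$i7_mean_p[seqmis])), 22)
})

test_that("sim_config validates its probabilities and dimensions", {
  expect_error(sim_config(p_seq_mis = 1.2), "probabilities")
  expect_error(sim_config(p_index_mis_i5 = 0.6, p_index_mis_i7 = 0.6),
               "sum below 1")
  expect_error(sim_config(read_length = 10), "read_length")
})
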