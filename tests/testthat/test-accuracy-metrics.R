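test_that("error decomposition partitions alignment columns exactly", {
  perfect <- decompose_errors(strrep("=", 100))
  expect_equal(perfect$total_pct, 0)
  expect_equal(perfect$identity_pct, 100)

  # hand count: 90 match, 3 mismatch, 4 insert, 5 delete; N = 102
  script <- paste0(strrep("=", 90), strrep("X", 3), strrep("I", 4),
                   strrep("D", 5))
  p <- decompose_errors(script)
  expect_equal(round(p$miscall_pct, 2), 2.94)
  expect_equal(round(p$ins_pct, 2), 3.92)
  expect_equal(round(p$del_pct, 2), 4.90)
  expect_equal(round(p$total_pct, 2), 11.76)
  expect_equal(p$total_pct, p$miscall_pct + p$ins_pct + p$del_pct)
  expect_equal(p$identity_pct + p$miscall_pct + p$ins_pct + p$del_pct, 100)

  all_x <- decompose_errors(strrep("X", 10))
  expect_equal(all_x$miscall_pct, 100)
  expect_equal(all_x$total_pct, 100)

  # read-length denominator divides by matches+mismatches+insertions
  p2 <- decompose_errors(script, denominator = "readlen")
  expect_equal(p2$del_pct, 100 * 5 / 97)

  expect_error(decompose_errors(""), "empty")
})

test_that("error partition identities hold on simulated alignments", {
  env <- shared_default_run()
  prof <- error_profiles(env$run$truth, env$run$calls, env$run$reads)
  expect_equal(prof$total_pct,
               prof$miscall_pct + prof$ins_pct + prof$del_pct)
  expect_equal(prof$identity_pct + prof$total_pct, rep(100, nrow(prof)))
  expect_true(all(prof$longest_perfect_run <=
                    prof$identity_pct / 100 * prof$n_columns + 1e-9))
})

test_that("longest perfect run finds the maximal match stretch", {
  expect_equal(longest_perfect_run(strrep("=", 50)), 50)
  script <- paste0(strrep("=", 30), "X", strrep("=", 90))
  expect_equal(longest_perfect_run(script), 90)
  expect_equal(longest_perfect_run(strrep("X", 5)), 0)
  expect_equal(longest_perfect_run(paste0("=I=D", strrep("=", 3))), 3)
})

test_that("mean quality is the arithmetic mean and permutation-invariant", {
  expect_equal(mean_quality(phred_to_string(rep(10, 8))), 10)
  expect_equal(mean_quality(phred_to_string(c(8, 12))), 10)
  q <- c(3, 30, 17, 9)
  expect_equal(mean_quality(phred_to_string(q)),
               mean_quality(phred_to_string(rev(q))))
  expect_error(mean_quality(""), "empty")
})

test_that("pass/fail uses the mean-Q-over-9 rule with no-2D failing", {
  expect_equal(classify_pass_fail(phred_to_string(rep(9, 10))), "fail")
  expect_equal(classify_pass_fail(phred_to_string(c(9, 9))), "fail")
  expect_equal(classify_pass_fail(phred_to_string(rep(12, 10))), "pass")
  expect_equal(classify_pass_fail(NA_character_), "fail")
  expect_equal(classify_pass_fail(""), "fail")
  # just above the boundary
  expect_equal(classify_pass_fail(phred_to_string(c(9, 10))), "pass")
})

test_that("the quality-error statistic follows its closed form", {
  expect_equal(quality_error_stat(0, 1), 1.0)
  expect_equal(quality_error_stat(1000, 1), 0.1)
  expect_equal(quality_error_stat(10, 2), quality_error_stat(10, 1) / 2)
  # standard Phred switch
  expect_equal(quality_error_stat(10, 1, phred = "standard"), 0.1)
  expect_error(quality_error_stat(10, 0), "positive")
})

test_that("mean quality anticorrelates with log total error", {
  env <- shared_default_run()
  prof <- error_profiles(env$run$truth, env$run$calls, env$run$reads)
  p2 <- prof[prof$read_type == "2D" & prof$total_pct > 0, ]
  expect_gt(nrow(p2), 30)
  expect_lt(cor(log(p2$total_pct), p2$mean_q), -0.2)
})

test_that("banded alignment handles identity and single substitutions", {
  s <- strrep("ACGT", 5)
  a <- anchored_align(s, s)
  expect_equal(a$script, strrep("=", 20))
  expect_equal(attr(a, "score"), 20)

  s2 <- paste0(substr(s, 1, 9), "T", substr(s, 11, 20))  # A -> T at pos 10
  a2 <- anchored_align(s2, s)
  ops <- script_ops(a2$script)
  expect_equal(sum(ops == "X"), 1)
  expect_equal(sum(ops == "="), 19)
})

test_that("banded alignment matches the exhaustive oracle on small pairs", {
  withr::local_seed(7)
  for (i in 1:60) {
    n1 <- sample(1:15, 1)
    n2 <- sample(1:15, 1)
    read <- random_dna(n1)
    ref <- random_dna(n2)
    a <- anchored_align(read, ref, band = 30)
    expect_equal(attr(a, "score"), full_gotoh_score(read, ref),
                 info = paste(read, ref))
    # the script is a valid global alignment of the pair
    ops <- script_ops(a$script)
    expect_equal(sum(ops %in% c("=", "X", "I")), n1)
    expect_equal(sum(ops %in% c("=", "X", "D")), n2)
  }
})

test_that("banded alignment recovers simulated corruptions", {
  cfg <- sim_config()
  ref <- generate_reference(800, 0.5, seed = 5)
  cr <- corrupt_sequence(ref, cfg, time = 0, seed = 6)
  a <- anchored_align(cr$read, ref, band = 60)
  p <- decompose_errors(a$script)
  truth <- decompose_errors(cr$script)
  # an optimal aligner can only tidy up the alignment, not worsen it
  expect_lte(p$total_pct, truth$total_pct + 1)
  expect_lt(abs(p$total_pct - truth$total_pct), 3)
})

test_that("aggregate_errors groups medians and conserves counts", {
  prof <- data.frame(
    uuid = letters[1:6], read_type = c("2D", "2D", "2D", "template",
                                       "template", "2D"),
    miscall_pct = c(1, 2, 3, 4, 5, 6), ins_pct = 0, del_pct = 0,
    total_pct = c(1, 2, 3, 4, 5, 6), identity_pct = 99,
    longest_perfect_run = 5, n_columns = 100,
    read_class = c("pass", "pass", "fail", "pass", "pass", "fail"))
  agg <- aggregate_errors(prof, by = c("read_type", "read_class"))
  expect_equal(sum(agg$n), nrow(prof))
  one <- agg[agg$read_type == "2D" & agg$read_class == "fail", ]
  expect_equal(one$total_pct_med, median(c(3, 6)))
  single <- aggregate_errors(prof[1, , drop = FALSE],
                             by = c("read_type", "read_class"))
  expect_equal(single$miscall_pct_med, 1)
  expect_equal(single$miscall_pct_iqr, 0)
  expect_error(aggregate_errors(prof, by = "lab"), "lab")
})
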