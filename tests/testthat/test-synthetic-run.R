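test_that("generate_reference honours length, composition and seed", {
  s <- generate_reference(12, 0.5, seed = 1)
  expect_equal(nchar(s), 12)
  expect_true(grepl("^[ACGT]+$", s))
  expect_identical(s, generate_reference(12, 0.5, seed = 1))

  gc_only <- generate_reference(1000, 1.0, seed = 1)
  expect_true(grepl("^[GC]+$", gc_only))
  at_only <- generate_reference(1000, 0.0, seed = 1)
  expect_true(grepl("^[AT]+$", at_only))

  # binomial concentration: observed GC within 0.508 +/- 0.005 at n = 1e5
  big <- generate_reference(100000, 0.508, seed = 7)
  expect_lt(abs(gc_content(big) / 100 - 0.508), 0.005)

  expect_error(generate_reference(0, 0.5), "positive")
  expect_error(generate_reference(10, 1.5), "gc")
})

test_that("flow-cell initialisation fills well-groups by quality rank", {
  fc1 <- init_flowcell(sim_config(well_active_prob = 1), seed = 1)
  expect_equal(unname(flowcell_group_counts(fc1)), rep(512L, 4))
  fc0 <- init_flowcell(sim_config(well_active_prob = 0), seed = 1)
  expect_equal(unname(flowcell_group_counts(fc0)), rep(0L, 4))

  # default activation: counts within 3 sd of the closed-form binomial
  # expectation for P(>= k active of 4) per channel
  fc <- init_flowcell(sim_config(), seed = 42)
  counts <- flowcell_group_counts(fc)
  p_ge_k <- pbinom(0:3, 4, 0.60, lower.tail = FALSE)
  expect_equal(unname(round(expected_group_counts(0.60))),
               c(499, 420, 243, 66))
  for (k in 1:4) {
    sd_k <- sqrt(512 * p_ge_k[k] * (1 - p_ge_k[k]))
    expect_lt(abs(counts[k] - 512 * p_ge_k[k]), 3 * sd_k)
  }
  # group counts are non-increasing and group assignment is injective
  expect_true(all(diff(unname(counts)) <= 0))
  assigned <- fc[!is.na(fc$group), ]
  expect_false(any(duplicated(assigned[, c("channel", "group")])))
  expect_false(any(duplicated(assigned[, c("channel", "well")])))
})

test_that("mux assignment ranks the best well into g1", {
  fc <- init_flowcell(sim_config(), seed = 7)
  by_ch <- split(fc[!is.na(fc$group), ], fc$channel[!is.na(fc$group)])
  for (ch in by_ch[1:20]) {
    o <- order(ch$group)
    expect_true(all(diff(ch$quality[o]) <= 0))
  }
})

test_that("corrupt_sequence implements the column-wise error model", {
  cfg0 <- zero_error_config()
  z <- corrupt_sequence("ACGTACGT", cfg0, time = 0, seed = 1)
  expect_identical(z$read, "ACGTACGT")
  expect_identical(z$script, strrep("=", 8))

  all_del <- sim_config(miscall_rate = 0, ins_rate = 0, del_rate = 1,
                        homopolymer_del_multiplier = 1)
  d <- corrupt_sequence("ACGTAC", all_del, time = 0, seed = 1)
  expect_identical(d$read, "")
  expect_identical(d$script, strrep("D", 6))

  # realized per-column frequencies within 3 sigma of configured rates
  cfg <- sim_config(homopolymer_del_multiplier = 1)
  seq <- generate_reference(100000, 0.5, seed = 11)
  cr <- corrupt_sequence(seq, cfg, time = 0, seed = 12)
  ops <- script_ops(cr$script)
  N <- length(ops)
  for (case in list(c("X", 0.03), c("I", 0.04), c("D", 0.05))) {
    p <- as.numeric(case[2])
    obs <- sum(ops == case[1]) / N
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / N))
  }
  expect_error(corrupt_sequence("", cfg), "non-empty")
})

test_that("edit scripts replay to the emitted read byte-for-byte", {
  cfg <- sim_config()
  for (seed in 1:5) {
    ref <- generate_reference(3000, 0.5, seed = seed)
    cr <- corrupt_sequence(ref, cfg, time = seed * 3, seed = seed + 100)
    expect_identical(replay_script(ref, 0, cr$script), cr$read)
    expect_equal(nchar(cr$qual), nchar(cr$read))
    expect_equal(script_ref_span(cr$script), 3000)
  }
})

test_that("homopolymer deletions are amplified", {
  cfg <- sim_config(homopolymer_del_multiplier = 5,
                    miscall_rate = 0, ins_rate = 0, del_rate = 0.05)
  seq <- paste(rep(c("ACGT", strrep("A", 10)), 2000), collapse = "")
  cr <- corrupt_sequence(seq, cfg, time = 0, seed = 3)
  ch <- strsplit(cr$script, "", fixed = TRUE)[[1]]
  refv <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(refv)
  in_hp <- rep(r$lengths >= 3, r$lengths)
  del_rate_hp <- mean(ch[in_hp] == "D")
  del_rate_out <- mean(ch[!in_hp] == "D")
  expect_gt(del_rate_hp, 3 * del_rate_out)
})

test_that("simulated runs have the expected structure and invariants", {
  env <- shared_default_run()
  run <- env$run
  refs <- env$refs
  expect_gt(nrow(run$reads), 50)
  expect_false(any(duplicated(run$reads$uuid)))
  expect_false(any(duplicated(
    run$reads[, c("experiment", "batch", "channel", "file_number")])))
  expect_true(all(grepl("^[0-9a-f]{32}$", run$reads$uuid)))

  # no base-called read outside the callable range
  called <- run$reads$uuid %in% run$calls$uuid
  expect_true(all(run$reads$n_events[called] >= 200))
  expect_true(all(run$reads$n_events[called] <= 230000))
  expect_true(all(run$reads$callable[called]))

  # pass implies a 2D call exists with mean quality > 9
  two_d <- run$calls[run$calls$read_type == "2D", ]
  pass <- run$reads[run$reads$read_class == "pass", ]
  expect_true(all(pass$uuid %in% two_d$uuid))
  mq <- vapply(two_d$quality[match(pass$uuid, two_d$uuid)],
               mean_quality, numeric(1), USE.NAMES = FALSE)
  expect_true(all(mq > 9))

  # ground truth replays exactly for every read and type
  ref_of <- function(nm) if (nm == refs$target_name) refs$target_seq
                         else refs$control_seq
  key <- paste(run$calls$uuid, run$calls$read_type)
  for (i in seq_len(nrow(run$truth))) {
    tr <- run$truth[i, ]
    called <- run$calls$sequence[match(paste(tr$uuid, tr$read_type), key)]
    src <- ref_of(tr$ref_name)
    window <- if (tr$strand == "-")
      revcomp(substr(src, tr$start0 + 1, tr$end0)) else src
    start <- if (tr$strand == "-") 0 else tr$start0
    expect_identical(replay_script(window, start, tr$script), called)
  }
})

test_that("zero-error runs give perfect reads everywhere", {
  refs <- reference_set(target_length = 20000, seed = 21)
  run <- simulate_run(zero_error_config(), refs, seed = 22)
  prof <- error_profiles(run$truth)
  expect_true(all(prof$total_pct == 0))
  expect_true(all(prof$identity_pct == 100))
})

test_that("control_fraction = 0 yields no control reads", {
  refs <- reference_set(target_length = 20000, seed = 31)
  run <- simulate_run(sim_config(control_fraction = 0), refs, seed = 32)
  expect_true(all(run$reads$source_ref == refs$target_name))
  cls <- classify_reads(run$truth, refs$target_name, refs$control_name)
  expect_equal(unname(attr(cls, "counts")["control"]), 0L)
})

test_that("about two thirds of events fall in the first day", {
  cfg <- sim_config()
  refs <- reference_set(seed = 41)
  fr <- vapply(1:5, function(s) {
    run <- simulate_run(cfg, refs, seed = 400 + s)
    sb <- bin_reads(run$reads)
    sum(sb$events[sb$t_end <= 24 * 3600]) / sum(sb$events)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.67), 0.08)
})

test_that("active g1 pore count is monotone non-increasing before the switch", {
  env <- shared_default_run()
  run <- env$run
  g1 <- run$reads[run$reads$well_group == "g1", ]
  ap <- active_pores(g1, 900, n_bins = 96)
  expect_true(all(diff(ap) <= 0))
})

test_that("2D quality declines linearly outside dip windows", {
  cfg <- sim_config(q_dip_depth = 0, q_read_sd = 0, error_sdlog = 0,
                    initial_event_rate = 900)
  refs <- reference_set(target_length = 20000, seed = 51)
  run <- simulate_run(cfg, refs, seed = 52)
  two_d <- run$calls[run$calls$read_type == "2D", ]
  m <- match(two_d$uuid, run$reads$uuid)
  t_h <- run$reads$start_time[m] / 3600
  mq <- vapply(two_d$quality, mean_quality, numeric(1), USE.NAMES = FALSE)
  fit <- lm(mq ~ t_h)
  slope_per_24h <- 24 * coef(fit)[["t_h"]]
  ci <- 24 * confint(fit)["t_h", ]
  expect_lt(abs(slope_per_24h + cfg$q_decline_per_24h), 0.5)
  expect_true(ci[1] < -cfg$q_decline_per_24h + 0.5 &&
              ci[2] > -cfg$q_decline_per_24h - 0.5)
})

test_that("a dead flow cell produces an empty run with a warning", {
  refs <- reference_set(target_length = 5000, seed = 61)
  expect_warning(
    run <- simulate_run(sim_config(well_active_prob = 0), refs, seed = 62),
    "no active pores")
  expect_equal(nrow(run$reads), 0)
  expect_true(any(grepl("no active pores", run$warnings)))
})
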