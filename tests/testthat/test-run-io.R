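test_that("FASTQ round trip is the identity on simulator output", {
  env <- shared_default_run()
  run <- env$run
  path <- withr::local_tempfile(fileext = ".fastq")
  write_run_fastq(run, path)
  back <- read_run_fastq(path)

  expect_equal(nrow(back$calls), nrow(run$calls))
  m <- match(paste(run$calls$uuid, run$calls$read_type),
             paste(back$calls$uuid, back$calls$read_type))
  expect_false(anyNA(m))
  expect_identical(back$calls$sequence[m], run$calls$sequence)
  expect_identical(back$calls$quality[m], run$calls$quality)

  called <- run$reads[run$reads$uuid %in% run$calls$uuid, ]
  mm <- match(called$uuid, back$reads$uuid)
  expect_false(anyNA(mm))
  for (col in c("experiment", "batch", "channel", "file_number",
                "start_time", "duration", "n_events", "well_group",
                "read_class"))
    expect_equal(back$reads[[col]][mm], called[[col]],
                 info = col, ignore_attr = TRUE)
  expect_false(any(duplicated(back$reads$uuid)))
})

test_that("FASTQ edge cases: empty file, single record, unknown keys", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), path)
  expect_equal(nrow(read_run_fastq(path)$calls), 0)

  rec <- list(
    reads = data.frame(experiment = "e", batch = 0L, channel = 3L,
                       well = 1L, file_number = 7L,
                       uuid = strrep("ab", 16), start_time = 12.5,
                       duration = 3.25, n_events = 500L,
                       well_group = "g1", read_class = "pass",
                       stringsAsFactors = FALSE),
    calls = data.frame(uuid = strrep("ab", 16), read_type = "2D",
                       sequence = "ACGT", quality = "IIII",
                       stringsAsFactors = FALSE))
  write_run_fastq(rec, path)
  back <- read_run_fastq(path)
  expect_identical(back$calls$sequence, "ACGT")
  expect_equal(back$reads$channel, 3L)
  expect_equal(back$reads$start_time, 12.5)

  # unknown comment keys are preserved through a round trip
  lines <- readLines(path)
  lines[1] <- paste(lines[1], "custom=hello")
  writeLines(lines, path)
  back2 <- read_run_fastq(path)
  expect_match(attr(back2$calls, "extra_comments")[1], "custom=hello")
  path2 <- withr::local_tempfile(fileext = ".fastq")
  write_run_fastq(back2, path2)
  expect_match(readLines(path2)[1], "custom=hello")
})

test_that("malformed quality length is reported with the record name", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@deadbeef_2D run=e", "ACGT", "+", "III"), path)
  expect_error(read_run_fastq(path), "deadbeef")
})

test_that("SAM =/X records expand to the expected columns", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:ref\tLN:100",
               paste("r1_2D", 0, "ref", 1, 60, "10=", "*", 0, 0,
                     "ACGTACGTAC", "*", sep = "\t")), path)
  aln <- read_alignments(path)
  expect_equal(nrow(aln), 1)
  ops <- script_ops(aln$script[1])
  expect_equal(sum(ops == "="), 10)
  expect_equal(aln$start0, 0)
  expect_equal(aln$end0, 10)

  # hand expansion of 3=1X2=1I3=1D2=
  writeLines(c("@SQ\tSN:ref\tLN:100",
               paste("r2_2D", 16, "ref", 5, 60, "3=1X2=1I3=1D2=", "*",
                     0, 0, "*", "*", sep = "\t")), path)
  aln2 <- read_alignments(path)
  ops2 <- script_ops(aln2$script[1])
  expect_equal(sum(ops2 == "="), 10)
  expect_equal(sum(ops2 == "X"), 1)
  expect_equal(sum(ops2 == "I"), 1)
  expect_equal(sum(ops2 == "D"), 1)
  expect_equal(aln2$strand, "-")
  expect_equal(aln2$start0, 4)
  expect_equal(aln2$end0, 4 + 12)   # 10 match + 1 mismatch + 1 deletion
})

test_that("M CIGARs need an MD tag and resolve through it", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:ref\tLN:100",
               paste("r3_2D", 0, "ref", 1, 60, "6M", "*", 0, 0,
                     "ACGTAC", "*", sep = "\t")), path)
  expect_error(read_alignments(path), "MD")

  writeLines(c("@SQ\tSN:ref\tLN:100",
               paste("r3_2D", 0, "ref", 1, 60, "6M", "*", 0, 0,
                     "ACGTAC", "*", "MD:Z:2A3", sep = "\t")), path)
  aln <- read_alignments(path)
  ops <- script_ops(aln$script[1])
  expect_equal(ops, c("=", "=", "X", "=", "=", "="))
})

test_that("SAM write -> read round trip preserves CIGAR and metadata", {
  env <- shared_default_run()
  run <- env$run
  refs <- env$refs
  path <- withr::local_tempfile(fileext = ".sam")
  ref_lengths <- stats::setNames(
    c(nchar(refs$target_seq), nchar(refs$control_seq)),
    c(refs$target_name, refs$control_name))
  write_alignments(run$truth, ref_lengths, path,
                   calls = run$calls, reads = run$reads)
  back <- read_alignments(path)
  expect_equal(nrow(back), nrow(run$truth))
  expect_equal(attr(back, "ref_lengths"), ref_lengths)

  key <- paste(run$truth$uuid, run$truth$read_type)
  m <- match(key, paste(back$uuid, back$read_type))
  expect_false(anyNA(m))
  expect_equal(back$start0[m], run$truth$start0)
  expect_equal(back$end0[m], run$truth$end0)
  expect_identical(back$strand[m], run$truth$strand)
  expect_identical(back$source_ref[m], run$truth$ref_name)
  # CIGAR round trip: the op classes survive exactly
  orig_cigar <- vapply(run$truth$script, ops_to_cigar, character(1),
                       USE.NAMES = FALSE)
  back_cigar <- vapply(back$script[m], ops_to_cigar, character(1),
                       USE.NAMES = FALSE)
  expect_identical(back_cigar, orig_cigar)
  # SEQ present, so mismatch/insertion identities survive too
  expect_identical(unname(back$script[m]), run$truth$script)
})

test_that("coordinate conversion is self-inverse", {
  # 0-based start s becomes POS s+1 on write and s again on read
  path <- withr::local_tempfile(fileext = ".sam")
  aln <- data.frame(uuid = "x", read_type = "2D", ref_name = "ref",
                    start0 = 41L, end0 = 45L, strand = "+",
                    script = "====", stringsAsFactors = FALSE)
  write_alignments(aln, c(ref = 100L), path)
  line <- grep("^x", readLines(path), value = TRUE)
  expect_equal(as.integer(strsplit(line, "\t")[[1]][4]), 42L)
  expect_equal(read_alignments(path)$start0, 41L)
})

test_that("run log and config round-trip through TSV / JSON", {
  env <- shared_default_run()
  run <- env$run
  log_path <- withr::local_tempfile(fileext = ".tsv")
  write_run_log(run$reads, log_path)
  back <- read_run_log(log_path)
  expect_equal(nrow(back), nrow(run$reads))
  expect_identical(back$uuid, run$reads$uuid)
  expect_equal(back$n_events, run$reads$n_events)

  cfg <- sim_config(miscall_rate = 0.01, run_hours = 12)
  cfg_path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, cfg_path)
  cfg2 <- read_sim_config(cfg_path)
  expect_equal(unclass(cfg2), unclass(cfg))
})
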