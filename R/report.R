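#' Run the full simulate-and-characterise pipeline
#'
#' Simulates a run, writes every stage artifact (references FASTA,
#' reads FASTQ, ground-truth SAM, run-log TSV, config JSON), then runs
#' the characterisation stages - time-binned yield profile,
#' target/control classification, error decomposition, 5-mer
#' representation bias, GC content, consensus accuracy versus coverage -
#' and emits a single run report (JSON + TSV tables) with a manifest.
#' Deterministic given `seed`: the same seed yields byte-identical
#' artifacts.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param refs Optional [reference_set()]; generated from
#'   `seed` when omitted.
#' @param consensus_levels Fold-coverage levels for the consensus stage
#'   (capped at the available fold; stage skipped when fold < 1).
#' @return The report, invisibly: a nested list mirroring
#'   `report.json`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1,
                         out_dir = tempfile("porewise_run_"),
                         refs = NULL,
                         consensus_levels = c(5, 10, 20)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(refs)) refs <- reference_set(seed = seed)
  run <- simulate_run(config, refs, seed = seed)

  paths <- c(
    references = file.path(out_dir, "references.fasta"),
    reads = file.path(out_dir, "reads.fastq"),
    truth = file.path(out_dir, "truth.sam"),
    run_log = file.path(out_dir, "run_log.tsv"),
    config = file.path(out_dir, "config.json"),
    profile = file.path(out_dir, "yield_profile.tsv"),
    classes = file.path(out_dir, "read_classes.tsv"),
    errors = file.path(out_dir, "error_profiles.tsv"),
    kmers = file.path(out_dir, "kmer_table.tsv"),
    consensus = file.path(out_dir, "consensus_accuracy.tsv"),
    report = file.path(out_dir, "report.json"),
    manifest = file.path(out_dir, "manifest.json"))

  write_reference_fasta(refs, paths["references"])
  write_run_fastq(run, paths["reads"])
  ref_lengths <- stats::setNames(
    c(nchar(refs$target_seq), nchar(refs$control_seq)),
    c(refs$target_name, refs$control_name))
  write_alignments(run$truth, ref_lengths, paths["truth"],
                   calls = run$calls, reads = run$reads)
  write_run_log(run$reads, paths["run_log"])
  write_sim_config(config, paths["config"])

  report <- list(seed = seed,
                 config_hash = config_hash(config),
                 package_version = as.character(
                   utils::packageVersion("porewise")),
                 warnings = run$warnings)

  # ---- yield -----------------------------------------------------------
  cal <- filter_callable(run$reads, config$callable_range)
  series <- bin_reads(run$reads)
  series <- exclude_windows(series, config$run_hours,
                            config$group_switch_hour)
  utils::write.table(series, paths["profile"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report$yield <- list(
    n_reads = nrow(run$reads),
    total_events = sum(run$reads$n_events),
    callable_fraction =
      if (nrow(run$reads)) nrow(cal$kept) / nrow(run$reads) else NA,
    events_first_24h_fraction = first_half_fraction(series, 24 * 3600),
    median_read_len_events =
      if (nrow(run$reads)) stats::median(run$reads$n_events) else NA)

  # ---- per-type yields -------------------------------------------------
  if (nrow(run$calls)) {
    by_type <- split(run$calls, run$calls$read_type)
    pass_ids <- run$reads$uuid[run$reads$read_class == "pass"]
    types <- list()
    for (ty in names(by_type)) {
      cc <- by_type[[ty]]
      types[[ty]] <- call_summary(cc)
      if (ty == "2D")
        types[["2D_pass"]] <-
          call_summary(cc[cc$uuid %in% pass_ids, , drop = FALSE])
    }
    report$base_calls <- types
    report$pct_2d_pass <- 100 * mean(
      run$reads$uuid[run$reads$callable] %in% pass_ids)
  }

  # ---- classification --------------------------------------------------
  cls <- classify_reads(run$truth, refs$target_name, refs$control_name)
  utils::write.table(cls, paths["classes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report$classification <- list(
    counts = as.list(attr(cls, "counts")),
    fractions = as.list(attr(cls, "fractions")))

  # ---- error decomposition --------------------------------------------
  if (nrow(run$truth)) {
    prof <- error_profiles(run$truth, run$calls, run$reads)
    utils::write.table(prof, paths["errors"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    agg <- aggregate_errors(prof, by = c("read_type", "read_class"))
    report$errors <- split(
      agg[, setdiff(names(agg), c("read_type", "read_class"))],
      paste(agg$read_type, agg$read_class))
  }

  # ---- k-mer bias and GC ----------------------------------------------
  two_d <- run$calls[run$calls$read_type == "2D" &
                       nzchar(run$calls$sequence), , drop = FALSE]
  if (nrow(two_d)) {
    kt <- representation_table(count_kmers(two_d$sequence),
                               count_kmers(refs$target_seq))
    utils::write.table(kt, paths["kmers"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    report$kmer <- list(
      n_possible = nrow(kt),
      under_represented = attr(kt, "under_represented"),
      over_represented = attr(kt, "over_represented"))
    report$gc <- list(reads_2d_pct = gc_content(two_d$sequence),
                      target_pct = gc_content(refs$target_seq))
  }

  # ---- consensus vs coverage ------------------------------------------
  tgt <- run$truth[run$truth$ref_name == refs$target_name &
                     run$truth$read_type == "2D", , drop = FALSE]
  tgt_calls <- two_d[two_d$uuid %in% tgt$uuid, , drop = FALSE]
  avail <- theoretical_coverage(nchar(tgt_calls$sequence),
                                nchar(refs$target_seq))
  levels <- consensus_levels[consensus_levels <= avail]
  if (length(levels) && nrow(tgt_calls)) {
    ca <- accuracy_vs_coverage(tgt_calls, tgt, refs$target_seq,
                               levels = levels, n_seeds = 3, seed = seed)
    utils::write.table(ca, paths["consensus"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    report$consensus <- as.list(ca)
  }

  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  manifest <- paths[file.exists(paths)]
  jsonlite::write_json(as.list(basename(manifest)), paths["manifest"],
                       pretty = TRUE)
  invisible(report)
}

config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}

call_summary <- function(cc) {
  cc <- cc[nzchar(cc$sequence), , drop = FALSE]
  if (nrow(cc) == 0)
    return(list(n_reads = 0, bases = 0, median_length = NA,
                median_mean_q = NA))
  mq <- vapply(cc$quality, mean_quality, numeric(1), USE.NAMES = FALSE)
  list(n_reads = nrow(cc),
       bases = sum(nchar(cc$sequence)),
       median_length = stats::median(nchar(cc$sequence)),
       median_mean_q = stats::median(mq))
}

first_half_fraction <- function(series, t_split) {
  tot <- sum(series$events)
  if (tot == 0) return(NA_real_)
  sum(series$events[series$t_end <= t_split + 1e-9]) / tot
}
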