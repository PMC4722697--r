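#' Simulate a complete nanopore run
#'
#' Generates a full simulated MinION-style run over a target + control
#' reference set: a mux-allocated flow cell, per-pore exponential
#' inactivation, read production at a linearly declining per-pore event
#' rate, a g1-to-g2 well-group switch at `group_switch_hour` (all g1
#' pores retired, fresh g2 pores activated), log-normal read lengths in
#' events, 2D base-call length = `bases_per_event` x events, template and
#' complement 1D calls at `oned_rate_multiplier` x the 2D error rates,
#' time-declining Phred qualities with transient dips after each
#' bias-voltage step, and a control spike-in fraction. Reads with an
#' event count outside `callable_range` appear in the run log but carry
#' no base-calls. A read is class `pass` iff a 2D call exists and its
#' mean quality exceeds 9.
#'
#' Fragment start positions are drawn uniformly over all placements
#' overlapping the reference and clipped to it, so expected coverage is
#' uniform along the reference (edge reads are shortened).
#'
#' @param config A [sim_config()].
#' @param refs A [reference_set()].
#' @param seed Optional integer seed.
#' @return An object of class `sim_run`: list with
#'   \describe{
#'     \item{reads}{data frame, one row per read (the run log):
#'       identity fields (`experiment`, `batch`, `channel`, `well`,
#'       `file_number`, `uuid`), `start_time` and `duration` (seconds),
#'       `n_events`, `well_group`, `read_class`, `callable`,
#'       `n_skips`, `n_stays`, `source_ref`.}
#'     \item{calls}{data frame, one row per base-called read type:
#'       `uuid`, `read_type` (template/complement/2D), `sequence`,
#'       `quality`.}
#'     \item{truth}{data frame of ground-truth alignments: `uuid`,
#'       `read_type`, `ref_name`, `start0`, `end0` (0-based half-open),
#'       `strand`, `script` (native edit script).}
#'     \item{refs, config}{the inputs.}
#'     \item{flowcell}{the initial `flowcell_state`.}
#'     \item{warnings}{character vector of run-level warnings.}
#'   }
#' @export
simulate_run <- function(config, refs, seed = NULL) {
  validate_sim_config(config)
  stopifnot(inherits(refs, "reference_set"))
  with_seed(seed, {
    fc <- init_flowcell(config)
    warnings <- character(0)

    switch_h <- min(config$group_switch_hour, config$run_hours)
    pores <- rbind(
      make_pore_epochs(fc, 1L, 0, switch_h),
      if (config$run_hours > switch_h)
        make_pore_epochs(fc, 2L, switch_h, config$run_hours)
    )
    if (is.null(pores) || nrow(pores) == 0 || !any(pores$group == 1L)) {
      warnings <- c(warnings, "no active pores at t=0")
      warning("no active pores at t=0; run will be empty or start late")
    }

    mean_events <- config$read_len_median_events *
      exp(config$read_len_sdlog^2 / 2)

    starts <- list()
    for (i in seq_len(NROW(pores))) {
      st <- pore_read_starts(config, pores$t_on[i], pores$t_off[i],
                             mean_events)
      if (length(st))
        starts[[length(starts) + 1L]] <- data.frame(
          channel = pores$channel[i], well = pores$well[i],
          well_group = paste0("g", pores$group[i]), start_h = st)
    }
    if (length(starts) == 0) {
      empty <- empty_run(config, refs, fc, c(warnings, "run produced no reads"))
      return(empty)
    }
    rd <- do.call(rbind, starts)
    rd <- rd[order(rd$start_h, rd$channel, rd$well), , drop = FALSE]
    n <- nrow(rd)

    n_events <- pmax(1, round(rlnorm(n, log(config$read_len_median_events),
                                     config$read_len_sdlog)))
    is_control <- runif(n) < config$control_fraction
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    # per-read error multiplier (median 1) and the coupled quality
    # offset: reads that sequence worse get lower base qualities
    err_mult <- rlnorm(n, 0, config$error_sdlog)
    q_read_off <- -config$q_error_coupling * log10(err_mult) +
      rnorm(n, 0, config$q_read_sd)

    # molecule intervals; a fragment clipped at a reference edge is a
    # shorter molecule, so its event count shrinks proportionally and
    # the events-to-2D-bases slope stays at bases_per_event
    ref_len <- ifelse(is_control, nchar(refs$control_seq),
                      nchar(refs$target_seq))
    frags <- t(vapply(seq_len(n), function(i)
      draw_fragment_len(ref_len[i],
                        round(config$bases_per_event * n_events[i])),
      numeric(2)))
    frag_width <- frags[, 2] - frags[, 1]
    n_events <- pmax(1, round(frag_width / config$bases_per_event))
    callable <- n_events >= config$callable_range[1] &
      n_events <= config$callable_range[2]

    # per-channel file numbering from 0
    ord <- order(rd$channel, rd$start_h)
    fn <- integer(n)
    fn[ord] <- sequence(tabulate(rd$channel[ord],
                                 nbins = config$n_channels)) - 1L

    reads <- data.frame(
      experiment = config$experiment_name,
      batch = 0L,
      channel = rd$channel,
      well = rd$well,
      file_number = fn,
      uuid = random_uuid(n),
      # millisecond resolution so text round-trips are exact
      start_time = round(rd$start_h * 3600, 3),
      duration = round(n_events / config$events_per_second, 3),
      n_events = n_events,
      well_group = rd$well_group,
      read_class = "fail",
      callable = callable,
      n_skips = rbinom(n, n_events,
                       pmin(pmax(config$skip_prob +
                                   config$skip_trend_per_hour * rd$start_h,
                                 0), 1)),
      n_stays = rbinom(n, n_events,
                       pmin(pmax(config$stay_prob +
                                   config$stay_trend_per_hour * rd$start_h,
                                 0), 1)),
      source_ref = ifelse(is_control, refs$control_name, refs$target_name),
      stringsAsFactors = FALSE
    )

    calls <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      if (!callable[i]) next
      ref_seq <- if (is_control[i]) refs$control_seq else refs$target_seq
      frag <- frags[i, ]
      frag_seq <- substr(ref_seq, frag[1] + 1, frag[2])
      if (strand[i] == "-") frag_seq <- revcomp(frag_seq)
      t_h <- rd$start_h[i]
      qoff <- q_read_off[i]

      two_d <- corrupt_sequence(frag_seq, config, time = t_h,
                                rate_multiplier = err_mult[i],
                                q_mean_offset = qoff)
      oned_mult <- err_mult[i] * config$oned_rate_multiplier
      tmpl <- corrupt_sequence(frag_seq, config, time = t_h,
                               rate_multiplier = oned_mult,
                               q_mean_offset = qoff + config$q_1d_offset)
      comp <- corrupt_sequence(revcomp(frag_seq), config, time = t_h,
                               rate_multiplier = oned_mult,
                               q_mean_offset = qoff + config$q_1d_offset)
      rn <- reads$uuid[i]
      src <- reads$source_ref[i]
      other <- function(s) if (s == "+") "-" else "+"
      calls[[i]] <- data.frame(
        uuid = rn,
        read_type = c("template", "complement", "2D"),
        sequence = c(tmpl$read, comp$read, two_d$read),
        quality = c(tmpl$qual, comp$qual, two_d$qual),
        stringsAsFactors = FALSE
      )
      truth[[i]] <- data.frame(
        uuid = rn,
        read_type = c("template", "complement", "2D"),
        ref_name = src,
        start0 = frag[1], end0 = frag[2],
        strand = c(strand[i], other(strand[i]), strand[i]),
        script = c(tmpl$script, comp$script, two_d$script),
        stringsAsFactors = FALSE
      )
    }
    calls <- do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
    truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
    if (is.null(calls)) {
      calls <- empty_calls()
      truth <- empty_truth()
    }

    # pass iff a 2D call exists and mean 2D quality > 9
    q2d <- calls[calls$read_type == "2D" & nchar(calls$sequence) > 0, ]
    if (nrow(q2d)) {
      mq <- vapply(q2d$quality, function(s) mean(string_to_phred(s)),
                   numeric(1), USE.NAMES = FALSE)
      pass_uuid <- q2d$uuid[mq > 9]
      reads$read_class[reads$uuid %in% pass_uuid] <- "pass"
    }

    run <- list(reads = reads, calls = calls, truth = truth, refs = refs,
                config = config, flowcell = fc, warnings = warnings)
    class(run) <- "sim_run"
    run
  })
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf(
    "<sim_run> %d reads (%d callable, %d pass), %.2f Mevents, %s\n",
    nrow(x$reads), sum(x$reads$callable),
    sum(x$reads$read_class == "pass"),
    sum(x$reads$n_events) / 1e6,
    if (length(x$warnings)) paste(x$warnings, collapse = "; ") else "ok"))
  invisible(x)
}

# pores active in a given well-group epoch: activation time, death-capped end
make_pore_epochs <- function(fc, group, t_on, t_end) {
  p <- fc[!is.na(fc$group) & fc$group == group, , drop = FALSE]
  if (nrow(p) == 0) return(NULL)
  data.frame(channel = p$channel, well = p$well, group = group,
             t_on = t_on, t_off = pmin(t_on + p$death_offset, t_end))
}

# non-homogeneous Poisson read starts for one pore via thinning
pore_read_starts <- function(config, t_on, t_off, mean_events) {
  if (t_off <= t_on) return(numeric(0))
  r_on <- event_rate_at(config, t_on)
  lmax <- r_on / mean_events
  if (lmax <= 0) return(numeric(0))
  t <- t_on
  out <- numeric(0)
  repeat {
    t <- t + rexp(1, lmax)
    if (t >= t_off) break
    if (runif(1) < event_rate_at(config, t) / r_on)  # thinning
      out <- c(out, t)
  }
  out
}

# uniform edge-clipped fragment: 0-based half-open interval on the reference
draw_fragment <- function(ref_seq, len) {
  draw_fragment_len(nchar(ref_seq), len)
}

draw_fragment_len <- function(L, len) {
  len <- max(1, min(len, L))
  s <- sample.int(L + len - 1, 1) - len   # in [-(len-1), L-1]
  c(max(0, s), min(L, s + len))
}

empty_calls <- function() {
  data.frame(uuid = character(0), read_type = character(0),
             sequence = character(0), quality = character(0),
             stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(uuid = character(0), read_type = character(0),
             ref_name = character(0), start0 = integer(0),
             end0 = integer(0), strand = character(0),
             script = character(0), stringsAsFactors = FALSE)
}

empty_run <- function(config, refs, fc, warnings) {
  reads <- data.frame(
    experiment = character(0), batch = integer(0), channel = integer(0),
    well = integer(0), file_number = integer(0), uuid = character(0),
    start_time = numeric(0), duration = numeric(0), n_events = numeric(0),
    well_group = character(0), read_class = character(0),
    callable = logical(0), n_skips = integer(0), n_stays = integer(0),
    source_ref = character(0), stringsAsFactors = FALSE)
  run <- list(reads = reads, calls = empty_calls(), truth = empty_truth(),
              refs = refs, config = config, flowcell = fc,
              warnings = warnings)
  class(run) <- "sim_run"
  run
}

#' Simulate 2D reads to a target coverage
#'
#' Convenience generator for coverage experiments: draws 2D reads
#' (uniform edge-clipped fragments, either strand, corrupted at the
#' configured 2D rates, qualities at t = 0) from one reference until the
#' theoretical fold coverage of the emitted base-calls reaches `fold`.
#'
#' @param ref_seq Reference sequence (string).
#' @param fold Target theoretical fold coverage (total 2D bases /
#'   reference length).
#' @param config A [sim_config()]; error rates and read-length
#'   distribution are taken from it.
#' @param seed Optional integer seed.
#' @return A list with `calls` and `truth` data frames as in
#'   [simulate_run()] (read type `"2D"` only).
#' @export
simulate_reads_at_coverage <- function(ref_seq, fold, config = sim_config(),
                                       seed = NULL) {
  stopifnot(fold >= 0, nchar(ref_seq) > 0)
  validate_sim_config(config)
  with_seed(seed, {
    L <- nchar(ref_seq)
    target_bases <- fold * L
    got <- 0
    calls <- list()
    truth <- list()
    while (got < target_bases) {
      ev <- max(config$callable_range[1],
                round(rlnorm(1, log(config$read_len_median_events),
                             config$read_len_sdlog)))
      frag <- draw_fragment(ref_seq, round(config$bases_per_event * ev))
      frag_seq <- substr(ref_seq, frag[1] + 1, frag[2])
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (strand == "-") frag_seq <- revcomp(frag_seq)
      cr <- corrupt_sequence(frag_seq, config, time = 0)
      id <- random_uuid(1)
      calls[[length(calls) + 1L]] <- data.frame(
        uuid = id, read_type = "2D", sequence = cr$read,
        quality = cr$qual, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        uuid = id, read_type = "2D", ref_name = "ref",
        start0 = frag[1], end0 = frag[2], strand = strand,
        script = cr$script, stringsAsFactors = FALSE)
      got <- got + nchar(cr$read)
    }
    if (length(calls) == 0)
      return(list(calls = empty_calls(), truth = empty_truth()))
    list(calls = do.call(rbind, calls), truth = do.call(rbind, truth))
  })
}
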