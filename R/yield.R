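#' Partition reads by the callable event range
#'
#' The base-caller does not attempt reads with fewer than 200 or more
#' than 230,000 events; this reproduces that filter.
#'
#' @param reads Run-log data frame with an `n_events` column.
#' @param range Two-element inclusive event-count range.
#' @return A list with `kept` and `excluded` data frames (an exhaustive
#'   partition of the input rows).
#' @examples
#' r <- data.frame(n_events = c(199, 200, 230000, 230001))
#' sapply(filter_callable(r), nrow)
#' @export
filter_callable <- function(reads, range = c(200, 230000)) {
  stopifnot("n_events" %in% names(reads))
  keep <- reads$n_events >= range[1] & reads$n_events <= range[2]
  list(kept = reads[keep, , drop = FALSE],
       excluded = reads[!keep, , drop = FALSE])
}

#' Bin reads into fixed time intervals
#'
#' Reads are counted in the left-closed right-open bin containing their
#' start time; each read's events are spread over the bins its
#' `[start, start + duration)` interval overlaps, proportionally to the
#' overlap (events are produced at a steady rate within a read). Also
#' derives per-bin active-pore counts ([active_pores()]) and
#' per-active-pore rates.
#'
#' @param reads Run-log data frame (`start_time`, `duration`, `n_events`
#'   in seconds/counts; `channel`/`well` enable pore normalisation;
#'   `read_class` enables the 2D-pass fraction).
#' @param bin_width Bin width in seconds (default 900 = 15 min).
#' @param n_bins Number of bins; defaults to cover the last read.
#' @return A `time_bin_series` data frame, one row per bin: `bin`
#'   (0-based index), `t_start`, `t_end` (seconds), `reads_started`,
#'   `events`, `active_pores`, `reads_per_hour_per_pore`,
#'   `events_per_hour_per_pore`, `median_read_len_events`,
#'   `pct_2d_pass`, `mean_skip_pct`, `mean_stay_pct`, `excluded`.
#' @export
bin_reads <- function(reads, bin_width = 900, n_bins = NULL) {
  stopifnot(all(c("start_time", "duration", "n_events") %in% names(reads)))
  if (any(reads$duration < 0)) stop("negative read duration")
  if (is.null(n_bins)) {
    end <- if (nrow(reads)) max(reads$start_time + reads$duration) else 0
    n_bins <- max(1L, ceiling((end + 1e-9) / bin_width))
  }
  bins <- data.frame(
    bin = seq_len(n_bins) - 1L,
    t_start = (seq_len(n_bins) - 1L) * bin_width,
    t_end = seq_len(n_bins) * bin_width)

  start_bin <- pmin(floor(reads$start_time / bin_width), n_bins - 1L)
  bins$reads_started <- tabulate(start_bin + 1L, nbins = n_bins)

  ev <- numeric(n_bins)
  for (i in seq_len(nrow(reads))) {
    s <- reads$start_time[i]
    d <- reads$duration[i]
    e <- reads$n_events[i]
    if (d <= 0) {
      b <- min(floor(s / bin_width), n_bins - 1L) + 1L
      ev[b] <- ev[b] + e
      next
    }
    b0 <- floor(s / bin_width)
    b1 <- ceiling((s + d) / bin_width) - 1
    for (b in b0:b1) {
      ov <- min(s + d, (b + 1) * bin_width) - max(s, b * bin_width)
      tgt <- min(b, n_bins - 1) + 1L   # overflow credited to last bin
      ev[tgt] <- ev[tgt] + e * ov / d
    }
  }
  bins$events <- ev

  bins$active_pores <- if (all(c("channel", "well") %in% names(reads)))
    active_pores(reads, bin_width, n_bins) else NA_integer_
  bh <- bin_width / 3600
  ap <- bins$active_pores
  bins$reads_per_hour_per_pore <-
    ifelse(!is.na(ap) & ap > 0, bins$reads_started / ap / bh, 0)
  bins$events_per_hour_per_pore <-
    ifelse(!is.na(ap) & ap > 0, bins$events / ap / bh, 0)

  med <- rep(NA_real_, n_bins)
  agg <- tapply(reads$n_events, start_bin, stats::median)
  med[as.integer(names(agg)) + 1L] <- agg
  bins$median_read_len_events <- med

  if ("read_class" %in% names(reads)) {
    p <- tapply(reads$read_class == "pass", start_bin, mean)
    bins$pct_2d_pass <- NA_real_
    bins$pct_2d_pass[as.integer(names(p)) + 1L] <- 100 * p
  }
  for (fld in c("skip", "stay")) {
    col <- paste0("n_", fld, "s")
    if (col %in% names(reads)) {
      v <- tapply(100 * reads[[col]] / reads$n_events, start_bin, mean)
      out <- rep(NA_real_, n_bins)
      out[as.integer(names(v)) + 1L] <- v
      bins[[paste0("mean_", fld, "_pct")]] <- out
    }
  }
  bins$excluded <- FALSE
  class(bins) <- c("time_bin_series", "data.frame")
  attr(bins, "bin_width") <- bin_width
  bins
}

#' Active pores per time bin
#'
#' A pore (channel, well) is active in bin b iff it produces at least
#' one read starting in bin b or later, i.e. its last read has not yet
#' started. This operationalises "still producing reads" from read
#' metadata alone and is monotone non-increasing by construction.
#'
#' @param reads Run-log data frame with `channel`, `well`, `start_time`.
#' @param bin_width Bin width in seconds.
#' @param n_bins Number of bins.
#' @return Integer vector of per-bin active-pore counts.
#' @export
active_pores <- function(reads, bin_width = 900, n_bins = NULL) {
  if (is.null(n_bins)) {
    end <- if (nrow(reads)) max(reads$start_time + reads$duration) else 0
    n_bins <- max(1L, ceiling((end + 1e-9) / bin_width))
  }
  if (nrow(reads) == 0) return(integer(n_bins))
  pore <- paste(reads$channel, reads$well)
  last_bin <- tapply(pmin(floor(reads$start_time / bin_width), n_bins - 1L),
                     pore, max)
  # count of pores with last read start in bin >= b
  counts <- tabulate(last_bin + 1L, nbins = n_bins)
  rev(cumsum(rev(counts)))
}

#' Flag bins inside excluded windows
#'
#' Flow-cell behaviour in the first hour, the hour after the well-group
#' switch, and the last hour of a run is dominated by initiation,
#' switching and low-pore-count stochasticity; bins intersecting those
#' windows are flagged and skipped by downstream summaries.
#'
#' @param series A `time_bin_series`.
#' @param run_hours Run length in hours.
#' @param switch_hour Well-group switch hour.
#' @param windows Optional list of `c(start_h, end_h)` windows
#'   overriding the defaults.
#' @return The series with its `excluded` column updated.
#' @export
exclude_windows <- function(series, run_hours = 48, switch_hour = 24,
                            windows = NULL) {
  if (nrow(series) == 0) return(series)
  if (is.null(windows))
    windows <- list(c(0, 1), c(switch_hour, switch_hour + 1),
                    c(run_hours - 1, run_hours))
  excl <- series$excluded
  for (w in windows) {
    ws <- w[1] * 3600
    we <- w[2] * 3600
    excl <- excl | (series$t_start < we & series$t_end > ws)
  }
  series$excluded <- excl
  series
}

#' Read-length quantiles and tail fractions
#'
#' Summaries under both read-count weighting and event-mass (or
#' base-mass) weighting: quartiles plus the fraction of reads (or of
#' total mass) at or above each threshold.
#'
#' @param lengths Numeric vector of read lengths (events or bases).
#' @param thresholds Tail thresholds (defaults: 10,000 bases and 21,000
#'   events, the run-summary conventions).
#' @return A list with `count_weighted` and `mass_weighted`, each holding
#'   `quartiles` (25/50/75 percent) and `tail_fraction` (named by
#'   threshold).
#' @export
length_stats <- function(lengths, thresholds = c(10000, 21000)) {
  stopifnot(length(lengths) > 0)
  qs <- c(0.25, 0.5, 0.75)
  cw <- list(
    quartiles = stats::quantile(lengths, qs, names = FALSE, type = 1),
    tail_fraction = stats::setNames(
      vapply(thresholds, function(th) mean(lengths >= th), numeric(1)),
      thresholds))
  mw <- list(
    quartiles = weighted_quantile(lengths, lengths, qs),
    tail_fraction = stats::setNames(
      vapply(thresholds, function(th)
        sum(lengths[lengths >= th]) / sum(lengths), numeric(1)),
      thresholds))
  list(count_weighted = cw, mass_weighted = mw)
}
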