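#' Simulation configuration for a nanopore run
#'
#' Builds the full set of generative parameters for a simulated 48 h
#' MinION-style run. Defaults emulate a standard R7.3 / SQK-MAP005-era
#' experiment: a 512-channel x 4-well flow cell, a 24 h g1-to-g2
#' well-group switch, a -5 mV bias-voltage step every 4 h with a short
#' quality dip after each step, a declining per-pore event rate, and 2D
#' reads whose base-call length is 0.367 x the event count with median
#' miscall/insertion/deletion rates of 3/4/5 percent.
#'
#' @param run_hours Total run length in hours.
#' @param group_switch_hour Hour at which all g1 pores are retired and g2
#'   pores activated.
#' @param bias_step_hours Interval between bias-voltage adjustments.
#' @param dip_minutes Length of the transient quality dip after each
#'   bias-voltage step.
#' @param n_channels,wells_per_channel Flow-cell geometry.
#' @param well_active_prob Probability that a well holds a usable pore.
#' @param initial_event_rate Events per hour per pore at t = 0. The
#'   default (300) puts the run-level starting rate near 150e3 events/h
#'   with the expected ~499 g1 pores.
#' @param event_rate_decline Linear fractional decline of the per-pore
#'   event rate per hour of run time (floored at zero). The default
#'   0.015/h calibrates the expected fraction of events produced in the
#'   first 24 h to 0.67.
#' @param pore_lifetime_mean Mean of the exponential pore lifetime, hours
#'   from activation.
#' @param read_len_median_events,read_len_sdlog Log-normal read length in
#'   events: median and sdlog. sdlog 0.8 reproduces a ~20 percent tail of
#'   reads at or above 21,000 events.
#' @param events_per_second Sequencing speed used to convert an event
#'   count into a read duration.
#' @param bases_per_event 2D base-call length as a fraction of the read's
#'   event count (slope 0.367, i.e. events:bases of 2.7:1).
#' @param miscall_rate,ins_rate,del_rate Per-column probabilities for the
#'   2D base-calls.
#' @param oned_rate_multiplier Multiplier applied to the three rates for
#'   the template and complement 1D calls (1D error is about twice 2D).
#' @param homopolymer_del_multiplier Factor (>= 1) applied to `del_rate`
#'   inside homopolymer runs of length >= 3.
#' @param q_start_2d Mean 2D Phred quality at t = 0.
#' @param q_decline_per_24h Phred units lost per 24 h of run time.
#' @param q_dip_depth Phred units subtracted during a dip window.
#' @param q_base_sd Within-read per-base quality standard deviation.
#' @param q_read_sd Between-read quality standard deviation (per-read
#'   offset independent of accuracy).
#' @param error_sdlog sdlog of the per-read log-normal error-rate
#'   multiplier (median 1): molecules differ in how well they sequence.
#' @param q_error_coupling Phred units of mean-quality decrease per
#'   decade of per-read error-rate multiplier; ties base quality to
#'   realised accuracy so mean Q anticorrelates with log total error.
#'   Together with `error_sdlog` this drives the declining pass
#'   fraction and the quality-error calibration statistic.
#' @param q_1d_offset Additive offset of 1D mean quality relative to 2D.
#' @param skip_prob,stay_prob Per-event skip/stay probabilities at t = 0.
#' @param skip_trend_per_hour,stay_trend_per_hour Linear time trends of
#'   the skip and stay probabilities (template skips drift down, stays
#'   drift up in real runs).
#' @param control_fraction Probability that a molecule comes from the
#'   control spike-in rather than the target.
#' @param callable_range Two-element integer vector: event-count limits
#'   outside which the base-caller does not attempt a call.
#' @param experiment_name Experiment identifier used in read identities.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config()
#' cfg$callable_range
#' @export
sim_config <- function(run_hours = 48,
                       group_switch_hour = 24,
                       bias_step_hours = 4,
                       dip_minutes = 30,
                       n_channels = 512,
                       wells_per_channel = 4,
                       well_active_prob = 0.60,
                       initial_event_rate = 300,
                       event_rate_decline = 0.015,
                       pore_lifetime_mean = 18,
                       read_len_median_events = 10700,
                       read_len_sdlog = 0.8,
                       events_per_second = 30,
                       bases_per_event = 0.367,
                       miscall_rate = 0.03,
                       ins_rate = 0.04,
                       del_rate = 0.05,
                       oned_rate_multiplier = 2,
                       homopolymer_del_multiplier = 2,
                       q_start_2d = 12.5,
                       q_decline_per_24h = 2,
                       q_dip_depth = 2.5,
                       q_base_sd = 3,
                       q_read_sd = 1,
                       error_sdlog = 0.35,
                       q_error_coupling = 10,
                       q_1d_offset = -3,
                       skip_prob = 0.04,
                       stay_prob = 0.05,
                       skip_trend_per_hour = -5e-4,
                       stay_trend_per_hour = 1e-3,
                       control_fraction = 0.05,
                       callable_range = c(200L, 230000L),
                       experiment_name = "simrun") {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  probs <- c("well_active_prob", "miscall_rate", "ins_rate", "del_rate",
             "skip_prob", "stay_prob", "control_fraction")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop(p, " must be a probability in [0, 1]")
  }
  nonneg <- c("run_hours", "bias_step_hours", "dip_minutes",
              "initial_event_rate", "event_rate_decline",
              "pore_lifetime_mean", "read_len_median_events",
              "events_per_second", "bases_per_event",
              "oned_rate_multiplier", "q_base_sd", "q_read_sd",
              "q_dip_depth", "error_sdlog", "q_error_coupling")
  for (p in nonneg) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || v < 0)
      stop(p, " must be a non-negative number")
  }
  if (cfg$homopolymer_del_multiplier < 1)
    stop("homopolymer_del_multiplier must be >= 1")
  if (length(cfg$callable_range) != 2 ||
      cfg$callable_range[1] >= cfg$callable_range[2])
    stop("callable_range must be c(min, max) with min < max")
  if (cfg$n_channels < 1 || cfg$wells_per_channel < 1)
    stop("flow cell must have at least one channel and one well")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  flow cell: %d channels x %d wells, P(active) = %.2f\n",
              x$n_channels, x$wells_per_channel, x$well_active_prob))
  cat(sprintf("  run: %g h, group switch at %g h, bias step every %g h\n",
              x$run_hours, x$group_switch_hour, x$bias_step_hours))
  cat(sprintf("  events: %g /h/pore, decline %g /h, pore lifetime %g h\n",
              x$initial_event_rate, x$event_rate_decline,
              x$pore_lifetime_mean))
  cat(sprintf("  2D rates m/i/d: %g/%g/%g, 1D x%g, homopolymer del x%g\n",
              x$miscall_rate, x$ins_rate, x$del_rate,
              x$oned_rate_multiplier, x$homopolymer_del_multiplier))
  cat(sprintf("  quality: start %g, -%g/24h, dip %g; control fraction %g\n",
              x$q_start_2d, x$q_decline_per_24h, x$q_dip_depth,
              x$control_fraction))
  invisible(x)
}

#' Write / read a simulation configuration as JSON
#'
#' @param cfg A `sim_config` object.
#' @param path File path.
#' @return `read_sim_config` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- sim_config()
  unknown <- setdiff(names(lst), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(lst)] <- lst
  cfg$callable_range <- as.numeric(cfg$callable_range)
  validate_sim_config(cfg)
}

# per-pore event rate (events/h) at run time t (hours)
event_rate_at <- function(cfg, t) {
  cfg$initial_event_rate * pmax(0, 1 - cfg$event_rate_decline * t)
}

# TRUE if t (hours) falls in a transient dip window after a bias step
in_dip_window <- function(cfg, t) {
  if (cfg$bias_step_hours <= 0) return(rep(FALSE, length(t)))
  phase <- t %% cfg$bias_step_hours
  t > 0 & phase >= 0 & phase < cfg$dip_minutes / 60
}

# mean 2D Phred quality for a read starting at t (hours)
q2d_mean_at <- function(cfg, t) {
  cfg$q_start_2d - cfg$q_decline_per_24h * t / 24 -
    ifelse(in_dip_window(cfg, t), cfg$q_dip_depth, 0)
}
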