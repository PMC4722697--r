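#' Initialise a simulated flow cell
#'
#' Each of the `n_channels x wells_per_channel` wells holds a usable pore
#' independently with probability `well_active_prob`. Within a channel the
#' active wells are ranked by an i.i.d. continuous quality score and
#' assigned to well-groups g1 (best) downward, so the number of channels
#' contributing to group k equals the number of channels with at least k
#' active wells. Each assigned well also receives an exponential lifetime
#' (hours from its activation).
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return An object of class `flowcell_state`: a data frame with one row
#'   per well (`channel`, `well`, `active`, `quality`, `group`,
#'   `death_offset`).
#' @examples
#' fc <- init_flowcell(sim_config(), seed = 1)
#' flowcell_group_counts(fc)
#' @export
init_flowcell <- function(config, seed = NULL) {
  validate_sim_config(config)
  with_seed(seed, {
    nc <- config$n_channels
    nw <- config$wells_per_channel
    wells <- data.frame(
      channel = rep(seq_len(nc), each = nw),
      well = rep(seq_len(nw), times = nc),
      active = runif(nc * nw) < config$well_active_prob,
      quality = runif(nc * nw),
      group = NA_integer_,
      death_offset = NA_real_
    )
    # rank active wells within channel by quality, best first
    act <- which(wells$active)
    if (length(act)) {
      o <- act[order(wells$channel[act], -wells$quality[act])]
      rank_in_channel <- sequence(tabulate(wells$channel[act], nbins = nc))
      wells$group[o] <- rank_in_channel
      wells$death_offset[o] <-
        rexp(length(o), rate = 1 / config$pore_lifetime_mean)
    }
    class(wells) <- c("flowcell_state", "data.frame")
    wells
  })
}

#' Per-group pore counts of a flow cell
#'
#' @param fc A `flowcell_state`.
#' @return Named integer vector `g1..g4` (length `wells_per_channel`).
#' @export
flowcell_group_counts <- function(fc) {
  ngroups <- max(fc$well)
  counts <- tabulate(fc$group, nbins = ngroups)
  names(counts) <- paste0("g", seq_len(ngroups))
  counts
}

#' Flow-cell utilisation summary
#'
#' The standard run-summary arithmetic: each group's pore count as a
#' percentage of the per-group maximum (one well per channel), the
#' percentage of all wells holding an active pore, and the percentage of
#' all wells usable under the standard protocol (groups g1 + g2 only).
#'
#' @param group_counts Named or plain integer vector of per-group pore
#'   counts (g1 first).
#' @param n_channels Number of channels (per-group maximum).
#' @param wells_per_channel Wells per channel.
#' @return A list with `pct_of_group_max` (one value per group),
#'   `pct_wells_active`, and `pct_wells_usable`.
#' @examples
#' # the study's median per-group counts
#' flowcell_utilization(c(484, 409, 262, 78))
#' @export
flowcell_utilization <- function(group_counts, n_channels = 512,
                                 wells_per_channel = 4) {
  stopifnot(length(group_counts) >= 1, all(group_counts >= 0))
  total_wells <- n_channels * wells_per_channel
  list(
    pct_of_group_max = 100 * group_counts / n_channels,
    pct_wells_active = 100 * sum(group_counts) / total_wells,
    pct_wells_usable = 100 * sum(group_counts[1:min(2, length(group_counts))]) /
      total_wells
  )
}

#' Closed-form expected group counts
#'
#' Expected number of channels with at least k of `wells_per_channel`
#' wells active, for k = 1..`wells_per_channel`.
#'
#' @param p Per-well activation probability.
#' @param n_channels,wells_per_channel Flow-cell geometry.
#' @return Numeric vector of expected group counts (g1 first).
#' @export
expected_group_counts <- function(p, n_channels = 512,
                                  wells_per_channel = 4) {
  k <- seq_len(wells_per_channel)
  n_channels * pbinom(k - 1, wells_per_channel, p, lower.tail = FALSE)
}
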