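#' Corrupt a sequence with miscalls, insertions and deletions
#'
#' Column-wise generative error process. Each alignment column is an
#' insertion with probability `ins_rate` (a uniform random base,
#' consuming no reference); otherwise it consumes the next reference
#' base, which is deleted with probability `del_rate` (multiplied by
#' `homopolymer_del_multiplier` inside single-base runs of length >= 3),
#' miscalled with probability `miscall_rate` (uniform over the three
#' alternatives), or emitted as a match. Under this factorisation the
#' realised per-column operation frequencies are unbiased estimates of
#' the configured rates.
#'
#' Per-base Phred qualities are drawn around the time-dependent mean
#' quality (start quality minus the linear 24 h drift, minus the dip
#' depth inside the transient window after each bias-voltage step).
#'
#' @param seq Reference fragment to corrupt (non-empty A/C/G/T string).
#' @param config A [sim_config()].
#' @param time Run time in hours at which the read starts (drives the
#'   quality mean).
#' @param seed Optional integer seed.
#' @param rate_multiplier Multiplier applied to the three error rates
#'   (used for the 1D template/complement calls; rates are capped so the
#'   per-reference-base probabilities stay below 1).
#' @param q_mean_offset Additive per-read offset on the mean quality.
#' @param q_mean Override the time-derived mean quality entirely.
#' @return A list with `read` (the corrupted sequence), `script` (native
#'   per-column edit script, see [replay_script()]), and `qual`
#'   (Phred+33 string, one symbol per read base).
#' @examples
#' cfg <- sim_config(miscall_rate = 0, ins_rate = 0, del_rate = 0)
#' corrupt_sequence("ACGTACGT", cfg, time = 0, seed = 1)$read
#' @export
corrupt_sequence <- function(seq, config, time = 0, seed = NULL,
                             rate_multiplier = 1, q_mean_offset = 0,
                             q_mean = NULL) {
  if (!nzchar(seq)) stop("seq must be non-empty")
  validate_sim_config(config)
  with_seed(seed, {
    refv <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(refv)
    mis <- config$miscall_rate * rate_multiplier
    ins <- min(config$ins_rate * rate_multiplier, 0.95)
    del <- config$del_rate * rate_multiplier

    # homopolymer membership (runs >= 3 of one base)
    r <- rle(refv)
    in_hp <- rep(r$lengths >= 3, r$lengths)
    # rates are per alignment column; a fraction ins of columns are
    # insertions, so the per-reference-base probabilities are scaled by
    # 1/(1 - ins) to keep the per-column frequencies at the configured
    # values
    delp <- pmin(ifelse(in_hp, del * config$homopolymer_del_multiplier,
                        del) / (1 - ins), 1)
    misp <- pmin(mis / (1 - ins), 1 - delp)

    # per-reference-base outcome
    u <- runif(n)
    base_op <- ifelse(u < delp, "D", ifelse(u < delp + misp, "X", "="))

    # geometric run of insertion columns before each reference base and
    # one after the last; makes the expected insertion-column fraction
    # equal ins exactly
    k <- if (ins > 0) rgeom(n + 1, prob = 1 - ins) else integer(n + 1)
    n_ins <- sum(k)

    # interleave: slot i carries k[i] insertions then base i (slot n+1
    # carries trailing insertions only)
    slot <- c(rep.int(seq_len(n + 1), k), seq_len(n))
    pri <- c(rep.int(0L, n_ins), rep.int(1L, n))
    opsv <- c(rep.int("I", n_ins), base_op)[order(slot, pri)]

    # emitted bases: matches copy the reference, miscalls pick one of the
    # three alternatives, insertions are uniform over four bases
    ref_cols <- opsv != "I"
    col_ref_base <- character(length(opsv))
    col_ref_base[ref_cols] <- refv
    script <- opsv
    is_x <- opsv == "X"
    if (any(is_x)) {
      shift <- sample.int(3, sum(is_x), replace = TRUE)
      idx <- (match(col_ref_base[is_x], BASES) - 1L + shift) %% 4L + 1L
      script[is_x] <- tolower(BASES[idx])
    }
    is_i <- opsv == "I"
    if (any(is_i))
      script[is_i] <- BASES[sample.int(4, sum(is_i), replace = TRUE)]

    emitted <- script != "D"
    readv <- character(sum(emitted))
    e_script <- script[emitted]
    readv[e_script == "="] <- col_ref_base[opsv == "="]
    lc <- e_script %in% c("a", "c", "g", "t")
    readv[lc] <- toupper(e_script[lc])
    uc <- e_script %in% BASES
    readv[uc] <- e_script[uc]

    qm <- if (!is.null(q_mean)) q_mean
          else q2d_mean_at(config, time) + q_mean_offset
    q <- pmin(pmax(round(rnorm(length(readv), qm, config$q_base_sd)), 1), 41)

    list(read = paste(readv, collapse = ""),
         script = paste(script, collapse = ""),
         qual = phred_to_string(q))
  })
}
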