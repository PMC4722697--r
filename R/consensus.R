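#' Theoretical fold coverage
#'
#' Total base-call length divided by reference length.
#'
#' @param lengths Read lengths in bases (or a calls data frame, from
#'   which 2D sequence lengths are taken).
#' @param ref_length Reference length (> 0).
#' @return Fold coverage (0 for no reads).
#' @export
theoretical_coverage <- function(lengths, ref_length) {
  stopifnot(ref_length > 0)
  if (is.data.frame(lengths))
    lengths <- nchar(lengths$sequence[lengths$read_type == "2D"])
  if (length(lengths) == 0) return(0)
  sum(as.numeric(lengths)) / ref_length
}

#' Subsample reads to a target theoretical coverage
#'
#' Draws a uniform random subset of reads whose total base-call length
#' reaches the target coverage; the achieved coverage overshoots the
#' target by less than one read length. Reproducible under a fixed
#' seed.
#'
#' @param calls Calls data frame (rows of the requested `read_type`
#'   are subsampled).
#' @param fold Target theoretical fold coverage.
#' @param ref_length Reference length.
#' @param seed Optional integer seed.
#' @param read_type Read type to subsample (default `"2D"`).
#' @return Character vector of selected uuids.
#' @export
subsample_to_coverage <- function(calls, fold, ref_length, seed = NULL,
                                  read_type = "2D") {
  cc <- calls[calls$read_type == read_type, , drop = FALSE]
  avail <- theoretical_coverage(nchar(cc$sequence), ref_length)
  if (fold > avail)
    stop(sprintf("target fold %.2f exceeds available %.2f", fold, avail))
  if (fold <= 0) return(character(0))
  with_seed(seed, {
    o <- sample.int(nrow(cc))
    cum <- cumsum(as.numeric(nchar(cc$sequence[o])))
    need <- which(cum >= fold * ref_length)[1]
    cc$uuid[o[seq_len(need)]]
  })
}

#' Majority-vote pileup consensus against one reference
#'
#' Each alignment column votes at its reference site: match columns
#' vote the reference base, mismatch columns vote the miscalled base,
#' deletion columns vote "absent"; insertion columns touch no site and
#' are ignored. The consensus at a site is the plurality vote, ties
#' broken by the fixed order A < C < G < T < absent. A site is called
#' correctly iff its consensus equals the reference base; sites with no
#' votes are reported separately.
#'
#' @param aln Alignment data frame against a single reference: `start0`
#'   and `script` (native edit scripts carrying mismatch base
#'   identities, as produced by the simulator or [read_alignments()]
#'   with SEQ present).
#' @param ref_seq Reference sequence.
#' @return A list: `consensus` (character vector, one of A/C/G/T,
#'   `"-"` for a winning absent vote, `NA` for zero coverage),
#'   `coverage` (votes per site), `correct` (logical per site, `FALSE`
#'   where coverage is zero), `n_zero_coverage`,
#'   `accuracy_pct` (100 x fraction of all sites correct) and
#'   `accuracy_covered_pct` (restricted to covered sites).
#' @export
pileup_consensus <- function(aln, ref_seq) {
  L <- nchar(ref_seq)
  refv <- strsplit(ref_seq, "", fixed = TRUE)[[1]]
  votes <- matrix(0L, nrow = L, ncol = 5,
                  dimnames = list(NULL, c(BASES, "-")))
  if (nrow(aln)) {
    ch <- strsplit(aln$script, "", fixed = TRUE)
    lens <- lengths(ch)
    allch <- unlist(ch, use.names = FALSE)
    read_idx <- rep.int(seq_along(lens), lens)
    ref_consuming <- allch %in% c("=", "X", "a", "c", "g", "t", "D")
    # per-read running reference offset of each ref-consuming column
    cs <- cumsum(ref_consuming)
    first_col <- cumsum(c(0L, lens[-length(lens)])) + 1L
    base_cs <- cs[first_col] - as.integer(ref_consuming[first_col])
    pos <- aln$start0[read_idx] + (cs - base_cs[read_idx])  # 1-based site
    vote <- integer(length(allch))                          # 0 = no vote
    is_match <- allch == "="
    vote[is_match] <- match(refv[pos[is_match]], BASES)
    is_mis <- allch %in% c("a", "c", "g", "t")
    vote[is_mis] <- match(toupper(allch[is_mis]), BASES)
    vote[allch == "X"] <- NA_integer_   # mismatch with unknown base
    vote[allch == "D"] <- 5L
    ok <- ref_consuming & !is.na(vote) & vote > 0 & pos >= 1 & pos <= L
    tab <- tabulate((pos[ok] - 1L) * 5L + vote[ok], nbins = L * 5L)
    votes <- matrix(tab, nrow = L, ncol = 5, byrow = TRUE,
                    dimnames = list(NULL, c(BASES, "-")))
  }
  coverage <- rowSums(votes)
  cons <- rep(NA_character_, L)
  covered <- coverage > 0
  if (any(covered)) {
    win <- max.col(votes[covered, , drop = FALSE], ties.method = "first")
    cons[covered] <- c(BASES, "-")[win]
  }
  correct <- !is.na(cons) & cons == refv
  list(consensus = cons, coverage = coverage, correct = correct,
       n_zero_coverage = sum(!covered),
       accuracy_pct = 100 * mean(correct),
       accuracy_covered_pct =
         if (any(covered)) 100 * mean(correct[covered]) else NA_real_)
}

#' Consensus accuracy as a function of coverage
#'
#' For each coverage level, subsamples the reads to that theoretical
#' fold, builds the majority pileup consensus, and records the fraction
#' of reference sites called correctly (zero-coverage sites counted
#' incorrect), averaged over seeds.
#'
#' @param calls,aln Calls and alignments of the available reads (2D).
#' @param ref_seq Reference sequence.
#' @param levels Numeric vector of target fold coverages.
#' @param n_seeds Number of subsampling replicates per level.
#' @param seed Base seed; replicate r of level l uses
#'   `seed + 1000 * l + r`.
#' @return A `coverage_accuracy` data frame: `fold`, `n_seeds`,
#'   `accuracy_pct` (mean), `accuracy_sd`, `accuracy_covered_pct`,
#'   `mean_zero_coverage`.
#' @export
accuracy_vs_coverage <- function(calls, aln, ref_seq,
                                 levels = c(5, 10, 20, 40, 60),
                                 n_seeds = 5, seed = 1) {
  rows <- lapply(seq_along(levels), function(li) {
    accs <- numeric(n_seeds)
    cov_accs <- numeric(n_seeds)
    zeros <- numeric(n_seeds)
    for (r in seq_len(n_seeds)) {
      ids <- subsample_to_coverage(calls, levels[li], nchar(ref_seq),
                                   seed = seed + 1000 * li + r)
      sub <- aln[aln$uuid %in% ids & aln$read_type == "2D", , drop = FALSE]
      pc <- pileup_consensus(sub, ref_seq)
      accs[r] <- pc$accuracy_pct
      cov_accs[r] <- pc$accuracy_covered_pct
      zeros[r] <- pc$n_zero_coverage
    }
    data.frame(fold = levels[li], n_seeds = n_seeds,
               accuracy_pct = mean(accs),
               accuracy_sd = stats::sd(accs),
               accuracy_covered_pct = mean(cov_accs),
               mean_zero_coverage = mean(zeros))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("coverage_accuracy", "data.frame")
  out
}
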