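#' Decompose an alignment into miscall/insertion/deletion percentages
#'
#' The total percent error of a read is the percentage of the read that
#' is inaccurate: miscalled bases, bases inserted in the read, and bases
#' deleted from the read but present in the reference. The denominator
#' is the total number of alignment columns N (matches + mismatches +
#' insertions + deletions), which makes miscall + insertion + deletion +
#' identity an exact partition of 100; `denominator = "readlen"` divides
#' by the aligned read length instead for comparison.
#'
#' @param script Native edit script or =/X/I/D operation string (or an
#'   alignment data-frame row's `script` value).
#' @param denominator `"columns"` (default) or `"readlen"`.
#' @return A one-row data frame: `miscall_pct`, `ins_pct`, `del_pct`,
#'   `total_pct` (exactly their sum), `identity_pct`,
#'   `longest_perfect_run`, `n_columns`.
#' @examples
#' decompose_errors(paste0(strrep("=", 90), strrep("X", 3),
#'                         strrep("I", 4), strrep("D", 5)))
#' @export
decompose_errors <- function(script, denominator = c("columns", "readlen")) {
  denominator <- match.arg(denominator)
  ops <- script_ops(script)
  if (length(ops) == 0) stop("empty alignment: error profile undefined")
  n_match <- sum(ops == "=")
  n_mis <- sum(ops == "X")
  n_ins <- sum(ops == "I")
  n_del <- sum(ops == "D")
  N <- if (denominator == "columns") length(ops)
       else n_match + n_mis + n_ins
  if (N == 0) stop("zero-length denominator: error profile undefined")
  m <- 100 * n_mis / N
  i <- 100 * n_ins / N
  d <- 100 * n_del / N
  data.frame(miscall_pct = m, ins_pct = i, del_pct = d,
             total_pct = m + i + d,
             identity_pct = 100 * n_match / N,
             longest_perfect_run = longest_perfect_run(script),
             n_columns = length(ops))
}

#' Longest run of consecutive match columns
#'
#' The longest perfect subsequence of a read's alignment, a
#' base-caller-independent measure of local accuracy.
#'
#' @param script Native edit script or =/X/I/D string.
#' @return Integer run length (0 if no match column).
#' @export
longest_perfect_run <- function(script) {
  ops <- script_ops(script)
  if (length(ops) == 0) return(0L)
  r <- rle(ops == "=")
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}

#' Mean Phred quality of a quality string
#'
#' @param qual Phred+33 quality string (non-empty).
#' @return Arithmetic mean of the per-base Phred scores.
#' @export
mean_quality <- function(qual) {
  q <- string_to_phred(qual)
  if (length(q) == 0) stop("empty quality string")
  mean(q)
}

#' Pass/fail classification of a read
#'
#' A read fails iff it has no 2D base-call or its mean 2D base quality
#' is less than or equal to 9; it passes otherwise.
#'
#' @param qual_2d 2D quality string, or `NA`/`""` when no 2D call exists.
#' @return `"pass"` or `"fail"`.
#' @export
classify_pass_fail <- function(qual_2d) {
  if (is.na(qual_2d) || !nzchar(qual_2d)) return("fail")
  if (mean_quality(qual_2d) <= 9) "fail" else "pass"
}

#' Quality/error calibration statistic
#'
#' The run-calibration statistic 10^(-Q/1000) / E, where Q is the mean
#' base quality of a read and E its total percent error; under a single
#' shared quality model the value should be the same for every read, so
#' its drift over a run exposes mis-calibration. The conventional Phred
#' interpretation p = 10^(-Q/10) is available via `phred = "standard"`.
#'
#' @param Q Mean base quality (Phred).
#' @param E Total percent error (> 0).
#' @param phred `"run"` (10^(-Q/1000), the run-summary convention) or
#'   `"standard"` (10^(-Q/10)).
#' @return The statistic 10^(-Q/k)/E.
#' @export
quality_error_stat <- function(Q, E, phred = c("run", "standard")) {
  phred <- match.arg(phred)
  if (any(E <= 0)) stop("E must be positive")
  k <- if (phred == "run") 1000 else 10
  10^(-Q / k) / E
}

#' Error profiles for a set of alignments
#'
#' Vectorised [decompose_errors()] over an alignment table, joined with
#' read metadata (mean quality, read class, start time) when available.
#'
#' @param aln Alignment data frame with `uuid`, `read_type`, `script`.
#' @param calls Optional calls data frame supplying quality strings.
#' @param reads Optional run-log data frame supplying `read_class` and
#'   `start_time`.
#' @param denominator Passed to [decompose_errors()].
#' @return Data frame, one row per alignment: identity columns plus the
#'   [decompose_errors()] fields, `mean_q`, `read_class`, `start_time`.
#' @export
error_profiles <- function(aln, calls = NULL, reads = NULL,
                           denominator = "columns") {
  if (nrow(aln) == 0) stop("no alignments")
  prof <- do.call(rbind, lapply(aln$script, decompose_errors,
                                denominator = denominator))
  out <- cbind(aln[, c("uuid", "read_type"), drop = FALSE], prof)
  out$mean_q <- NA_real_
  if (!is.null(calls)) {
    key <- paste(out$uuid, out$read_type)
    m <- match(key, paste(calls$uuid, calls$read_type))
    ok <- !is.na(m) & nzchar(calls$quality[m])
    out$mean_q[ok] <- vapply(calls$quality[m[ok]], mean_quality,
                             numeric(1), USE.NAMES = FALSE)
  }
  if (!is.null(reads)) {
    m <- match(out$uuid, reads$uuid)
    out$read_class <- reads$read_class[m]
    out$start_time <- reads$start_time[m]
  }
  rownames(out) <- NULL
  out
}

#' Aggregate error profiles by group
#'
#' Medians and interquartile ranges of the miscall, insertion, deletion
#' and total percentages per group (read type, class, time bin, ...).
#'
#' @param profiles [error_profiles()] output.
#' @param by Character vector of grouping columns present in `profiles`
#'   (e.g. `c("read_type", "read_class")`); `"bin"` is derived from
#'   `start_time` when requested.
#' @param bin_width Bin width in seconds for the `"bin"` key.
#' @return Data frame with one row per group: the keys, `n`, and
#'   `<metric>_med` / `<metric>_iqr` for the four error metrics.
#' @export
aggregate_errors <- function(profiles, by = c("read_type", "read_class"),
                             bin_width = 900) {
  if ("bin" %in% by && !"bin" %in% names(profiles))
    profiles$bin <- floor(profiles$start_time / bin_width)
  missing_keys <- setdiff(by, names(profiles))
  if (length(missing_keys))
    stop("grouping columns not present: ",
         paste(missing_keys, collapse = ", "))
  keys <- profiles[, by, drop = FALSE]
  metrics <- c("miscall_pct", "ins_pct", "del_pct", "total_pct")
  split_idx <- split(seq_len(nrow(profiles)), keys, drop = TRUE)
  rows <- lapply(split_idx, function(idx) {
    g <- profiles[idx, , drop = FALSE]
    row <- unique(g[, by, drop = FALSE])[1, , drop = FALSE]
    row$n <- length(idx)
    for (m in metrics) {
      row[[paste0(m, "_med")]] <- stats::median(g[[m]])
      row[[paste0(m, "_iqr")]] <- stats::IQR(g[[m]])
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Banded anchored alignment of a read to a reference window
#'
#' Global affine-gap (Gotoh) alignment of a read against an anchored
#' reference window, restricted to a diagonal band. A gap of length k
#' costs `gap_open + k * gap_extend`. If the optimal path touches the
#' band boundary the band is widened once (x4) and the alignment
#' re-run; if it still touches, an error is raised. A desk-scale
#' substitute for a genome-scale mapper when inputs lack alignments.
#'
#' @param read Read sequence.
#' @param ref Full reference sequence.
#' @param anchor 0-based half-open reference interval `c(start0, end0)`
#'   to align against.
#' @param band Half-width of the diagonal band.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A one-row alignment data frame (`ref_name` `NA`): `start0`,
#'   `end0`, `strand` `"+"`, `mapq` 60, `script` (native edit script),
#'   and a `score` attribute.
#' @export
anchored_align <- function(read, ref, anchor = c(0, nchar(ref)),
                           band = 50, match = 1, mismatch = -1,
                           gap_open = -2, gap_extend = -1) {
  stopifnot(anchor[1] >= 0, anchor[2] <= nchar(ref), anchor[1] < anchor[2])
  window <- substr(ref, anchor[1] + 1, anchor[2])
  res <- banded_gotoh_cpp(read, window, as.integer(band),
                          match, mismatch, gap_open, gap_extend)
  if (res$band_hit) {
    res <- banded_gotoh_cpp(read, window, as.integer(band * 4L),
                            match, mismatch, gap_open, gap_extend)
    if (res$band_hit)
      stop("alignment leaves the band even after widening; ",
           "increase `band` or re-anchor")
  }
  script <- enrich_script(strsplit(res$ops, "", fixed = TRUE)[[1]], read)
  out <- data.frame(uuid = NA_character_, read_type = "2D",
                    ref_name = NA_character_, start0 = anchor[1],
                    end0 = anchor[2], strand = "+", mapq = 60L,
                    script = paste(script, collapse = ""),
                    stringsAsFactors = FALSE)
  attr(out, "score") <- res$score
  out
}
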