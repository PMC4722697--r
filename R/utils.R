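#' @useDynLib porewise, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm rexp rbinom rlnorm rgeom pbinom
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. `seed = NULL` uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

BASES <- c("A", "C", "G", "T")

#' Convert integer Phred scores to a Phred+33 quality string
#'
#' @param q Integer vector of per-base quality scores.
#' @return A single quality string.
#' @export
phred_to_string <- function(q) {
  if (length(q) == 0) return("")
  intToUtf8(as.integer(round(q)) + 33L)
}

#' Convert a Phred+33 quality string to integer scores
#'
#' @param s Quality string.
#' @return Integer vector of Phred scores (length `nchar(s)`).
#' @export
string_to_phred <- function(s) {
  if (nchar(s) == 0) return(integer(0))
  utf8ToInt(s) - 33L
}

#' Reverse-complement a DNA string
#'
#' @param seq Character scalar over A/C/G/T (case-insensitive).
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# ---- edit scripts ------------------------------------------------------
#
# A native edit script is a character string with one symbol per alignment
# column, rich enough to replay the read from the reference alone:
#   '='          match (emit the reference base)
#   'a','c','g','t'  mismatch (consume a reference base, emit this base)
#   'A','C','G','T'  insertion (emit this base, consume nothing)
#   'D'          deletion (consume a reference base, emit nothing)

#' Column operation classes of an edit script
#'
#' Maps a native edit script (or an =/X/I/D operation string) to one
#' class character per column: `=` match, `X` mismatch, `I` insertion,
#' `D` deletion.
#'
#' @param script Edit script string.
#' @return Character vector of per-column classes.
#' @export
script_ops <- function(script) {
  ch <- strsplit(script, "", fixed = TRUE)[[1]]
  ops <- ch
  ops[ch %in% c("a", "c", "g", "t", "X")] <- "X"
  ops[ch %in% c("A", "C", "G", "T", "I")] <- "I"
  ops
}

#' Replay an edit script against a reference window
#'
#' Reconstructs the read sequence encoded by a native edit script. This is
#' the ground-truth invariant of the simulator: replaying a read's script
#' against its source interval reproduces the emitted read exactly.
#'
#' @param ref Reference sequence (full chromosome/contig) as a string.
#' @param start0 0-based start of the aligned window on `ref`.
#' @param script Native edit script.
#' @return The read sequence implied by the script.
#' @export
replay_script <- function(ref, start0, script) {
  ch <- strsplit(script, "", fixed = TRUE)[[1]]
  if (length(ch) == 0) return("")
  ref_consuming <- ch %in% c("=", "a", "c", "g", "t", "D")
  refv <- strsplit(ref, "", fixed = TRUE)[[1]]
  pos <- start0 + cumsum(ref_consuming)        # 1-based index into refv
  out <- character(length(ch))
  m <- ch == "="
  out[m] <- refv[pos[m]]
  mm <- ch %in% c("a", "c", "g", "t")
  out[mm] <- toupper(ch[mm])
  ins <- ch %in% c("A", "C", "G", "T")
  out[ins] <- ch[ins]
  paste(out[ch != "D"], collapse = "")
}

#' Reference span of an edit script
#'
#' @param script Native edit script or =/X/I/D string.
#' @return Number of reference bases consumed.
#' @export
script_ref_span <- function(script) {
  ops <- script_ops(script)
  sum(ops %in% c("=", "X", "D"))
}

#' Convert per-column operations to a CIGAR string
#'
#' Uses the =/X dialect (match `=`, mismatch `X`) so that error
#' decomposition needs no reference lookup.
#'
#' @param script Native edit script or =/X/I/D string.
#' @return CIGAR string, e.g. `"10=1X2=1I3=1D2="`.
#' @export
ops_to_cigar <- function(script) {
  ops <- script_ops(script)
  if (length(ops) == 0) return("*")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Expand a CIGAR string to per-column operations
#'
#' Accepts the =/X dialect plus S/H clipping (clipped columns are
#' dropped). A CIGAR using M requires an MD tag to locate mismatches; see
#' [read_alignments()].
#'
#' @param cigar CIGAR string.
#' @return Character vector of per-column operations over `=`, `X`, `I`,
#'   `D`, `M`.
#' @export
cigar_to_ops <- function(cigar) {
  if (cigar == "*" || nchar(cigar) == 0) return(character(0))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[=XIDMSHNP]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  keep <- !(ops %in% c("S", "H"))
  rep(ops[keep], lens[keep])
}

# weighted quantile (inverse empirical CDF, type 1)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

random_uuid <- function(n = 1) {
  hex <- c(0:9, letters[1:6])
  vapply(seq_len(n), function(i)
    paste(sample(hex, 32, replace = TRUE), collapse = ""), character(1))
}
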