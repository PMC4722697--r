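#' Count overlapping k-mers in a set of sequences
#'
#' Slides a window of size k base-by-base over each sequence and counts
#' every window; windows containing non-ACGT symbols are skipped.
#' Counts are summed across sequences.
#'
#' @param sequences Character vector of sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param k Word size (default 5).
#' @return Named integer vector of counts over the 4^k possible k-mers
#'   (zeros included), in lexicographic order.
#' @examples
#' count_kmers("AAAAAA", k = 5)[["AAAAA"]]
#' @export
count_kmers <- function(sequences, k = 5) {
  stopifnot(k >= 1)
  if (!inherits(sequences, "DNAStringSet")) {
    sequences <- sequences[nzchar(sequences)]
    if (length(sequences) == 0 ||
        all(nchar(sequences) < k)) {
      warning("k larger than every sequence; no k-mers counted")
      kmers <- mkAllStrings_acgt(k)
      return(stats::setNames(integer(length(kmers)), kmers))
    }
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  counts <- Biostrings::oligonucleotideFrequency(
    sequences, width = k, step = 1, simplify.as = "collapse")
  storage.mode(counts) <- "integer"
  counts
}

mkAllStrings_acgt <- function(k) {
  g <- do.call(expand.grid,
               c(rep(list(BASES), k), KEEP.OUT.ATTRS = FALSE,
                 stringsAsFactors = FALSE))
  sort(apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = ""))
}

#' k-mer representation table: reads versus reference
#'
#' Relative abundance of each k-mer in the reads and in the reference
#' (each normalised to sum to 1), their difference, and the top-10
#' under- and over-represented lists. Under-represented k-mers are those
#' with the largest abundance deficit in the reads relative to the
#' reference; over-represented symmetrically. Ties are broken
#' lexicographically. By default the reference is counted on both
#' strands so the comparison is strand-balanced against reads sequenced
#' from either strand.
#'
#' @param read_counts Named k-mer counts from the reads
#'   ([count_kmers()]).
#' @param ref_counts Named k-mer counts from the reference; pass counts
#'   of the forward strand and leave `ref_both_strands = TRUE` to add
#'   the reverse complement, or set it to `FALSE` to compare as given.
#' @param ref_both_strands Count the reference's reverse complement too.
#' @param top Number of entries in the ranked lists.
#' @return A `kmer_table` data frame ranked by difference (most
#'   under-represented first): `kmer`, `read_count`, `ref_count`,
#'   `read_abundance`, `ref_abundance`, `difference` (read - ref), with
#'   `under_represented` and `over_represented` character-vector
#'   attributes.
#' @export
representation_table <- function(read_counts, ref_counts,
                                 ref_both_strands = TRUE, top = 10) {
  if (sum(read_counts) == 0 || sum(ref_counts) == 0)
    stop("read and reference k-mer counts must be non-empty")
  kmers <- names(ref_counts)
  if (ref_both_strands) {
    rc <- vapply(kmers, revcomp, character(1), USE.NAMES = FALSE)
    ref_counts <- ref_counts + ref_counts[match(rc, kmers)]
  }
  stopifnot(identical(sort(names(read_counts)), sort(kmers)))
  read_counts <- read_counts[kmers]
  tab <- data.frame(
    kmer = kmers,
    read_count = as.integer(read_counts),
    ref_count = as.integer(ref_counts),
    read_abundance = as.numeric(read_counts) / sum(read_counts),
    ref_abundance = as.numeric(ref_counts) / sum(ref_counts),
    stringsAsFactors = FALSE)
  tab$difference <- tab$read_abundance - tab$ref_abundance
  tab <- tab[order(tab$difference, tab$kmer), ]
  rownames(tab) <- NULL
  under <- tab$kmer[tab$difference < 0 &
                      tab$ref_abundance > tab$read_abundance]
  over_tab <- tab[order(-tab$difference, tab$kmer), ]
  over <- over_tab$kmer[over_tab$difference > 0 &
                          over_tab$read_abundance > over_tab$ref_abundance]
  attr(tab, "under_represented") <- utils::head(under, top)
  attr(tab, "over_represented") <- utils::head(over, top)
  class(tab) <- c("kmer_table", "data.frame")
  tab
}

#' GC content of a set of sequences
#'
#' 100 x (G + C) / (A + C + G + T); other symbols are ignored.
#'
#' @param sequences Character vector or `DNAStringSet`.
#' @return GC percentage.
#' @examples
#' gc_content("GGCC")
#' @export
gc_content <- function(sequences) {
  if (!inherits(sequences, "DNAStringSet")) {
    sequences <- sequences[nzchar(sequences)]
    if (length(sequences) == 0) stop("no bases to compute GC content from")
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  f <- Biostrings::letterFrequency(sequences, c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) stop("no A/C/G/T bases to compute GC content from")
  100 * sum(f[, c("C", "G")]) / tot
}
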