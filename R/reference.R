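#' Generate a random reference sequence
#'
#' Bases are drawn i.i.d. with P(G) + P(C) = `gc`, G and C equiprobable
#' within their class, likewise A and T.
#'
#' @param length Sequence length in bases (>= 1).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Optional integer seed; the caller's RNG stream is left
#'   untouched when a seed is given.
#' @return A character scalar over A/C/G/T.
#' @examples
#' generate_reference(12, 0.5, seed = 1)
#' @export
generate_reference <- function(length, gc = 0.5, seed = NULL) {
  if (!is.numeric(length) || length < 1)
    stop("length must be a positive integer")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  with_seed(seed, {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Build a target + control reference set
#'
#' The target stands in for a sequenced genome (default 50 kb at GC
#' 0.508, the E. coli value); the control stands in for the ~3,555-base
#' lambda-derived 'DNA CS' spike-in. A single known-mutation position is
#' recorded on the control (mirroring its one documented variant); it is
#' carried as metadata only and used by no metric.
#'
#' @param target_length,target_gc Target genome length and GC fraction.
#' @param control_length Control spike-in length.
#' @param control_mutation_pos 0-based position of the control's known
#'   mutation (defaults to the midpoint).
#' @param seed Optional integer seed.
#' @return An object of class `reference_set`: a list with `target_name`,
#'   `target_seq`, `control_name`, `control_seq`, `control_mutation_pos`.
#' @export
reference_set <- function(target_length = 50000, target_gc = 0.508,
                          control_length = 3555,
                          control_mutation_pos = NULL, seed = NULL) {
  if (control_length < 1) stop("control_length must be >= 1")
  with_seed(seed, {
    refs <- list(
      target_name = "sim_target",
      target_seq = generate_reference(target_length, target_gc),
      control_name = "sim_control",
      control_seq = generate_reference(control_length, 0.5),
      control_mutation_pos =
        if (is.null(control_mutation_pos)) control_length %/% 2
        else control_mutation_pos
    )
    class(refs) <- "reference_set"
    refs
  })
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %s (%d bp), %s (%d bp)\n",
              x$target_name, nchar(x$target_seq),
              x$control_name, nchar(x$control_seq)))
  invisible(x)
}

#' Write / read a reference set as FASTA
#'
#' @param refs A `reference_set`.
#' @param path FASTA file path.
#' @return `read_reference_fasta` returns a `reference_set` (the first
#'   record is taken as target, the second as control).
#' @export
write_reference_fasta <- function(refs, path) {
  stopifnot(inherits(refs, "reference_set"))
  ss <- Biostrings::DNAStringSet(c(refs$target_seq, refs$control_seq))
  names(ss) <- c(refs$target_name, refs$control_name)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 2) stop("reference FASTA must hold target and control")
  refs <- list(
    target_name = sub("\\s.*$", "", names(ss)[1]),
    target_seq = as.character(ss[[1]]),
    control_name = sub("\\s.*$", "", names(ss)[2]),
    control_seq = as.character(ss[[2]]),
    control_mutation_pos = NA_integer_
  )
  class(refs) <- "reference_set"
  refs
}
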