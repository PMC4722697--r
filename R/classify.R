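#' Classify one read as target, control or unclassified
#'
#' A read is `target` iff exactly the target reference has at least one
#' significant alignment, `control` symmetrically, and `unclassified`
#' when both or neither reference has a significant hit. Significance is
#' mapping quality at or above `min_mapq` (ground-truth alignments carry
#' mapq 60 and always qualify).
#'
#' @param target_alns,control_alns Data frames of this read's alignments
#'   to the two references (possibly zero-row), with a `mapq` column.
#' @param min_mapq Significance threshold.
#' @return `"target"`, `"control"` or `"unclassified"`.
#' @export
classify_read <- function(target_alns, control_alns, min_mapq = 10) {
  sig <- function(a) !is.null(a) && nrow(a) > 0 && any(a$mapq >= min_mapq)
  t <- sig(target_alns)
  c <- sig(control_alns)
  if (t && !c) "target" else if (c && !t) "control" else "unclassified"
}

#' Classify every 2D read in an alignment set
#'
#' @param aln Alignment data frame ([read_alignments()] output or the
#'   simulator's `truth`), 2D rows are used.
#' @param target_name,control_name Reference names.
#' @param min_mapq Significance threshold (a `mapq` column of 60 is
#'   assumed when absent, as for ground-truth alignments).
#' @param uuids Optional vector of all 2D read uuids; reads with no
#'   alignment at all are then included as `unclassified`.
#' @return An object of class `classification_result`: data frame with
#'   `uuid` and `class`; per-class `counts` and `fractions` attributes.
#' @export
classify_reads <- function(aln, target_name, control_name,
                           min_mapq = 10, uuids = NULL) {
  a <- aln[aln$read_type == "2D", , drop = FALSE]
  if (!"mapq" %in% names(a)) a$mapq <- 60L
  ids <- unique(if (is.null(uuids)) a$uuid else uuids)
  sig <- a[a$mapq >= min_mapq, , drop = FALSE]
  hit_t <- unique(sig$uuid[sig$ref_name == target_name])
  hit_c <- unique(sig$uuid[sig$ref_name == control_name])
  cls <- ifelse(ids %in% hit_t & !(ids %in% hit_c), "target",
         ifelse(ids %in% hit_c & !(ids %in% hit_t), "control",
                "unclassified"))
  res <- data.frame(uuid = ids, class = cls, stringsAsFactors = FALSE)
  counts <- c(target = sum(cls == "target"),
              control = sum(cls == "control"),
              unclassified = sum(cls == "unclassified"))
  attr(res, "counts") <- counts
  attr(res, "fractions") <- if (length(ids)) counts / length(ids) else counts
  class(res) <- c("classification_result", "data.frame")
  res
}

#' Per-bin read production rate by class
#'
#' Reads started per bin, divided by the number of active pores and the
#' bin length in hours, split by classification.
#'
#' @param result A `classification_result`.
#' @param reads Run-log data frame (for start times and pores).
#' @param bin_width Bin width in seconds.
#' @return Data frame: `bin`, `class`, `reads_started`, `active_pores`,
#'   `reads_per_hour_per_pore`.
#' @export
classification_rates <- function(result, reads, bin_width = 900) {
  m <- match(reads$uuid, result$uuid)
  reads$class <- result$class[m]
  reads <- reads[!is.na(reads$class), , drop = FALSE]
  end <- if (nrow(reads)) max(reads$start_time + reads$duration) else 0
  n_bins <- max(1L, ceiling((end + 1e-9) / bin_width))
  ap <- active_pores(reads, bin_width, n_bins)
  bh <- bin_width / 3600
  out <- expand.grid(bin = seq_len(n_bins) - 1L,
                     class = c("target", "control", "unclassified"),
                     stringsAsFactors = FALSE)
  sb <- pmin(floor(reads$start_time / bin_width), n_bins - 1L)
  cnt <- table(factor(sb, levels = 0:(n_bins - 1)),
               factor(reads$class,
                      levels = c("target", "control", "unclassified")))
  out$reads_started <- as.vector(cnt)
  out$active_pores <- ap[out$bin + 1L]
  out$reads_per_hour_per_pore <-
    ifelse(out$active_pores > 0,
           out$reads_started / out$active_pores / bh, 0)
  out
}
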