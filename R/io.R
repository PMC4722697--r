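#' Write reads as FASTQ with structured per-read metadata
#'
#' One FASTQ record per base-called read type. The record name is
#' `<uuid>_<type>`; the comment is a space-separated key=value schema:
#' `run=<id> batch=<n> ch=<n> file=<n> uuid=<hex32> start=<s> dur=<s>
#' events=<n> group=<g1|g2> class=<pass|fail> type=<template|complement|2D>`.
#' Records are written in (uuid, type) input order, so output is
#' deterministic for sorted input.
#'
#' @param run A `sim_run`, or a list with `reads` and `calls` data frames
#'   shaped as in [simulate_run()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_fastq <- function(run, path) {
  reads <- run$reads
  calls <- run$calls
  if (nrow(calls) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  m <- match(calls$uuid, reads$uuid)
  if (anyNA(m)) stop("calls reference uuids missing from the read table")
  extras <- attr(calls, "extra_comments")
  comment <- sprintf(
    "run=%s batch=%d ch=%d file=%d uuid=%s start=%.3f dur=%.3f events=%d group=%s class=%s type=%s",
    reads$experiment[m], reads$batch[m], reads$channel[m],
    reads$file_number[m], calls$uuid, reads$start_time[m],
    reads$duration[m], reads$n_events[m], reads$well_group[m],
    reads$read_class[m], calls$read_type)
  if (!is.null(extras)) comment <- paste(comment, extras)
  lines <- as.vector(rbind(
    paste0("@", calls$uuid, "_", calls$read_type, " ", comment),
    calls$sequence,
    "+",
    calls$quality))
  writeLines(lines, path)
  invisible(path)
}

#' Read FASTQ written with the structured comment schema
#'
#' Round-trips [write_run_fastq()] output: all identity, timing and class
#' fields are recovered; unknown comment keys are preserved in an
#' `extra_comments` attribute on `calls` and re-emitted on write.
#'
#' @param path FASTQ file.
#' @return A list with `reads` and `calls` data frames shaped as in
#'   [simulate_run()] (run-log-only columns such as skip/stay counts are
#'   absent; `callable` is inferred as TRUE for every base-called read).
#' @export
read_run_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0)
    return(list(reads = data.frame(), calls = empty_calls()))
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: line count not a multiple of 4")
  hdr <- lines[seq(1, length(lines), 4)]
  seqs <- lines[seq(2, length(lines), 4)]
  quals <- lines[seq(4, length(lines), 4)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("quality length mismatch in record ", sub("^@", "", hdr[bad[1]]))

  name <- sub("^@(\\S+).*$", "\\1", hdr)
  comment <- sub("^@\\S+\\s*", "", hdr)
  kv <- strsplit(comment, " ", fixed = TRUE)
  known <- c("run", "batch", "ch", "file", "uuid", "start", "dur",
             "events", "group", "class", "type")
  get <- function(pairs, key) {
    hit <- grep(paste0("^", key, "="), pairs, value = TRUE)
    if (length(hit) == 0) NA_character_ else sub("^[^=]+=", "", hit[1])
  }
  fields <- lapply(known, function(k)
    vapply(kv, get, character(1), key = k))
  names(fields) <- known
  extra <- vapply(kv, function(pairs) {
    keep <- pairs[!sub("=.*$", "", pairs) %in% known & nzchar(pairs)]
    paste(keep, collapse = " ")
  }, character(1))

  calls <- data.frame(uuid = fields$uuid, read_type = fields$type,
                      sequence = seqs, quality = quals,
                      stringsAsFactors = FALSE)
  if (any(nzchar(extra))) attr(calls, "extra_comments") <- extra
  first <- !duplicated(fields$uuid)
  reads <- data.frame(
    experiment = fields$run[first],
    batch = as.integer(fields$batch[first]),
    channel = as.integer(fields$ch[first]),
    file_number = as.integer(fields$file[first]),
    uuid = fields$uuid[first],
    start_time = as.numeric(fields$start[first]),
    duration = as.numeric(fields$dur[first]),
    n_events = as.integer(fields$events[first]),
    well_group = fields$group[first],
    read_class = fields$class[first],
    callable = TRUE,
    stringsAsFactors = FALSE
  )
  list(reads = reads, calls = calls, name = name)
}

# ---- SAM ---------------------------------------------------------------

#' Write alignments as SAM (=/X dialect)
#'
#' Emits a minimal plain-text SAM with an @SQ header per reference,
#' CIGAR strings using `=`/`X` (so error decomposition needs no
#' reference lookup), 1-based positions, and custom tags: `ZR:Z:` source
#' reference, `ZK:i:` skip count, `ZY:i:` stay count (when available).
#'
#' @param aln Data frame of alignments: `uuid`, `read_type`, `ref_name`,
#'   `start0` (0-based), `strand`, `script` (native edit script or
#'   =/X/I/D string); optionally `mapq`.
#' @param ref_lengths Named integer vector of reference lengths.
#' @param path Output file.
#' @param calls Optional `calls` data frame supplying SEQ/QUAL.
#' @param reads Optional `reads` data frame supplying skip/stay tags.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, ref_lengths, path, calls = NULL,
                             reads = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  if (nrow(aln) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  qname <- paste0(aln$uuid, "_", aln$read_type)
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  cigar <- vapply(aln$script, ops_to_cigar, character(1), USE.NAMES = FALSE)
  mapq <- if ("mapq" %in% names(aln)) aln$mapq else 60L
  seqf <- "*"; qualf <- "*"
  if (!is.null(calls)) {
    key <- paste(aln$uuid, aln$read_type)
    m <- match(key, paste(calls$uuid, calls$read_type))
    seqf <- ifelse(is.na(m), "*", calls$sequence[m])
    qualf <- ifelse(is.na(m), "*", calls$quality[m])
    seqf[seqf == ""] <- "*"
    qualf[seqf == "*"] <- "*"
  }
  tags <- sprintf("ZR:Z:%s", aln$ref_name)
  if (!is.null(reads)) {
    m <- match(aln$uuid, reads$uuid)
    ok <- !is.na(m)
    tags[ok] <- sprintf("%s\tZK:i:%d\tZY:i:%d", tags[ok],
                        reads$n_skips[m[ok]], reads$n_stays[m[ok]])
  }
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\t%s",
                  qname, flag, aln$ref_name, aln$start0 + 1L, mapq,
                  cigar, seqf, qualf, tags)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SAM alignments
#'
#' Accepts the =/X dialect directly; CIGARs using `M` are resolved to
#' `=`/`X` through the MD tag (required in that case). Positions are
#' converted to 0-based half-open intervals. Unmapped records (CIGAR
#' `*`) are dropped.
#'
#' @param path SAM file.
#' @return A data frame: `uuid`, `read_type`, `ref_name`, `start0`,
#'   `end0`, `strand`, `mapq`, `script` (per-column =/X/I/D string, with
#'   mismatch/insertion base identities where SEQ is present), plus
#'   `ref_lengths` as an attribute.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_lengths <- stats::setNames(
    as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)),
    sub(".*\tSN:(\\S+).*", "\\1", sq))
  if (length(body) == 0) {
    out <- empty_truth()
    out$mapq <- integer(0)
    attr(out, "ref_lengths") <- ref_lengths
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nfield <- vapply(f, length, integer(1))
  if (any(nfield < 11)) stop("malformed SAM record (fewer than 11 fields)")
  qname <- vapply(f, `[[`, character(1), 1)
  flag <- as.integer(vapply(f, `[[`, character(1), 2))
  rname <- vapply(f, `[[`, character(1), 3)
  pos1 <- as.integer(vapply(f, `[[`, character(1), 4))
  mapq <- as.integer(vapply(f, `[[`, character(1), 5))
  cigar <- vapply(f, `[[`, character(1), 6)
  seqs <- vapply(f, `[[`, character(1), 10)
  tags <- lapply(f, function(x) if (length(x) > 11) x[12:length(x)] else character(0))

  keep <- cigar != "*"
  script <- character(sum(keep))
  ki <- which(keep)
  for (j in seq_along(ki)) {
    i <- ki[j]
    ops <- cigar_to_ops(cigar[i])
    if (any(ops == "M")) {
      md <- grep("^MD:Z:", tags[[i]], value = TRUE)
      if (length(md) == 0)
        stop("CIGAR with M but no MD tag for ", qname[i],
             "; use =/X CIGAR or provide MD")
      ops <- resolve_m_ops(ops, sub("^MD:Z:", "", md[1]))
    }
    script[j] <- paste(enrich_script(ops, seqs[i]), collapse = "")
  }
  uuid <- sub("_(template|complement|2D)$", "", qname[keep])
  rtype <- ifelse(grepl("_(template|complement|2D)$", qname[keep]),
                  sub("^.*_(template|complement|2D)$", "\\1", qname[keep]),
                  "2D")
  span <- vapply(script, script_ref_span, numeric(1), USE.NAMES = FALSE)
  src <- vapply(tags[keep], function(tg) {
    zr <- grep("^ZR:Z:", tg, value = TRUE)
    if (length(zr)) sub("^ZR:Z:", "", zr[1]) else NA_character_
  }, character(1))
  out <- data.frame(
    uuid = uuid, read_type = rtype, ref_name = rname[keep],
    start0 = pos1[keep] - 1L, end0 = pos1[keep] - 1L + as.integer(span),
    strand = ifelse(bitwAnd(flag[keep], 16L) > 0, "-", "+"),
    mapq = mapq[keep], script = script, source_ref = src,
    stringsAsFactors = FALSE)
  attr(out, "ref_lengths") <- ref_lengths
  out
}

# Replace M columns by = or X using the MD tag
resolve_m_ops <- function(ops, md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  states <- character(0)  # per M/D reference column: "=", "X" or "D"
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) {
      states <- c(states, rep("=", as.integer(tk)))
    } else if (startsWith(tk, "^")) {
      states <- c(states, rep("D", nchar(tk) - 1))
    } else {
      states <- c(states, "X")
    }
  }
  mstates <- states[states != "D"]
  out <- ops
  out[ops == "M"] <- mstates[seq_len(sum(ops == "M"))]
  out
}

# attach base identities (lowercase mismatch, uppercase insertion) to ops
enrich_script <- function(ops, seq) {
  if (seq == "*" || !nzchar(seq)) return(ops)
  readv <- strsplit(seq, "", fixed = TRUE)[[1]]
  read_cols <- ops %in% c("=", "X", "I", "M")
  if (sum(read_cols) != length(readv)) return(ops)  # clipped; keep plain ops
  base_at <- character(length(ops))
  base_at[read_cols] <- readv
  ops[ops == "X"] <- tolower(base_at[ops == "X"])
  ops[ops == "I"] <- toupper(base_at[ops == "I"])
  ops
}

# ---- run log -----------------------------------------------------------

#' Write / read the run log TSV
#'
#' One row per read (including non-callable reads), in read start order.
#' Columns are those of the `reads` data frame of [simulate_run()].
#'
#' @param reads Run-log data frame.
#' @param path TSV file.
#' @return `read_run_log` returns the data frame.
#' @export
write_run_log <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_run_log
#' @export
read_run_log <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(uuid = "character"))
}
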