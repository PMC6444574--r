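# Read preprocessing: adapter trimming, quality and length filtering, tag
# collapsing. All operations are vectorised over whole read tibbles; the
# adapter scans work on a padded character matrix so per-read loops are
# avoided.

# Character matrix of reads padded with " " (a sentinel that never matches
# a DNA base).
read_char_matrix <- function(seqs, width) {
  padded <- formatC(seqs, width = -width, flag = "-")
  matrix(unlist(strsplit(padded, ""), use.names = FALSE),
    nrow = length(seqs), ncol = width, byrow = TRUE
  )
}

#' Trim the 3' sequencing adapter
#'
#' Scans each read for the leftmost position at which a prefix of the
#' adapter matches the read suffix, with overlap at least `min_overlap`
#' and mismatch fraction at most `max_mismatch_rate`; everything from that
#' position on is removed. Reads in which no 3' adapter is found are
#' flagged (`adapter_found = FALSE`): for 16-40 nt inserts on standard
#' read lengths the adapter must be read through, so such reads are
#' discarded downstream. The leftmost qualifying position wins, keeping
#' the shortest insert - the conservative anti-chimera choice.
#'
#' @param reads Tibble with `read_id`, `sequence`, `qualities`.
#' @param adapter 3' adapter sequence.
#' @param min_overlap Minimum read/adapter overlap in nt (default 6).
#' @param max_mismatch_rate Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @return `reads` with `sequence`/`qualities` trimmed and a logical
#'   `adapter_found` column.
#' @export
trim_adapter_3p <- function(reads, adapter, min_overlap = 6L, max_mismatch_rate = 0.1) {
  stopifnot(nchar(adapter) >= 1, min_overlap >= 1)
  n <- nrow(reads)
  if (n == 0) {
    return(mutate(reads, adapter_found = logical(0)))
  }
  rlen <- nchar(reads$sequence)
  width <- max(rlen)
  alen <- nchar(adapter)
  M <- read_char_matrix(reads$sequence, width)
  a <- strsplit(adapter, "")[[1]]
  # mism[r, i]: mismatches of adapter[1..] laid on read r starting at i
  # (sentinel padding counted as mismatch, corrected below)
  mism <- matrix(0L, n, width)
  for (j in seq_len(min(alen, width))) {
    cols <- seq_len(width - j + 1L)
    mism[, cols] <- mism[, cols] + (M[, cols + j - 1L, drop = FALSE] != a[j])
  }
  starts <- matrix(seq_len(width), n, width, byrow = TRUE)
  ov <- pmin(rlen - starts + 1L, alen)
  pad <- pmax(0L, pmin(starts + alen - 1L, width) - rlen)
  qualifies <- ov >= min_overlap & (mism - pad) <= max_mismatch_rate * ov + 1e-9
  found <- rowSums(qualifies) > 0
  pos <- max.col(qualifies, ties.method = "first")
  insert_len <- ifelse(found, pos - 1L, rlen)
  mutate(reads,
    sequence = substr(.data$sequence, 1L, insert_len),
    qualities = substr(.data$qualities, 1L, insert_len),
    adapter_found = found
  )
}

#' Trim a 5' adapter remnant
#'
#' Removes the longest prefix of the adapter (at least `min_overlap` nt,
#' mismatch fraction at most `max_mismatch_rate`) found at the start of the
#' read. Reads without a 5' adapter are kept unmodified - 5' adapter
#' read-through is protocol-dependent and optional.
#'
#' @inheritParams trim_adapter_3p
#' @param adapter 5' adapter sequence.
#' @return `reads` with any leading adapter removed.
#' @export
trim_adapter_5p <- function(reads, adapter, min_overlap = 6L, max_mismatch_rate = 0.1) {
  stopifnot(nchar(adapter) >= 1, min_overlap >= 1)
  n <- nrow(reads)
  if (n == 0) {
    return(reads)
  }
  rlen <- nchar(reads$sequence)
  width <- max(rlen)
  alen <- nchar(adapter)
  M <- read_char_matrix(reads$sequence, width)
  a <- strsplit(adapter, "")[[1]]
  best <- integer(n)
  cum <- integer(n)
  for (o in seq_len(min(alen, width))) {
    cum <- cum + (M[, o] != a[o])
    ok <- o >= min_overlap & o <= rlen & cum <= max_mismatch_rate * o + 1e-9
    best[ok] <- o
  }
  mutate(reads,
    sequence = substr(.data$sequence, best + 1L, rlen),
    qualities = substr(.data$qualities, best + 1L, rlen)
  )
}

#' Filter reads on base quality
#'
#' A read is kept iff its mean Phred score is at least `min_mean_q`, no
#' base is below `min_base_q`, and the sequence contains no N. These
#' operationalise "high quality"; all three are configurable. Zero-length
#' reads carry no quality evidence and pass through (the length filter
#' judges them).
#'
#' @inheritParams trim_adapter_3p
#' @param min_mean_q Minimum mean Phred score (default 20).
#' @param min_base_q Minimum per-base Phred score (default 5).
#' @return The kept rows of `reads`; the number dropped is in attribute
#'   `n_dropped`.
#' @export
quality_filter <- function(reads, min_mean_q = 20, min_base_q = 5) {
  n <- nrow(reads)
  lens <- nchar(reads$qualities)
  grp <- rep.int(seq_len(n), lens)
  q <- utf8ToInt(paste(reads$qualities, collapse = "")) - 33L
  mean_q <- rep(NA_real_, n)
  n_low <- integer(n)
  if (length(q) > 0) {
    sums <- rowsum(q, grp)
    present <- as.integer(rownames(sums))
    mean_q[present] <- sums[, 1] / lens[present]
    n_low[present] <- rowsum(as.integer(q < min_base_q), grp)[, 1]
  }
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  keep <- (is.na(mean_q) | (mean_q >= min_mean_q & n_low == 0L)) & !has_n
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Filter inserts on length
#'
#' Keeps sequences whose length lies in `[min_len, max_len]`, bounds
#' inclusive (default 16-40 nt).
#'
#' @inheritParams trim_adapter_3p
#' @param min_len,max_len Inclusive length bounds in nt.
#' @return The kept rows; dropped count in attribute `n_dropped`.
#' @export
length_filter <- function(reads, min_len = 16L, max_len = 40L) {
  lens <- nchar(reads$sequence)
  keep <- lens >= min_len & lens <= max_len
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Collapse identical inserts into counted sequence tags
#'
#' @param reads Tibble with a `sequence` column (retained inserts).
#' @return Tibble `tag_sequence`, `count`, sorted by decreasing count then
#'   sequence; `sum(count)` equals `nrow(reads)`.
#' @export
collapse_tags <- function(reads) {
  if (nrow(reads) == 0) {
    return(tibble(tag_sequence = character(0), count = integer(0)))
  }
  reads |>
    count(tag_sequence = .data$sequence, name = "count") |>
    arrange(dplyr::desc(.data$count), .data$tag_sequence)
}

#' Preprocess a raw small-RNA library
#'
#' Runs the full preprocessing chain: 3' adapter trimming (reads without a
#' 3' adapter are discarded), optional 5' adapter trimming, quality
#' filtering, 16-40 nt length selection and tag collapsing. The report
#' satisfies the conservation equation
#' `reads_in == discarded_no_adapter + discarded_quality +
#' discarded_length + sum(tag counts)`.
#'
#' @inheritParams trim_adapter_3p
#' @inheritParams quality_filter
#' @inheritParams length_filter
#' @param adapter_5p Optional 5' adapter; `NULL` skips 5' trimming.
#' @return A list of class `tsrna_preprocess` with `tags` (tibble
#'   `tag_sequence`, `count`) and `report` (one-row tibble of conservation
#'   counts).
#' @export
preprocess_reads <- function(reads, adapter_3p, adapter_5p = NULL,
                             min_overlap = 6L, max_mismatch_rate = 0.1,
                             min_mean_q = 20, min_base_q = 5,
                             min_len = 16L, max_len = 40L) {
  n_in <- nrow(reads)
  trimmed <- trim_adapter_3p(reads, adapter_3p, min_overlap, max_mismatch_rate)
  n_no_adapter <- sum(!trimmed$adapter_found)
  trimmed <- filter(trimmed, .data$adapter_found)
  if (!is.null(adapter_5p)) {
    trimmed <- trim_adapter_5p(trimmed, adapter_5p, min_overlap, max_mismatch_rate)
  }
  qf <- quality_filter(trimmed, min_mean_q, min_base_q)
  n_quality <- attr(qf, "n_dropped")
  lf <- length_filter(qf, min_len, max_len)
  n_length <- attr(lf, "n_dropped")
  tags <- collapse_tags(lf)
  report <- tibble(
    reads_in = n_in,
    discarded_no_adapter = n_no_adapter,
    discarded_quality = n_quality,
    discarded_length = n_length,
    reads_retained = sum(tags$count)
  )
  stopifnot(
    report$reads_in == report$discarded_no_adapter + report$discarded_quality +
      report$discarded_length + report$reads_retained
  )
  structure(list(tags = tags, report = report), class = "tsrna_preprocess")
}

#' @export
print.tsrna_preprocess <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<tsrna_preprocess> %d reads in; %d retained as %d tags (no-adapter %d, quality %d, length %d)\n",
    r$reads_in, r$reads_retained, nrow(x$tags),
    r$discarded_no_adapter, r$discarded_quality, r$discarded_length
  ))
  invisible(x)
}
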