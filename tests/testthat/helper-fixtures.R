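# Fixture builders and independent oracles used across test files.
# Oracles are deliberately naive (loops, full scans) and share no code with
# the implementation paths they check.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# One-row tRNA gene tibble with sensible defaults.
toy_gene <- function(gene_id = "g1", gene_sequence = NULL, introns = NULL,
                     amino_acid = "Gly", anticodon = "GCC",
                     anticodon_start = NA_integer_, chrom = "chr1",
                     start = 100L, strand = "+") {
  if (is.null(gene_sequence)) {
    set.seed(1)
    gene_sequence <- paste(sample(c("A", "C", "G", "T"), 72, replace = TRUE),
      collapse = ""
    )
  }
  if (is.null(introns)) introns <- matrix(integer(0), ncol = 2)
  tibble(
    gene_id = gene_id, chrom = chrom, start = start,
    end = start + nchar(gene_sequence), strand = strand,
    amino_acid = amino_acid, anticodon = anticodon,
    anticodon_start = anticodon_start,
    introns = list(introns), gene_sequence = gene_sequence
  )
}

# A 75 nt mature tRNA with a known anticodon interval, plus its reference
# container, for classification tests.
toy_mature_reference <- function(seed = 42, n = 1) {
  set.seed(seed)
  matures <- lapply(seq_len(n), function(i) {
    seq <- paste(sample(c("A", "C", "G", "T"), 72, replace = TRUE), collapse = "")
    tibble(
      mature_id = sprintf("tRNA-GlyGCC-%d", i),
      isoacceptor = "GlyGCC",
      sequence = paste0(seq, "CCA"),
      anticodon_start = 33L, anticodon_end = 36L,
      source_gene_ids = list(sprintf("g%d", i))
    )
  })
  structure(
    list(
      matures = bind_rows(matures),
      precursors = tibble(
        precursor_id = character(0), isoacceptor = character(0),
        sequence = character(0), leader_len = integer(0),
        trailer_len = integer(0), mature3_boundary = integer(0)
      ),
      collapse_map = tibble(gene_id = character(0), mature_id = character(0)),
      genes = tibble(), params = list()
    ),
    class = "trna_reference"
  )
}

# Brute-force ungapped aligner: scans every offset of every reference and
# applies the per-class best-stratum rule.
brute_align <- function(tag, references, max_mismatches = 1L) {
  L <- nchar(tag)
  tag_chars <- strsplit(tag, "")[[1]]
  hits <- list()
  for (i in seq_len(nrow(references))) {
    s <- references$sequence[i]
    n <- nchar(s)
    if (n < L) next
    for (start0 in 0:(n - L)) {
      win <- strsplit(substr(s, start0 + 1, start0 + L), "")[[1]]
      mm <- sum(win != tag_chars)
      if (mm <= max_mismatches) {
        hits[[length(hits) + 1]] <- tibble(
          tag_sequence = tag,
          ref_id = references$ref_id[i],
          rna_class = references$rna_class[i],
          ref_start = start0, ref_end = start0 + L,
          mismatches = mm
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble(
      tag_sequence = character(0), ref_id = character(0),
      rna_class = character(0), ref_start = integer(0),
      ref_end = integer(0), mismatches = integer(0)
    ))
  }
  bind_rows(hits) |>
    group_by(rna_class) |>
    filter(!any(mismatches == 0) | mismatches == 0) |>
    ungroup() |>
    arrange(rna_class, ref_id, ref_start)
}

# Literal transcription of the positional classification rules for one
# fragment of a mature tRNA, independent of the vectorised implementation.
brute_classify_position <- function(ref_start, ref_end, mature_len,
                                    delta5 = 1, delta3 = 2) {
  at5 <- ref_start <= delta5
  at3 <- ref_end >= mature_len - delta3
  if (at5 && at3) {
    return("unclassified")
  }
  if (at5) {
    return("tRNA-5")
  }
  if (at3) {
    return("tRNA-3")
  }
  "tRNA-i"
}

# Literal transcription of the tRF/tRH rule.
brute_subtype <- function(ref_start, ref_end, ts_class, ac_start, ac_end,
                          half_min_len = 28, window = 2) {
  if (!ts_class %in% c("tRNA-5", "tRNA-3")) {
    return(NA_character_)
  }
  bp <- if (ts_class == "tRNA-5") ref_end else ref_start
  long_enough <- (ref_end - ref_start) >= half_min_len
  in_loop <- bp >= ac_start - window && bp <= ac_end + window
  if (long_enough && in_loop) "tRH" else "tRF"
}

# Naive quadratic Benjamini-Hochberg step-up.
brute_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i] - 1e-15)
    min(1, min(vapply(js, function(j) {
      rank_j <- sum(p <= p[j] + 1e-15)
      p[j] * m / rank_j
    }, numeric(1))))
  }, numeric(1))
}

# Brute-force leftmost 3' adapter scan for one read.
brute_trim_3p <- function(seq, adapter, min_overlap = 6, max_mismatch_rate = 0.1) {
  rlen <- nchar(seq)
  alen <- nchar(adapter)
  for (i in seq_len(rlen)) {
    ov <- min(rlen - i + 1, alen)
    if (ov < min_overlap) next
    a <- strsplit(substr(adapter, 1, ov), "")[[1]]
    w <- strsplit(substr(seq, i, i + ov - 1), "")[[1]]
    if (sum(a != w) <= max_mismatch_rate * ov + 1e-9) {
      return(list(insert = substr(seq, 1, i - 1), found = TRUE))
    }
  }
  list(insert = seq, found = FALSE)
}

# Fixed-quality read tibble from sequences.
reads_from_seqs <- function(seqs, q = "F") {
  tibble(
    read_id = sprintf("r%04d", seq_along(seqs)),
    sequence = seqs,
    qualities = strrep(q, nchar(seqs))
  )
}

# Shared small simulation refs (built once per test run).
shared_refs <- local({
  refs <- NULL
  function() {
    if (is.null(refs)) refs <<- make_toy_references(12, seed = 7)
    refs
  }
})
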