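# File-format adapters: FASTA, FASTQ (.gz tolerated), BED-like tRNA
# annotation, sample sheets, count tables, SAM export.

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read FASTQ into a read tibble
#'
#' Plain or gzip-compressed FASTQ. Records are validated as they are
#' parsed; a malformed record (missing `@`/`+` marker, or a sequence/quality
#' length mismatch) is rejected with the 1-based line number at which it
#' occurs.
#'
#' @param path FASTQ(.gz) file.
#' @return Tibble with `read_id`, `sequence`, `qualities` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4 != 0) {
    abort_msg("%s: truncated FASTQ, %d lines is not a multiple of 4", path, n)
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr) > 0) {
    abort_msg("%s: line %d: expected '@' record header", path, idx[bad_hdr[1]])
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0) {
    abort_msg("%s: line %d: expected '+' separator", path, idx[bad_plus[1]] + 2L)
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len) > 0) {
    abort_msg(
      "%s: line %d: sequence and quality lengths differ",
      path, idx[bad_len[1]] + 3L
    )
  }
  tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", hdr)),
    sequence = toupper(seqs),
    qualities = qual
  )
}

#' Write a read tibble as FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence`, `qualities`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$qualities)))
  rec <- paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n", reads$qualities)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Read a BED-like tRNA gene annotation
#'
#' Tab-separated, one gene per line, columns:
#' `chrom, start, end, name, score, strand, introns, anticodon_start`.
#' `name` must carry an amino-acid/anticodon token such as
#' `tRNA-Gly-GCC-1-1`; `introns` is a comma-separated list of gene-local
#' half-open `s-e` intervals or `.`; `anticodon_start` is the gene-local
#' 0-based offset of the anticodon in the unspliced sense sequence, or `.`.
#' Gene sequences are extracted (and strand-corrected) from `genome`.
#'
#' @param path Annotation TSV.
#' @param genome Named character vector or [Biostrings::DNAStringSet].
#' @return A tRNA gene tibble suitable for [build_trna_reference()].
#' @export
read_trna_annotation <- function(path, genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  ann <- readr::read_tsv(
    path,
    col_names = c(
      "chrom", "start", "end", "name", "score", "strand",
      "introns", "anticodon_start"
    ),
    col_types = "ciicdccc", comment = "#", progress = FALSE
  )
  token <- stringr::str_match(ann$name, "tRNA-([A-Za-z]{3}|SeC|iMet|Und)-?([ACGT]{3})")
  if (anyNA(token[, 1])) {
    bad <- which(is.na(token[, 1]))[1]
    abort_msg("%s: gene name %s lacks an amino-acid/anticodon token", path, ann$name[bad])
  }
  introns <- lapply(ann$introns, function(s) {
    if (is.na(s) || s %in% c(".", "")) {
      return(matrix(integer(0), ncol = 2))
    }
    parts <- strsplit(strsplit(s, ",")[[1]], "-")
    m <- do.call(rbind, lapply(parts, function(p) as.integer(p)))
    m
  })
  seqs <- vapply(seq_len(nrow(ann)), function(i) {
    contig <- genome[[ann$chrom[i]]]
    if (is.null(contig)) abort_msg("%s: contig %s not in genome", path, ann$chrom[i])
    s <- substr(contig, ann$start[i] + 1L, ann$end[i])
    if (ann$strand[i] == "-") revcomp(s) else s
  }, character(1))
  tibble(
    gene_id = ann$name,
    chrom = ann$chrom,
    start = ann$start,
    end = ann$end,
    strand = ann$strand,
    amino_acid = token[, 2],
    anticodon = token[, 3],
    anticodon_start = suppressWarnings(as.integer(ann$anticodon_start)),
    introns = introns,
    gene_sequence = seqs
  )
}

#' Write a tRNA gene table in the BED-like annotation dialect
#'
#' Inverse of [read_trna_annotation()] (sequence column is re-derived from
#' the genome on read).
#'
#' @inheritParams validate_trna_genes
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trna_annotation <- function(genes, path) {
  introns <- vapply(genes$introns, function(m) {
    if (is.null(m) || nrow(m) == 0) {
      "."
    } else {
      paste(paste0(m[, 1], "-", m[, 2]), collapse = ",")
    }
  }, character(1))
  out <- tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$gene_id, score = 0, strand = genes$strand,
    introns = introns,
    anticodon_start = ifelse(is.na(genes$anticodon_start), ".",
      as.character(genes$anticodon_start)
    )
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `fastq_path`, `group`.
#'
#' @param path Sample sheet TSV.
#' @return Tibble with those three character columns.
#' @export
read_sample_sheet <- function(path) {
  ss <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  needed <- c("sample_id", "fastq_path", "group")
  if (!all(needed %in% names(ss))) {
    abort_msg(
      "%s: sample sheet must have columns %s",
      path, paste(needed, collapse = ", ")
    )
  }
  if (anyDuplicated(ss$sample_id)) {
    abort_msg("%s: duplicate sample_id in sample sheet", path)
  }
  ss
}

#' Export tag alignments as SAM
#'
#' Ungapped, full-length alignments written with a `<len>M` CIGAR and an
#' `NM` tag carrying the mismatch count, for inspection in standard
#' viewers. The header `@SQ` lines carry the reference lengths.
#'
#' @param alignments Alignment tibble (`tag_sequence`, `ref_id`,
#'   `ref_start`, `ref_end`, `mismatches`).
#' @param references Reference tibble with `ref_id` and `sequence`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_tag_sam <- function(alignments, references, path) {
  refs_used <- references |> filter(.data$ref_id %in% alignments$ref_id)
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", refs_used$ref_id, nchar(refs_used$sequence))
  )
  body <- sprintf(
    "%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
    paste0("tag_", seq_len(nrow(alignments))),
    alignments$ref_id,
    alignments$ref_start + 1L,
    nchar(alignments$tag_sequence),
    alignments$tag_sequence,
    alignments$mismatches
  )
  writeLines(c(header, body), path)
  invisible(path)
}
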