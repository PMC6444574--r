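# Mature and precursor tRNA reference construction.
#
# Coordinate conventions (used package-wide):
#   * all intervals are 0-based, half-open;
#   * gene-local coordinates run 5'->3' along the SENSE strand of the gene,
#     so minus-strand genes are handled once, at sequence extraction;
#   * mature coordinates include the appended CCA, so the mature 3' end is
#     len(sequence).

#' Validate a tRNA gene table
#'
#' Checks the structural invariants of a tRNA gene annotation table:
#' coordinates ordered, sequence length equal to the genomic span, and
#' intron intervals disjoint, sorted and strictly inside the gene body.
#'
#' @param genes A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `amino_acid`, `anticodon`, `anticodon_start` (gene-local
#'   0-based offset of the anticodon in the unspliced sense sequence, `NA`
#'   if unannotated), `introns` (list-column of two-column matrices of
#'   gene-local half-open intervals) and `gene_sequence` (sense strand).
#' @return `genes`, invisibly, if all invariants hold; otherwise an error
#'   naming the offending gene.
#' @export
validate_trna_genes <- function(genes) {
  needed <- c(
    "gene_id", "chrom", "start", "end", "strand", "amino_acid",
    "anticodon", "anticodon_start", "introns", "gene_sequence"
  )
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols) > 0) {
    abort_msg("gene table lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$start >= g$end) {
      abort_msg("gene %s: start must be < end", g$gene_id)
    }
    if (nchar(g$gene_sequence) != g$end - g$start) {
      abort_msg("gene %s: sequence length != end - start", g$gene_id)
    }
    check_introns(g$introns[[1]], nchar(g$gene_sequence), g$gene_id)
  }
  invisible(genes)
}

check_introns <- function(introns, gene_len, gene_id) {
  if (is.null(introns) || nrow(introns) == 0) {
    return(invisible(NULL))
  }
  if (ncol(introns) != 2) {
    abort_msg("gene %s: introns must be a two-column matrix", gene_id)
  }
  s <- introns[, 1]
  e <- introns[, 2]
  if (any(s >= e)) {
    abort_msg("gene %s: empty or inverted intron interval", gene_id)
  }
  if (any(s <= 0) || any(e >= gene_len)) {
    abort_msg("gene %s: intron outside the open gene body (0, %d)", gene_id, gene_len)
  }
  if (is.unsorted(s, strictly = TRUE)) {
    abort_msg("gene %s: introns must be sorted", gene_id)
  }
  if (any(s[-1] < e[-length(e)])) {
    abort_msg("gene %s: overlapping introns", gene_id)
  }
  invisible(NULL)
}

#' Excise introns from tRNA gene sequences
#'
#' Removes each gene's annotated intron intervals from its sense-strand
#' sequence, preserving exon order.
#'
#' @inheritParams validate_trna_genes
#' @return Character vector of spliced sequences, one per gene row.
#' @export
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = "g1", chrom = "chr1", start = 0L, end = 9L, strand = "+",
#'   amino_acid = "Gly", anticodon = "GCC", anticodon_start = NA_integer_,
#'   introns = list(cbind(3L, 6L)), gene_sequence = "AAACCCGGG"
#' )
#' splice_introns(genes)  # "AAAGGG"
splice_introns <- function(genes) {
  vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    introns <- g$introns[[1]]
    seq <- g$gene_sequence
    check_introns(introns, nchar(seq), g$gene_id)
    if (is.null(introns) || nrow(introns) == 0) {
      return(seq)
    }
    keep_start <- c(0L, introns[, 2])
    keep_end <- c(introns[, 1], nchar(seq))
    paste(substring(seq, keep_start + 1L, keep_end), collapse = "")
  }, character(1))
}

# Map a gene-local (unspliced) offset into spliced coordinates; NA if the
# position falls inside an intron.
splice_offset <- function(pos, introns) {
  if (is.null(introns) || nrow(introns) == 0) {
    return(pos)
  }
  if (any(pos >= introns[, 1] & pos < introns[, 2])) {
    return(NA_integer_)
  }
  removed <- sum(pmax(0L, pmin(pos, introns[, 2]) - introns[, 1]))
  as.integer(pos - removed)
}

#' Build mature tRNA sequences
#'
#' Splices each gene and appends the non-templated 3' CCA added during tRNA
#' maturation. The anticodon interval is recomputed into mature coordinates;
#' genes without an annotated anticodon position fall back to the canonical
#' location, mature positions (33, 36).
#'
#' @inheritParams validate_trna_genes
#' @return A tibble with one row per gene: `gene_id`, `mature_id`
#'   (`tRNA-<AA><Anticodon>` plus a copy suffix), `isoacceptor`, `sequence`
#'   (ending in CCA), `anticodon_start`, `anticodon_end` (mature
#'   coordinates).
#' @export
build_mature <- function(genes) {
  spliced <- splice_introns(genes)
  ac_start <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (is.na(g$anticodon_start)) {
      ac_start[i] <- 33L
    } else {
      ac_start[i] <- splice_offset(g$anticodon_start, g$introns[[1]])
      if (is.na(ac_start[i])) {
        abort_msg("gene %s: anticodon locus falls inside an intron", g$gene_id)
      }
    }
    found <- substr(spliced[i], ac_start[i] + 1L, ac_start[i] + 3L)
    if (!is.na(g$anticodon_start) && !identical(found, g$anticodon)) {
      abort_msg(
        "gene %s: anticodon %s not found at annotated locus (saw %s)",
        g$gene_id, g$anticodon, found
      )
    }
  }
  iso <- paste0(genes$amino_acid, genes$anticodon)
  base_id <- paste0("tRNA-", iso)
  copy <- stats::ave(seq_along(base_id), base_id, FUN = seq_along)
  tibble(
    gene_id = genes$gene_id,
    mature_id = paste0(base_id, "-", copy),
    isoacceptor = iso,
    sequence = paste0(spliced, "CCA"),
    anticodon_start = ac_start,
    anticodon_end = ac_start + 3L
  )
}

#' Build precursor tRNA sequences
#'
#' Assembles, in sense orientation, a 5' leader, the unspliced gene body and
#' a 3' trailer for each gene. The trailer carries the genomic poly-T tract
#' (transcribed poly-U) that precursor-derived 3'U tRFs end in. Flanks are
#' truncated at contig edges and the realised lengths recorded.
#'
#' @inheritParams validate_trna_genes
#' @param genome Named character vector (or [Biostrings::DNAStringSet]) of
#'   contig sequences, plus strand.
#' @param leader_len,trailer_len Requested flank lengths in nt (default 50).
#' @return A tibble: `gene_id`, `precursor_id`, `isoacceptor`, `sequence`,
#'   `leader_len`, `trailer_len`, `mature3_boundary` (offset of the first
#'   trailer base, i.e. where the mature 3' end sits before CCA addition).
#' @export
build_precursor <- function(genes, genome, leader_len = 50L, trailer_len = 50L) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    contig <- genome[[g$chrom]]
    if (is.null(contig)) abort_msg("gene %s: contig %s not in genome", g$gene_id, g$chrom)
    clen <- nchar(contig)
    if (g$strand == "+") {
      lead_n <- min(leader_len, g$start)
      trail_n <- min(trailer_len, clen - g$end)
      leader <- substr(contig, g$start - lead_n + 1L, g$start)
      trailer <- substr(contig, g$end + 1L, g$end + trail_n)
    } else {
      # sense 5' leader lies genomically downstream of `end`
      lead_n <- min(leader_len, clen - g$end)
      trail_n <- min(trailer_len, g$start)
      leader <- revcomp(substr(contig, g$end + 1L, g$end + lead_n))
      trailer <- revcomp(substr(contig, g$start - trail_n + 1L, g$start))
    }
    body_len <- g$end - g$start
    tibble(
      gene_id = g$gene_id,
      precursor_id = paste0("pre-", g$gene_id),
      isoacceptor = paste0(g$amino_acid, g$anticodon),
      sequence = paste0(leader, g$gene_sequence, trailer),
      leader_len = as.integer(lead_n),
      trailer_len = as.integer(trail_n),
      mature3_boundary = as.integer(lead_n + body_len)
    )
  })
  bind_rows(rows)
}

#' Collapse identical mature tRNA sequences
#'
#' Multicopy tRNA genes often produce byte-identical mature sequences;
#' collapsing them to one representative prevents spurious multi-mapping.
#' The representative and its id are chosen canonically (sorted by
#' isoacceptor label, then sequence), so the result is independent of input
#' order.
#'
#' @param matures Output of [build_mature()].
#' @return A list with `matures` (one row per distinct sequence, with
#'   `source_gene_ids` list-column) and `collapse_map` (tibble `gene_id` ->
#'   `mature_id`, total over the input genes).
#' @export
collapse_identical <- function(matures) {
  m <- matures |>
    arrange(.data$isoacceptor, .data$sequence) |>
    group_by(.data$isoacceptor, .data$sequence) |>
    summarise(
      anticodon_start = .data$anticodon_start[1],
      anticodon_end = .data$anticodon_end[1],
      source_gene_ids = list(.data$gene_id),
      .groups = "drop"
    ) |>
    group_by(.data$isoacceptor) |>
    mutate(mature_id = paste0("tRNA-", .data$isoacceptor, "-", dplyr::row_number())) |>
    ungroup() |>
    select(
      "mature_id", "isoacceptor", "sequence",
      "anticodon_start", "anticodon_end", "source_gene_ids"
    )
  collapse_map <- m |>
    select("mature_id", "source_gene_ids") |>
    tidyr::unnest_longer("source_gene_ids", values_to = "gene_id") |>
    select("gene_id", "mature_id") |>
    arrange(.data$gene_id)
  list(matures = m, collapse_map = collapse_map)
}

#' Build a complete tRNA reference set
#'
#' Runs validation, mature construction with CCA addition, identity
#' collapsing and precursor assembly in one call.
#'
#' @inheritParams build_precursor
#' @return An object of class `trna_reference`: a list with `matures`
#'   (collapsed), `precursors`, `collapse_map`, `genes` and `params`.
#' @export
build_trna_reference <- function(genes, genome, leader_len = 50L, trailer_len = 50L) {
  validate_trna_genes(genes)
  collapsed <- collapse_identical(build_mature(genes))
  precursors <- build_precursor(genes, genome, leader_len, trailer_len)
  structure(
    list(
      matures = collapsed$matures,
      precursors = precursors,
      collapse_map = collapsed$collapse_map,
      genes = genes,
      params = list(leader_len = leader_len, trailer_len = trailer_len)
    ),
    class = "trna_reference"
  )
}

#' @export
print.trna_reference <- function(x, ...) {
  cat(sprintf(
    "<trna_reference> %d genes -> %d collapsed matures, %d precursors\n",
    nrow(x$genes), nrow(x$matures), nrow(x$precursors)
  ))
  invisible(x)
}

#' Write a tRNA reference set to disk
#'
#' Emits `mature.fa`, `precursor.fa` and `collapse_map.tsv` into `dir`.
#'
#' @param ref A `trna_reference`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trna_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(
    setNames(ref$matures$sequence, ref$matures$mature_id),
    file.path(dir, "mature.fa")
  )
  write_fasta(
    setNames(ref$precursors$sequence, ref$precursors$precursor_id),
    file.path(dir, "precursor.fa")
  )
  readr::write_tsv(ref$collapse_map, file.path(dir, "collapse_map.tsv"))
  invisible(dir)
}
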