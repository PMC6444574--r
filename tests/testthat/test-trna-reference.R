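test_that("intron excision preserves exon order and flags bad annotations", {
  g <- toy_gene(gene_sequence = "AAACCCGGG")
  expect_equal(splice_introns(g), "AAACCCGGG")

  g2 <- toy_gene(gene_sequence = "AAACCCGGG", introns = cbind(3L, 6L))
  expect_equal(splice_introns(g2), "AAAGGG")

  set.seed(9)
  body <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  g3 <- toy_gene(gene_sequence = body, introns = cbind(37L, 52L))
  expect_equal(
    splice_introns(g3),
    paste0(substr(body, 1, 37), substr(body, 53, 90))
  )
  expect_equal(nchar(splice_introns(g3)), 75L)

  overlapping <- toy_gene(
    gene_id = "bad1", gene_sequence = body,
    introns = rbind(c(10L, 20L), c(15L, 25L))
  )
  expect_error(splice_introns(overlapping), "bad1")
  outside <- toy_gene(
    gene_id = "bad2", gene_sequence = "AAACCCGGG",
    introns = cbind(3L, 9L)
  )
  expect_error(splice_introns(outside), "bad2")
})

test_that("mature construction appends CCA and maps the anticodon", {
  set.seed(2)
  body <- paste(
    c(
      sample(c("A", "C", "G", "T"), 33, replace = TRUE), "G", "C", "C",
      sample(c("A", "C", "G", "T"), 36, replace = TRUE)
    ),
    collapse = ""
  )
  g <- toy_gene(gene_sequence = body, anticodon_start = 33L)
  m <- build_mature(g)
  expect_equal(nchar(m$sequence), 75L)
  expect_true(endsWith(m$sequence, "CCA"))
  expect_equal(m$anticodon_start, 33L)
  expect_equal(m$anticodon_end, 36L)
  expect_equal(substr(m$sequence, 34, 36), "GCC")
  expect_match(m$mature_id, "^tRNA-GlyGCC-1$")

  # a 10 nt intron after the anticodon: body 82 -> mature 75
  body_i <- paste0(substr(body, 1, 40), strrep("A", 10), substr(body, 41, 72))
  gi <- toy_gene(
    gene_sequence = body_i, introns = cbind(40L, 50L),
    anticodon_start = 33L
  )
  mi <- build_mature(gi)
  expect_equal(nchar(mi$sequence), 82L - 10L + 3L)
  expect_equal(substr(mi$sequence, 34, 36), "GCC")

  # unannotated anticodon falls back to the canonical mature interval
  g_na <- toy_gene(gene_sequence = body, anticodon_start = NA_integer_)
  expect_equal(build_mature(g_na)$anticodon_start, 33L)

  wrong <- toy_gene(gene_sequence = body, anticodon = "TTT", anticodon_start = 33L)
  expect_error(build_mature(wrong), "anticodon")
})

test_that("precursor assembly handles strands and contig edges", {
  set.seed(3)
  body <- paste(sample(c("A", "C", "G", "T"), 72, replace = TRUE), collapse = "")
  left <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  contig <- paste0(left, body, right)
  g <- toy_gene(gene_sequence = body, start = 100L)
  p <- build_precursor(g, c(chr1 = contig))
  expect_equal(nchar(p$sequence), 50L + 72L + 50L)
  expect_equal(p$mature3_boundary, 122L)
  expect_equal(p$sequence, substr(contig, 51, 222))

  # minus strand: sense precursor equals the reverse complement of the
  # genomic plus-strand window (independent Biostrings oracle)
  g_minus <- toy_gene(
    gene_sequence = revcomp(substr(contig, 101, 172)),
    start = 100L, strand = "-"
  )
  p_minus <- build_precursor(g_minus, c(chr1 = contig))
  oracle <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 51, 222))
  ))
  expect_equal(p_minus$sequence, oracle)

  # gene 10 nt from the contig start: leader truncated and recorded
  g_edge <- toy_gene(
    gene_sequence = substr(contig, 11, 82), start = 10L
  )
  p_edge <- build_precursor(g_edge, c(chr1 = contig))
  expect_equal(p_edge$leader_len, 10L)
  expect_equal(p_edge$trailer_len, 50L)
  expect_equal(p_edge$mature3_boundary, 10L + 72L)
})

test_that("identical matures collapse to one representative", {
  set.seed(4)
  body <- paste(sample(c("A", "C", "G", "T"), 72, replace = TRUE), collapse = "")
  body2 <- paste(sample(c("A", "C", "G", "T"), 72, replace = TRUE), collapse = "")
  genes <- dplyr::bind_rows(
    toy_gene("gA", gene_sequence = body),
    toy_gene("gB", gene_sequence = body),
    toy_gene("gC", gene_sequence = body2)
  )
  m <- build_mature(genes)
  cc <- collapse_identical(m)
  expect_equal(nrow(cc$matures), 2L)
  expect_equal(nrow(cc$collapse_map), 3L)
  expect_setequal(cc$collapse_map$gene_id, c("gA", "gB", "gC"))
  expect_equal(
    sort(cc$collapse_map$mature_id[cc$collapse_map$gene_id %in% c("gA", "gB")]),
    rep(cc$matures$mature_id[cc$matures$sequence == paste0(body, "CCA")], 2)
  )

  # all-distinct input keeps every sequence
  m2 <- build_mature(dplyr::bind_rows(
    toy_gene("gC", gene_sequence = body2), toy_gene("gA", gene_sequence = body)
  ))
  expect_equal(nrow(collapse_identical(m2)$matures), 2L)

  # idempotent and order-independent (hash-set oracle on generated input)
  set.seed(5)
  seqs <- replicate(40, paste(sample(c("A", "C", "G", "T"), 72, replace = TRUE),
    collapse = ""
  ))
  seqs <- sample(seqs[sample.int(40, 60, replace = TRUE)]) # duplicates
  genes_many <- dplyr::bind_rows(lapply(seq_along(seqs), function(i) {
    toy_gene(sprintf("g%03d", i), gene_sequence = seqs[i])
  }))
  m_many <- build_mature(genes_many)
  c1 <- collapse_identical(m_many)
  expect_equal(nrow(c1$matures), length(unique(seqs)))
  c2 <- collapse_identical(m_many[sample.int(nrow(m_many)), ])
  expect_equal(c1$matures$sequence, c2$matures$sequence)
  expect_equal(c1$matures$mature_id, c2$matures$mature_id)
})

test_that("mature sequences round-trip to the gene and stay clean DNA", {
  refs <- shared_refs()
  genes <- refs$genes
  matures_by_gene <- build_mature(genes)
  for (i in seq_len(nrow(genes))) {
    m <- matures_by_gene$sequence[i]
    expect_true(endsWith(m, "CCA"))
    expect_false(grepl("[^ACGT]", m))
    spliced <- substr(m, 1, nchar(m) - 3)
    # re-insert introns to recover the annotated gene body
    introns <- genes$introns[[i]]
    body <- spliced
    if (nrow(introns) > 0) {
      gs <- genes$gene_sequence[i]
      body <- paste0(
        substr(spliced, 1, introns[1, 1]),
        substr(gs, introns[1, 1] + 1, introns[1, 2]),
        substr(spliced, introns[1, 1] + 1, nchar(spliced))
      )
    }
    expect_equal(body, genes$gene_sequence[i])
  }
})

test_that("the full reference builder wires annotation, genome and disk IO", {
  refs <- shared_refs()
  ref <- refs$reference
  expect_s3_class(ref, "trna_reference")
  expect_equal(nrow(ref$collapse_map), nrow(refs$genes))
  expect_true(all(endsWith(ref$matures$sequence, "CCA")))
  expect_true(all(
    ref$precursors$mature3_boundary ==
      ref$precursors$leader_len + (refs$genes$end - refs$genes$start)
  ))

  dir <- withr::local_tempdir()
  write_trna_reference(ref, dir)
  mat <- read_fasta(file.path(dir, "mature.fa"))
  expect_equal(unname(mat[ref$matures$mature_id]), ref$matures$sequence)

  # annotation TSV round trip re-derives identical gene sequences
  ann_path <- file.path(dir, "genes.tsv")
  write_trna_annotation(refs$genes, ann_path)
  back <- read_trna_annotation(ann_path, refs$genome)
  expect_equal(back$gene_sequence, refs$genes$gene_sequence)
  expect_equal(back$anticodon, refs$genes$anticodon)
  expect_equal(back$introns, lapply(refs$genes$introns, function(m) {
    if (nrow(m) == 0) matrix(integer(0), ncol = 2) else m
  }))
})
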