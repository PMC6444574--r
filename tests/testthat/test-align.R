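make_random_refs <- function(seed = 31) {
  set.seed(seed)
  widths <- c(120, 300, 80, 150, 60)
  tibble::tibble(
    ref_id = sprintf("ref%d", seq_along(widths)),
    rna_class = c("miRNA", "tRNA", "tRNA", "rRNA", "piRNA"),
    ref_role = c("class", "mature", "mature", "class", "class"),
    sequence = vapply(widths, function(w) {
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
    }, character(1))
  )
}

test_that("the indexed aligner matches a brute-force Hamming scan", {
  refs <- make_random_refs()
  index <- build_tag_index(refs, max_mismatches = 1)
  set.seed(32)
  tags <- character(0)
  # exact substrings of references
  for (i in 1:15) {
    r <- sample.int(nrow(refs), 1)
    L <- sample(16:40, 1)
    s <- sample.int(nchar(refs$sequence[r]) - L + 1, 1)
    tags <- c(tags, substr(refs$sequence[r], s, s + L - 1))
  }
  # one-substitution neighbours
  for (i in 1:15) {
    t <- tags[sample.int(length(tags), 1)]
    p <- sample.int(nchar(t), 1)
    substr(t, p, p) <- sample(setdiff(c("A", "C", "G", "T"), substr(t, p, p)), 1)
    tags <- c(tags, t)
  }
  # random tags, mostly unalignable
  tags <- c(tags, vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(16:40, 1), replace = TRUE),
      collapse = ""
    )
  }, character(1)))
  tags <- unique(tags)
  got <- align_tags(tags, index) |>
    dplyr::arrange(tag_sequence, rna_class, ref_id, ref_start)
  want <- dplyr::bind_rows(lapply(tags, brute_align, references = refs)) |>
    dplyr::arrange(tag_sequence, rna_class, ref_id, ref_start)
  expect_equal(
    got[, c("tag_sequence", "ref_id", "ref_start", "ref_end", "mismatches")],
    want[, c("tag_sequence", "ref_id", "ref_start", "ref_end", "mismatches")]
  )
})

test_that("alignment geometry and stratum behaviour follow the contract", {
  refs <- make_random_refs()
  index <- build_tag_index(refs, max_mismatches = 1)

  prefix <- substr(refs$sequence[2], 1, 30)
  hit <- align_tags(prefix, index)
  trna_hits <- dplyr::filter(hit, rna_class == "tRNA")
  expect_true(any(trna_hits$ref_id == "ref2" & trna_hits$ref_start == 0 &
    trna_hits$ref_end == 30 & trna_hits$mismatches == 0))
  expect_true(all(trna_hits$ref_end - trna_hits$ref_start == 30))

  # an exact hit in one class suppresses that class's mismatched hits but
  # not another class's
  mut <- substr(refs$sequence[4], 11, 43) # rRNA interior, positions 10..43
  got_exact <- align_tags(mut, index)
  expect_true(all(got_exact$mismatches[got_exact$rna_class == "rRNA"] == 0))
  substr(mut, 16, 16) <- if (substr(mut, 16, 16) == "A") "G" else "A"
  got_mut <- align_tags(mut, index)
  expect_true(all(got_mut$mismatches[got_mut$rna_class == "rRNA"] == 1))
  expect_equal(sum(got_mut$rna_class == "rRNA"), 1L)

  # raising max_mismatches never removes an alignment (exact unaffected)
  got0 <- align_tags(mut, index, max_mismatches = 0)
  expect_true(nrow(got0) == 0 ||
    nrow(dplyr::anti_join(got0, got_mut,
      by = c("tag_sequence", "ref_id", "ref_start")
    )) == 0)
})

test_that("multi-mapping weights are uniform and total one", {
  set.seed(33)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  seq_shared <- pad(40)
  refs <- tibble::tibble(
    ref_id = c("m1", "m2"), rna_class = "tRNA", ref_role = "mature",
    sequence = c(paste0(seq_shared, pad(35)), paste0(pad(20), seq_shared, pad(15)))
  )
  index <- build_tag_index(refs)
  ann <- annotate_tags(seq_shared, index)
  expect_equal(nrow(ann$alignments), 2L)
  expect_equal(ann$alignments$weight, c(0.5, 0.5))

  one <- assign_weights(align_tags(substr(refs$sequence[1], 41, 60), index))
  expect_equal(sum(one$weight[one$tag_sequence == unique(one$tag_sequence)[1]]), 1)

  # weights sum to one per tag across a simulated library
  full_refs <- shared_refs()
  cfg <- simulation_config(seed = 34, n_reads = 10000, error_rate = 0)
  sim <- simulate_library(cfg, full_refs)
  pp <- preprocess_reads(sim$reads, cfg$adapter_3p)
  idx <- build_tag_index(full_refs$references)
  ann_full <- annotate_tags(pp$tags, idx)
  sums <- ann_full$alignments |>
    dplyr::group_by(tag_sequence) |>
    dplyr::summarise(w = sum(weight))
  expect_true(all(abs(sums$w - 1) < 1e-9))

  # feature-level aggregation conserves annotated reads, and a 1-mismatch
  # (error) tag folds into the feature it aligns to
  tags <- dplyr::mutate(pp$tags, sample_id = "S1")
  fc <- feature_count_matrix(ann_full, tags)
  annotated <- sum(ann_full$annotations$count[ann_full$annotations$rna_class != "other"])
  expect_equal(sum(fc$count), annotated)
  mat1 <- full_refs$reference$matures$mature_id[1]
  err_tag <- substr(full_refs$reference$matures$sequence[1], 1, 30)
  substr(err_tag, 10, 10) <- if (substr(err_tag, 10, 10) == "A") "C" else "A"
  fc_err <- feature_count_matrix(
    annotate_tags(err_tag, idx),
    tibble::tibble(sample_id = "S1", tag_sequence = err_tag, count = 7L)
  )
  expect_true(paste0("tRNA:", mat1) %in% fc_err$species_key)
  expect_equal(sum(fc_err$count), 7)
})

test_that("hierarchical annotation follows the class priority", {
  set.seed(35)
  shared <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = "")
  trna_only <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  refs <- tibble::tibble(
    ref_id = c("mirX", "matX"),
    rna_class = c("miRNA", "tRNA"),
    ref_role = c("class", "mature"),
    sequence = c(shared, paste0(shared, trna_only, pad(28)))
  )
  index <- build_tag_index(refs)
  ann <- annotate_tags(c(shared, trna_only, strrep("AC", 10)), index)
  got <- setNames(ann$annotations$rna_class, ann$annotations$tag_sequence)
  expect_equal(unname(got[shared]), "miRNA") # hits both; miRNA outranks tRNA
  expect_equal(unname(got[trna_only]), "tRNA")
  expect_equal(unname(got[strrep("AC", 10)]), "other")
  expect_true(all(ann$alignments$rna_class[
    ann$alignments$tag_sequence == shared
  ] == "miRNA"))

  # weighted class fractions over all tags sum to 1
  fr <- ann$annotations |>
    dplyr::count(rna_class, wt = count) |>
    dplyr::mutate(f = n / sum(n))
  expect_equal(sum(fr$f), 1)
})
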