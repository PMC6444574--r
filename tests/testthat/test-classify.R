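aln_row <- function(tag, ref_id, start, end, role = "mature") {
  tibble::tibble(
    tag_sequence = tag, ref_id = ref_id, rna_class = "tRNA", ref_role = role,
    ref_start = as.integer(start), ref_end = as.integer(end), mismatches = 0L
  )
}

test_that("positional rules assign tRNA-5 / tRNA-i / tRNA-3 and reject carryover", {
  ref <- toy_mature_reference()
  m <- ref$matures
  mk <- function(s, e) aln_row(substr(m$sequence, s + 1, e), m$mature_id, s, e)
  expect_equal(classify_mature_alignment(mk(0, 33), m), "tRNA-5")
  expect_equal(classify_mature_alignment(mk(57, 75), m), "tRNA-3")
  expect_equal(classify_mature_alignment(mk(20, 40), m), "tRNA-i")
  expect_equal(classify_mature_alignment(mk(0, 75), m), "unclassified")
  expect_equal(classify_mature_alignment(mk(1, 33), m), "tRNA-5") # delta5 = 1
  expect_equal(classify_mature_alignment(mk(55, 73), m), "tRNA-3") # delta3 = 2
  expect_error(
    classify_mature_alignment(aln_row("X", m$mature_id, 50, 80), m),
    "bounds"
  )
})

test_that("every 16-40 nt substring classifies exactly as the rule transcription", {
  ref <- toy_mature_reference()
  m <- ref$matures
  len <- nchar(m$sequence)
  rows <- list()
  for (L in 16:40) {
    for (s in 0:(len - L)) {
      rows[[length(rows) + 1]] <- c(s, s + L)
    }
  }
  grid <- do.call(rbind, rows)
  aln <- aln_row(
    substring(m$sequence, grid[, 1] + 1, grid[, 2]),
    m$mature_id, grid[, 1], grid[, 2]
  )
  got <- classify_mature_alignment(aln, m)
  want <- vapply(
    seq_len(nrow(grid)),
    function(i) brute_classify_position(grid[i, 1], grid[i, 2], len),
    character(1)
  )
  expect_equal(got, want)
  expect_equal(nrow(grid), sum(len - (16:40) + 1))

  got_sub <- subtype_half_or_fragment(aln, m, got)
  want_sub <- vapply(seq_len(nrow(grid)), function(i) {
    brute_subtype(grid[i, 1], grid[i, 2], want[i], 33, 36)
  }, character(1))
  expect_equal(got_sub, want_sub)
})

test_that("halves need both the length and the anticodon-loop breakpoint", {
  ref <- toy_mature_reference()
  m <- ref$matures
  mk <- function(s, e) aln_row(substr(m$sequence, s + 1, e), m$mature_id, s, e)
  # 35 nt ending inside the padded anticodon interval -> half
  expect_equal(
    subtype_half_or_fragment(mk(0, 35), m, "tRNA-5"), "tRH"
  )
  # short 5' fragment -> tRF regardless of breakpoint
  expect_equal(
    subtype_half_or_fragment(mk(0, 18), m, "tRNA-5"), "tRF"
  )
  # long but breakpoint outside the loop -> tRF
  expect_equal(
    subtype_half_or_fragment(mk(0, 45), m, "tRNA-5"), "tRF"
  )
  # 3' half: breakpoint is ref_start
  expect_equal(
    subtype_half_or_fragment(mk(34, 75), m, "tRNA-3"), "tRH"
  )
})

test_that("3'U tRF detection requires trailer overlap and a poly-T tail", {
  pre <- tibble::tibble(
    precursor_id = "pre-g1", isoacceptor = "GlyGCC",
    sequence = paste0(strrep("A", 50), strrep("G", 72), "TTTT", strrep("C", 46)),
    leader_len = 50L, trailer_len = 50L, mature3_boundary = 122L
  )
  mk <- function(tag, s, e) aln_row(tag, "pre-g1", s, e, role = "precursor")
  crossing <- paste0(strrep("G", 16), "TTTT")
  expect_true(detect_3pU_trf(mk(crossing, 106, 126), pre))
  inside <- strrep("G", 20)
  expect_false(detect_3pU_trf(mk(inside, 60, 80), pre))
  bad_tail <- paste0(strrep("G", 18), "TA")
  expect_false(detect_3pU_trf(mk(bad_tail, 104, 124), pre))
})

test_that("multi-mapping tags resolve by weighted majority with conservative ties", {
  ref <- toy_mature_reference(n = 2)
  m <- ref$matures
  # agreement: the same 5' fragment on both copies
  tag5 <- substr(m$sequence[1], 1, 30)
  aln <- dplyr::bind_rows(
    aln_row(tag5, m$mature_id[1], 0, 30),
    aln_row(tag5, m$mature_id[2], 0, 30)
  ) |> dplyr::mutate(weight = 0.5)
  rec <- classify_tags(aln, ref)
  expect_equal(rec$ts_class, "tRNA-5")
  expect_equal(rec$isoacceptor, "GlyGCC")
  expect_equal(rec$weight, 1)

  # disagreement 0.5 / 0.5 -> unclassified
  aln_tie <- dplyr::bind_rows(
    aln_row("TAGTAGTAGTAGTAGTAGTA", m$mature_id[1], 0, 20),
    aln_row("TAGTAGTAGTAGTAGTAGTA", m$mature_id[2], 30, 50)
  )
  rec_tie <- classify_tags(aln_tie, ref)
  expect_equal(rec_tie$ts_class, "unclassified")
  expect_true(is.na(rec_tie$subtype))
  expect_equal(rec_tie$weight, 1)

  # majority 2/3 wins and weights renormalise to the whole tag
  tagm <- "CCACCACCACCACCACCACC"
  aln_maj <- dplyr::bind_rows(
    aln_row(tagm, m$mature_id[1], 0, 20),
    aln_row(tagm, m$mature_id[1], 1, 21),
    aln_row(tagm, m$mature_id[2], 30, 50)
  )
  rec_maj <- classify_tags(aln_maj, ref)
  expect_equal(rec_maj$ts_class, "tRNA-5")
  expect_equal(sum(rec_maj$weight), 1)
})

test_that("simulated reads recover their true class almost perfectly", {
  refs <- shared_refs()
  cfg <- simulation_config(seed = 41, n_reads = 20000, error_rate = 0)
  sim <- simulate_library(cfg, refs)
  pp <- preprocess_reads(sim$reads, cfg$adapter_3p)
  idx <- build_tag_index(refs$references)
  ann <- annotate_tags(pp$tags, idx)
  rec <- classify_tags(ann, refs$reference)

  # partition: weighted class fractions over the five classes sum to 1
  expect_equal(sum(rec$weighted_count), sum(ann$annotations$count[
    ann$annotations$rna_class == "tRNA"
  ]))

  truth <- sim$truth |> dplyr::filter(rna_class == "tRNA")
  tag_class <- rec |> dplyr::distinct(tag_sequence, ts_class)
  joined <- truth |> dplyr::left_join(tag_class, by = c(insert = "tag_sequence"))
  expect_gte(mean(joined$ts_class.y == joined$ts_class.x), 0.99)

  # isoacceptor recovery for uniquely mapped tags
  tag_iso <- rec |>
    dplyr::group_by(tag_sequence) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::select(tag_sequence, isoacceptor)
  joined_iso <- truth |>
    dplyr::inner_join(tag_iso, by = c(insert = "tag_sequence"))
  expect_gte(mean(joined_iso$isoacceptor.y == joined_iso$isoacceptor.x), 0.99)
})

test_that("widening the end tolerances never evicts a 5'/3' call", {
  ref <- toy_mature_reference()
  m <- ref$matures
  len <- nchar(m$sequence)
  grid <- expand.grid(s = 0:10, L = 16:30)
  grid$e <- grid$s + grid$L
  grid <- grid[grid$e <= len, ]
  aln <- aln_row(
    substring(m$sequence, grid$s + 1, grid$e), m$mature_id, grid$s, grid$e
  )
  tight <- classify_mature_alignment(aln, m, classifier_params(delta5 = 1, delta3 = 2))
  loose <- classify_mature_alignment(aln, m, classifier_params(delta5 = 3, delta3 = 4))
  expect_true(all(loose[tight == "tRNA-5"] %in% c("tRNA-5", "unclassified")))
  expect_true(all(loose[tight == "tRNA-3"] %in% c("tRNA-3", "unclassified")))
  # "unclassified" can only appear when both ends qualify, i.e. widening
  # promoted the other end as well - never a move to the interior
  expect_false(any(loose[tight %in% c("tRNA-5", "tRNA-3")] == "tRNA-i"))
})
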