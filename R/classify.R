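# Positional tsRNA classification: tRNA-5 / tRNA-i / tRNA-3 on the mature
# tRNA, tRF vs tRH subtyping at the anticodon loop, and precursor-derived
# 3'U tRFs.

#' Classifier tolerances
#'
#' @param delta5 Tolerance in nt at the mature 5' end: a fragment starting
#'   at `ref_start <= delta5` counts as 5'-anchored (default 1, allowing a
#'   non-templated start).
#' @param delta3 Tolerance at the mature 3' end, CCA-aware: a fragment
#'   ending at `ref_end >= len - delta3` counts as 3'-anchored (default 2,
#'   allowing partial CCA).
#' @param half_min_len Minimum length in nt for a fragment to qualify as a
#'   tRNA half (default 28).
#' @param anticodon_window Padding in nt around the anticodon interval
#'   within which the internal breakpoint of a half must fall (default 2).
#' @param min_u Number of terminal U (T in DNA) bases required to call a
#'   precursor fragment a 3'U tRF (default 2).
#' @return A named list of class `classifier_params`.
#' @export
classifier_params <- function(delta5 = 1L, delta3 = 2L, half_min_len = 28L,
                              anticodon_window = 2L, min_u = 2L) {
  p <- list(
    delta5 = delta5, delta3 = delta3, half_min_len = half_min_len,
    anticodon_window = anticodon_window, min_u = min_u
  )
  stopifnot(all(unlist(p) >= 0))
  structure(p, class = "classifier_params")
}

#' Positional class of a mature-tRNA alignment
#'
#' Applies the positional rules: `tRNA-5` iff the alignment starts within
#' `delta5` of the mature 5' end; `tRNA-3` iff it ends within `delta3` of
#' the mature 3' end (which includes the CCA); `tRNA-i` otherwise. A tag
#' satisfying both end conditions is near-full-length tRNA carryover, not
#' a fragment, and is `unclassified`.
#'
#' @param alignments Alignment tibble on mature references (`ref_id`,
#'   `ref_start`, `ref_end`).
#' @param matures Collapsed mature table (from a `trna_reference`).
#' @param params A [classifier_params()] list.
#' @return Character vector of classes, one per alignment row.
#' @export
classify_mature_alignment <- function(alignments, matures, params = classifier_params()) {
  len <- setNames(nchar(matures$sequence), matures$mature_id)[alignments$ref_id]
  if (anyNA(len)) abort_msg("alignment to unknown mature reference")
  if (any(alignments$ref_start < 0 | alignments$ref_end > len)) {
    abort_msg("alignment outside mature reference bounds")
  }
  is5 <- alignments$ref_start <= params$delta5
  is3 <- alignments$ref_end >= len - params$delta3
  dplyr::case_when(
    is5 & is3 ~ "unclassified",
    is5 ~ "tRNA-5",
    is3 ~ "tRNA-3",
    .default = "tRNA-i"
  )
}

#' Fragment-or-half subtype of a 5'/3'-anchored tsRNA
#'
#' A tRNA half (tRH) arises from angiogenin cleavage within the anticodon
#' loop: a fragment is a tRH iff it is at least `half_min_len` nt long AND
#' its internal breakpoint (`ref_end` for tRNA-5, `ref_start` for tRNA-3)
#' falls inside the anticodon interval padded by `anticodon_window`;
#' otherwise it is a tRF.
#'
#' @inheritParams classify_mature_alignment
#' @param ts_class Positional class per alignment (only `tRNA-5`/`tRNA-3`
#'   rows are subtyped; others return `NA`).
#' @return Character vector `tRF`/`tRH` (or `NA`).
#' @export
subtype_half_or_fragment <- function(alignments, matures, ts_class,
                                     params = classifier_params()) {
  meta <- matures[match(alignments$ref_id, matures$mature_id), ]
  bp <- ifelse(ts_class == "tRNA-5", alignments$ref_end, alignments$ref_start)
  lo <- meta$anticodon_start - params$anticodon_window
  hi <- meta$anticodon_end + params$anticodon_window
  frag_len <- alignments$ref_end - alignments$ref_start
  in_loop <- bp >= lo & bp <= hi
  out <- ifelse(frag_len >= params$half_min_len & in_loop, "tRH", "tRF")
  out[!ts_class %in% c("tRNA-5", "tRNA-3")] <- NA_character_
  out
}

#' Detect precursor 3'U tRFs
#'
#' A precursor alignment is a 3'U tRF iff it extends past the mature 3'
#' boundary into the trailer AND the tag's last `min_u` bases are all T
#' (the transcribed poly-U left by RNase Z processing / pol-III
#' termination).
#'
#' @param alignments Alignment tibble on precursor references.
#' @param precursors Precursor table (from a `trna_reference`).
#' @inheritParams classify_mature_alignment
#' @return Logical vector, one per alignment row.
#' @export
detect_3pU_trf <- function(alignments, precursors, params = classifier_params()) {
  boundary <- setNames(
    precursors$mature3_boundary, precursors$precursor_id
  )[alignments$ref_id]
  if (anyNA(boundary)) abort_msg("alignment to unknown precursor reference")
  L <- nchar(alignments$tag_sequence)
  suffix <- substr(alignments$tag_sequence, L - params$min_u + 1L, L)
  alignments$ref_end > boundary & suffix == strrep("T", params$min_u)
}

#' Classify tRNA-annotated tags into tsRNA records
#'
#' Resolves each tag's tRNA alignments into a single tsRNA class.
#' Candidate 3'U-tRF alignments (precursor, trailer-crossing, poly-T
#' suffix) take precedence, since the trailer is the only signal that
#' distinguishes precursor fragments; otherwise mature alignments are
#' classified positionally and the majority class by weight wins, with
#' ties resolved conservatively to `unclassified`. A tag whose winning
#' class spans several isoacceptors contributes fractional weight to each.
#'
#' @param annotation A `tsrna_annotation` from [annotate_tags()], or a
#'   weighted alignment tibble restricted to one class per tag.
#' @param reference A `trna_reference`.
#' @inheritParams classify_mature_alignment
#' @return Tibble of tsRNA records: `tag_sequence`, `fragment_sequence`
#'   (the reference subsequence under the winning alignment - identical to
#'   the tag for exact matches, the parent fragment for 1-mismatch tags),
#'   `ts_class`, `subtype`, `source_id`, `isoacceptor`, `length`,
#'   `count`, `weight` (fraction of the tag assigned to this isoacceptor;
#'   sums to 1 per classified tag) and `weighted_count = count * weight`.
#' @export
classify_tags <- function(annotation, reference, params = classifier_params()) {
  aln <- if (inherits(annotation, "tsrna_annotation")) {
    annotation$alignments
  } else {
    annotation
  }
  counts <- if (inherits(annotation, "tsrna_annotation")) {
    annotation$annotations |> select("tag_sequence", "count")
  } else {
    distinct(aln, .data$tag_sequence) |> mutate(count = 1L)
  }
  aln <- filter(aln, .data$rna_class == "tRNA")
  if (nrow(aln) == 0) {
    return(tibble(
      tag_sequence = character(0), ts_class = character(0),
      subtype = character(0), source_id = character(0),
      isoacceptor = character(0), length = integer(0),
      count = integer(0), weight = numeric(0), weighted_count = numeric(0)
    ))
  }
  matures <- reference$matures
  precursors <- reference$precursors

  is_pre <- aln$ref_role == "precursor"
  aln$is_3pu <- FALSE
  if (any(is_pre)) {
    aln$is_3pu[is_pre] <- detect_3pU_trf(aln[is_pre, ], precursors, params)
  }
  aln$aln_class <- NA_character_
  aln$subtype <- NA_character_
  is_mat <- aln$ref_role == "mature"
  if (any(is_mat)) {
    cls <- classify_mature_alignment(aln[is_mat, ], matures, params)
    aln$aln_class[is_mat] <- cls
    aln$subtype[is_mat] <- subtype_half_or_fragment(aln[is_mat, ], matures, cls, params)
    aln$subtype[is_mat][cls == "tRNA-i"] <- "tRF"
  }
  aln$aln_class[aln$is_3pu] <- "3pU-tRF"
  iso_mat <- setNames(matures$isoacceptor, matures$mature_id)
  iso_pre <- setNames(precursors$isoacceptor, precursors$precursor_id)
  aln$isoacceptor <- ifelse(is_mat, iso_mat[aln$ref_id], iso_pre[aln$ref_id])

  # precedence: 3'U candidates, else mature alignments, else unclassifiable
  retained <- aln |>
    group_by(.data$tag_sequence) |>
    mutate(
      any_3pu = any(.data$is_3pu),
      any_mature = any(.data$ref_role == "mature")
    ) |>
    ungroup() |>
    filter(
      (.data$any_3pu & .data$is_3pu) |
        (!.data$any_3pu & .data$any_mature & .data$ref_role == "mature")
    ) |>
    group_by(.data$tag_sequence) |>
    mutate(weight = 1 / n()) |>
    ungroup()

  class_w <- retained |>
    group_by(.data$tag_sequence, .data$aln_class) |>
    summarise(class_weight = sum(.data$weight), .groups = "drop_last") |>
    mutate(
      is_max = .data$class_weight >= max(.data$class_weight) - 1e-9,
      tied = sum(.data$is_max) > 1L
    ) |>
    ungroup()
  winners <- class_w |> filter(.data$is_max, !.data$tied)

  # reference-projected fragment: the reference subsequence under the
  # alignment, so 1-mismatch (sequencing-error) tags share their parent
  # species' identity
  ref_seq <- c(
    setNames(matures$sequence, matures$mature_id),
    setNames(precursors$sequence, precursors$precursor_id)
  )
  classified <- retained |>
    inner_join(winners, by = c("tag_sequence", "aln_class")) |>
    mutate(fragment_sequence = substr(
      ref_seq[.data$ref_id], .data$ref_start + 1L, .data$ref_end
    )) |>
    group_by(.data$tag_sequence) |>
    mutate(weight = .data$weight / sum(.data$weight)) |>
    # subtype: weight-majority within the winning class, ties -> tRF
    mutate(subtype = {
      st <- .data$subtype
      if (all(is.na(st))) {
        NA_character_
      } else {
        w <- tapply(.data$weight, st, sum)
        names(w)[order(-w, names(w))][1]
      }
    }) |>
    group_by(.data$tag_sequence, .data$aln_class, .data$subtype, .data$isoacceptor) |>
    summarise(
      source_id = .data$ref_id[1],
      fragment_sequence = .data$fragment_sequence[1],
      weight = sum(.data$weight),
      .groups = "drop"
    ) |>
    rename(ts_class = "aln_class")

  unresolved <- setdiff(unique(aln$tag_sequence), unique(classified$tag_sequence))
  records <- bind_rows(
    classified,
    tibble(
      tag_sequence = unresolved, ts_class = "unclassified",
      subtype = NA_character_, isoacceptor = NA_character_,
      source_id = NA_character_, fragment_sequence = unresolved, weight = 1
    )
  ) |>
    mutate(
      subtype = ifelse(.data$ts_class %in% c("3pU-tRF", "unclassified"),
        NA_character_, .data$subtype
      ),
      length = nchar(.data$tag_sequence)
    ) |>
    inner_join(counts, by = "tag_sequence") |>
    mutate(weighted_count = .data$count * .data$weight) |>
    select(
      "tag_sequence", "fragment_sequence", "ts_class", "subtype",
      "source_id", "isoacceptor", "length", "count", "weight",
      "weighted_count"
    ) |>
    arrange(.data$tag_sequence, .data$isoacceptor)
  records
}

#' Species key for a tsRNA record
#'
#' Builds the species identifier used for counting and differential
#' expression, in the field's naming style: `tRNA-<isoacceptor>-<type>`
#' plus the tag sequence (several distinct fragments can share an
#' isoacceptor and type).
#'
#' @param isoacceptor,ts_class,tag_sequence Vectors as in a record tibble.
#' @return Character vector of keys, e.g. `"tRNA-GlyGCC-5|TCAT..."`.
#' @export
species_key <- function(isoacceptor, ts_class, tag_sequence) {
  suffix <- c(
    "tRNA-5" = "5", "tRNA-i" = "i", "tRNA-3" = "3",
    "3pU-tRF" = "3pU", "unclassified" = "un"
  )[ts_class]
  paste0("tRNA-", isoacceptor, "-", suffix, "|", tag_sequence)
}
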