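# Ungapped, full-length tag alignment against per-class small-RNA
# references, with best-stratum reporting and hierarchical class
# assignment.
#
# The aligner indexes every reference substring in the indexable length
# range in a hash map. Exact hits are direct lookups; mismatched hits use
# the pigeonhole principle (a tag with <= k mismatches must contain an
# exact piece when split into k+1 pieces), so candidate positions come
# from piece lookups and are then verified by Hamming count. This keeps
# the scan exact (equivalent to brute force over every offset) while
# running in near-constant time per tag.

#' Assemble the combined reference table
#'
#' Binds the tRNA mature/precursor references and the per-class decoy
#' references into the single table the aligner indexes.
#'
#' @param trna_reference A `trna_reference` from [build_trna_reference()],
#'   or `NULL` to align against class references only.
#' @param class_seqs Named list (class name -> named character vector of
#'   sequences), e.g. `list(miRNA = c(mir1 = "..."), rRNA = ...)`.
#' @return Tibble `ref_id`, `rna_class`, `ref_role`
#'   (`mature`/`precursor`/`class`), `sequence`.
#' @export
reference_table <- function(trna_reference = NULL, class_seqs = list()) {
  parts <- list()
  if (!is.null(trna_reference)) {
    parts$mature <- tibble(
      ref_id = trna_reference$matures$mature_id,
      rna_class = "tRNA", ref_role = "mature",
      sequence = trna_reference$matures$sequence
    )
    parts$precursor <- tibble(
      ref_id = trna_reference$precursors$precursor_id,
      rna_class = "tRNA", ref_role = "precursor",
      sequence = trna_reference$precursors$sequence
    )
  }
  for (cls in names(class_seqs)) {
    seqs <- class_seqs[[cls]]
    parts[[cls]] <- tibble(
      ref_id = names(seqs), rna_class = cls, ref_role = "class",
      sequence = unname(seqs)
    )
  }
  out <- bind_rows(parts)
  if (anyDuplicated(out$ref_id)) {
    abort_msg("reference ids must be unique across classes")
  }
  out
}

#' Build an alignment index over a reference table
#'
#' @param references Output of [reference_table()].
#' @param max_mismatches Largest mismatch count the index must support
#'   (default 1).
#' @param min_tag_len,max_tag_len Tag length range the index must serve
#'   (defaults 16 and 40, the insert-size window).
#' @return An object of class `tag_index`.
#' @export
build_tag_index <- function(references, max_mismatches = 1L,
                            min_tag_len = 16L, max_tag_len = 40L) {
  stopifnot(nrow(references) > 0, max_mismatches >= 0)
  min_piece <- max(1L, min_tag_len %/% (max_mismatches + 1L))
  seqs <- references$sequence
  keys <- vector("list", length(seqs))
  codes <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    ks <- character(0)
    cs <- numeric(0)
    for (L in min_piece:min(max_tag_len, n)) {
      starts <- seq_len(n - L + 1L)
      ks <- c(ks, substring(s, starts, starts + L - 1L))
      cs <- c(cs, i * 1e6 + (starts - 1L))
    }
    keys[[i]] <- ks
    codes[[i]] <- cs
  }
  env <- list2env(split(unlist(codes), unlist(keys)), envir = new.env(hash = TRUE))
  structure(
    list(
      env = env, references = references, max_mismatches = max_mismatches,
      min_piece = min_piece, min_tag_len = min_tag_len, max_tag_len = max_tag_len
    ),
    class = "tag_index"
  )
}

#' @export
print.tag_index <- function(x, ...) {
  cat(sprintf(
    "<tag_index> %d references (%d nt), <=%d mismatches\n",
    nrow(x$references), sum(nchar(x$references$sequence)), x$max_mismatches
  ))
  invisible(x)
}

# All (ref_idx, start0) with Hamming distance <= k for one tag. Both
# strata are returned; the per-class best-stratum rule is applied by the
# caller (exact hits in one class must not mask mismatched hits in
# another).
align_one <- function(tag, index, max_mismatches) {
  L <- nchar(tag)
  exact <- index$env[[tag]]
  exact_hits <- NULL
  if (!is.null(exact)) {
    exact_hits <- tibble(
      ref_idx = as.integer(exact %/% 1e6),
      ref_start = as.integer(exact %% 1e6),
      mismatches = 0L
    )
  }
  if (max_mismatches == 0L) {
    return(exact_hits)
  }
  k <- max_mismatches
  bounds <- round(seq(0L, L, length.out = k + 2L))
  cand <- numeric(0)
  for (p in seq_len(k + 1L)) {
    piece <- substr(tag, bounds[p] + 1L, bounds[p + 1L])
    hit <- index$env[[piece]]
    if (!is.null(hit)) {
      cand <- c(cand, hit - bounds[p])
    }
  }
  if (length(cand) == 0) {
    return(exact_hits)
  }
  cand <- unique(cand)
  ref_idx <- as.integer(cand %/% 1e6)
  start0 <- as.integer(round(cand - ref_idx * 1e6))
  ok <- start0 >= 0L & start0 + L <= nchar(index$references$sequence[ref_idx])
  ref_idx <- ref_idx[ok]
  start0 <- start0[ok]
  if (length(ref_idx) == 0) {
    return(exact_hits)
  }
  windows <- substr(
    index$references$sequence[ref_idx], start0 + 1L, start0 + L
  )
  mm <- hamming_vec(windows, rep(tag, length(windows)))
  keep <- mm >= 1L & mm <= k
  if (!any(keep)) {
    return(exact_hits)
  }
  bind_rows(exact_hits, tibble(
    ref_idx = ref_idx[keep], ref_start = start0[keep],
    mismatches = as.integer(mm[keep])
  ))
}

#' Align sequence tags to indexed references
#'
#' Reports every position at which the full tag aligns ungapped with at
#' most `max_mismatches` substitutions, under best-stratum reporting
#' within each RNA class: if a tag has an exact hit in a class, mismatched
#' hits in that class are suppressed.
#'
#' @param tags Tibble with a `tag_sequence` column (a bare character
#'   vector is also accepted).
#' @param index A `tag_index` from [build_tag_index()].
#' @param max_mismatches Maximum substitutions (default 1; must not exceed
#'   the index's setting).
#' @return Alignment tibble: `tag_sequence`, `ref_id`, `rna_class`,
#'   `ref_role`, `ref_start`, `ref_end` (0-based half-open), `mismatches`.
#'   Unaligned tags contribute no rows.
#' @export
align_tags <- function(tags, index, max_mismatches = 1L) {
  if (is.character(tags)) tags <- tibble(tag_sequence = tags)
  if (max_mismatches > index$max_mismatches) {
    abort_msg(
      "index built for <=%d mismatches; rebuild for %d",
      index$max_mismatches, max_mismatches
    )
  }
  uniq <- unique(tags$tag_sequence)
  hits <- lapply(uniq, function(tg) {
    h <- align_one(tg, index, max_mismatches)
    if (is.null(h)) {
      return(NULL)
    }
    h$tag_sequence <- tg
    h
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble(
      tag_sequence = character(0), ref_id = character(0),
      rna_class = character(0), ref_role = character(0),
      ref_start = integer(0), ref_end = integer(0), mismatches = integer(0)
    ))
  }
  refs <- index$references
  hits |>
    mutate(
      ref_id = refs$ref_id[.data$ref_idx],
      rna_class = refs$rna_class[.data$ref_idx],
      ref_role = refs$ref_role[.data$ref_idx],
      ref_end = .data$ref_start + nchar(.data$tag_sequence)
    ) |>
    group_by(.data$tag_sequence, .data$rna_class) |>
    filter(!any(.data$mismatches == 0L) | .data$mismatches == 0L) |>
    ungroup() |>
    select(
      "tag_sequence", "ref_id", "rna_class", "ref_role",
      "ref_start", "ref_end", "mismatches"
    ) |>
    arrange(.data$tag_sequence, .data$rna_class, .data$ref_id, .data$ref_start)
}

#' Uniform multi-mapping weights
#'
#' Gives each of a tag's retained alignments weight `1/n`, so weights per
#' tag sum to one.
#'
#' @param alignments Alignment tibble (one class per tag; typically the
#'   winning-class alignments from [annotate_tags()]).
#' @return `alignments` with a `weight` column.
#' @export
assign_weights <- function(alignments) {
  alignments |>
    group_by(.data$tag_sequence) |>
    mutate(weight = 1 / n()) |>
    ungroup()
}

#' Hierarchical small-RNA class annotation
#'
#' Assigns each tag to the highest-priority RNA class in which it has at
#' least one alignment (default priority `miRNA > tRNA > rRNA > snoRNA >
#' snRNA > piRNA`); tags with no alignment are `other`. Alignments of the
#' winning class receive uniform multi-mapping weights.
#'
#' @param tags Tibble with `tag_sequence` and (optionally) `count`.
#' @inheritParams align_tags
#' @param priority Class priority order, highest first.
#' @return A list of class `tsrna_annotation`: `annotations` (tibble
#'   `tag_sequence`, `count`, `rna_class`) and `alignments` (weighted
#'   winning-class alignments).
#' @export
annotate_tags <- function(tags, index, max_mismatches = 1L,
                          priority = c("miRNA", "tRNA", "rRNA", "snoRNA", "snRNA", "piRNA")) {
  if (is.character(tags)) tags <- tibble(tag_sequence = tags)
  if (!"count" %in% names(tags)) tags$count <- 1L
  aln <- align_tags(tags, index, max_mismatches)
  rank <- setNames(seq_along(priority), priority)
  winners <- aln |>
    mutate(class_rank = rank[.data$rna_class]) |>
    filter(!is.na(.data$class_rank)) |>
    group_by(.data$tag_sequence) |>
    filter(.data$class_rank == min(.data$class_rank)) |>
    ungroup() |>
    select(-"class_rank")
  winners <- assign_weights(winners)
  annotations <- tags |>
    select("tag_sequence", "count") |>
    left_join(distinct(winners, .data$tag_sequence, .data$rna_class),
      by = "tag_sequence"
    ) |>
    mutate(rna_class = dplyr::coalesce(.data$rna_class, "other"))
  structure(
    list(annotations = annotations, alignments = winners),
    class = "tsrna_annotation"
  )
}

#' @export
print.tsrna_annotation <- function(x, ...) {
  tab <- x$annotations |>
    group_by(.data$rna_class) |>
    summarise(reads = sum(.data$count), .groups = "drop") |>
    arrange(dplyr::desc(.data$reads))
  cat(sprintf(
    "<tsrna_annotation> %d tags, %d alignments\n",
    nrow(x$annotations), nrow(x$alignments)
  ))
  print(tab)
  invisible(x)
}
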