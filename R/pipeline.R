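# Pipeline orchestration: preprocess -> annotate -> classify -> profile ->
# (optional) differential expression, with TSV outputs and a manifest.

#' Build the species-by-sample count matrix
#'
#' Joins per-sample tag counts with the tsRNA records (weights per
#' isoacceptor/class) into a long count table keyed by species. The
#' species sequence is the reference-projected fragment, so tags that
#' differ from a species only by a tolerated mismatch (sequencing error)
#' are counted with that species.
#'
#' @param records tsRNA records from [classify_tags()] (computed on the
#'   union of tags across samples).
#' @param sample_tags Long tag-count tibble: `sample_id`, `tag_sequence`,
#'   `count`.
#' @param drop_unclassified Drop `unclassified` records (default TRUE).
#' @return Long tibble `species_key`, `sample_id`, `count` (weighted,
#'   possibly fractional).
#' @export
build_count_matrix <- function(records, sample_tags, drop_unclassified = TRUE) {
  rec <- records
  if (drop_unclassified) rec <- filter(rec, .data$ts_class != "unclassified")
  sample_tags |>
    inner_join(
      rec |>
        mutate(species_key = species_key(
          .data$isoacceptor, .data$ts_class, .data$fragment_sequence
        )) |>
        select("tag_sequence", "species_key", "weight"),
      by = "tag_sequence", relationship = "many-to-many"
    ) |>
    group_by(.data$species_key, .data$sample_id) |>
    summarise(count = sum(.data$count * .data$weight), .groups = "drop")
}

#' Feature-level count matrix across samples
#'
#' Aggregates per-sample tag counts to reference features (one row per
#' `rna_class:reference`), using the winning-class alignment weights.
#' Reads carrying sequencing errors fold into the feature they align to,
#' so this is the expression profile used for replicate-correlation
#' figures; per-sequence tsRNA species (see [build_count_matrix()]) remain
#' the unit for classification and differential expression.
#'
#' @param annotation A `tsrna_annotation` over the union of tags.
#' @param sample_tags Long tag-count tibble (`sample_id`, `tag_sequence`,
#'   `count`).
#' @return Long tibble `species_key` (`<class>:<ref_id>`), `sample_id`,
#'   `count`.
#' @export
feature_count_matrix <- function(annotation, sample_tags) {
  if (inherits(annotation, "tsrna_annotation")) annotation <- annotation$alignments
  sample_tags |>
    inner_join(
      annotation |> select("tag_sequence", "rna_class", "ref_id", "weight"),
      by = "tag_sequence", relationship = "many-to-many"
    ) |>
    group_by(
      species_key = paste0(.data$rna_class, ":", .data$ref_id),
      .data$sample_id
    ) |>
    summarise(count = sum(.data$count * .data$weight), .groups = "drop")
}

#' Per-sample annotated library sizes
#'
#' Total weighted count of tags annotated to any small-RNA class (i.e.
#' everything but `other`) - the library-size denominator used for CPM.
#'
#' @param annotations Annotation tibble (`tag_sequence`, `count`,
#'   `rna_class`) for the union of tags.
#' @param sample_tags Long tag-count tibble (`sample_id`, `tag_sequence`,
#'   `count`).
#' @return Named numeric vector, one entry per sample.
#' @export
annotated_library_sizes <- function(annotations, sample_tags) {
  if (inherits(annotations, "tsrna_annotation")) annotations <- annotations$annotations
  sizes <- sample_tags |>
    inner_join(
      annotations |>
        filter(.data$rna_class != "other") |>
        distinct(.data$tag_sequence),
      by = "tag_sequence"
    ) |>
    group_by(.data$sample_id) |>
    summarise(n = sum(.data$count), .groups = "drop")
  setNames(sizes$n, sizes$sample_id)
}

#' Run the full tsRNA pipeline
#'
#' Preprocesses every sample in the sheet, annotates the union of tags
#' hierarchically, classifies tRNA tags into tsRNA records, profiles the
#' pooled records, and (when both groups have at least two samples) runs
#' differential expression. All tables are written as TSVs under
#' `out_dir`, together with a manifest recording parameter values, input
#' digests and stage conservation counts.
#'
#' @param sample_sheet Tibble (`sample_id`, `fastq_path`, `group`) or path
#'   to a sample-sheet TSV.
#' @param reference A `trna_reference`.
#' @param class_seqs Named list of per-class reference sequences.
#' @param out_dir Output directory.
#' @param adapter_3p,adapter_5p Adapter sequences for trimming.
#' @param max_mismatches Alignment mismatch allowance (default 1).
#' @param params [classifier_params()].
#' @param run_de `TRUE` to run differential expression (requires exactly
#'   two groups with >= 2 samples each); case group = the sheet's second
#'   group in sorted order unless `case`/`control` are given.
#' @param case,control Group labels for DE.
#' @param fdr,lfc,min_cpm DE thresholds.
#' @param priority Class priority for [annotate_tags()].
#' @return A list of class `tsrna_pipeline` with the in-memory results
#'   (`reports`, `annotation`, `records`, `counts`, `library_sizes`,
#'   `profile`, `de`) and `out_dir`.
#' @export
run_pipeline <- function(sample_sheet, reference, class_seqs, out_dir,
                         adapter_3p, adapter_5p = NULL, max_mismatches = 1L,
                         params = classifier_params(), run_de = FALSE,
                         case = NULL, control = NULL,
                         fdr = 0.05, lfc = 1, min_cpm = 5,
                         priority = c("miRNA", "tRNA", "rRNA", "snoRNA", "snRNA", "piRNA")) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  if (nrow(sample_sheet) == 0) abort_msg("sample sheet is empty")
  missing_files <- sample_sheet$fastq_path[!file.exists(sample_sheet$fastq_path)]
  if (length(missing_files) > 0) {
    abort_msg("missing FASTQ file(s): %s", paste(missing_files, collapse = ", "))
  }
  groups <- sort(unique(sample_sheet$group))
  if (run_de) {
    if (length(groups) != 2) {
      abort_msg("differential expression needs exactly 2 groups, found %d", length(groups))
    }
    tab <- table(sample_sheet$group)
    if (any(tab < 2)) {
      abort_msg(
        "differential expression needs >= 2 samples per group (%s has %d)",
        names(tab)[which.min(tab)], min(tab)
      )
    }
    if (is.null(control)) control <- groups[1]
    if (is.null(case)) case <- groups[2]
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  message("preprocessing ", nrow(sample_sheet), " sample(s)")
  pre <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    reads <- read_fastq(sample_sheet$fastq_path[i])
    preprocess_reads(reads, adapter_3p, adapter_5p)
  })
  names(pre) <- sample_sheet$sample_id
  reports <- bind_rows(lapply(pre, `[[`, "report"), .id = "sample_id")
  sample_tags <- bind_rows(lapply(pre, `[[`, "tags"), .id = "sample_id")

  message("annotating tag union")
  union_tags <- sample_tags |>
    group_by(.data$tag_sequence) |>
    summarise(count = sum(.data$count), .groups = "drop")
  index <- build_tag_index(reference_table(reference, class_seqs), max_mismatches)
  annotation <- annotate_tags(union_tags, index, max_mismatches, priority)

  message("classifying tsRNAs")
  records <- classify_tags(annotation, reference, params)
  counts <- build_count_matrix(records, sample_tags)
  feature_counts <- feature_count_matrix(annotation, sample_tags)
  library_sizes <- annotated_library_sizes(annotation, sample_tags)
  profile <- composition_profile(records, annotation)

  de <- NULL
  if (run_de) {
    message("differential expression: ", case, " vs ", control)
    de <- de_test(counts, sample_sheet,
      case = case, control = control,
      min_cpm = min_cpm, fdr = fdr, lfc = lfc, library_sizes = library_sizes
    )
    readr::write_tsv(de$results, file.path(out_dir, "de_results.tsv"))
  }

  readr::write_tsv(reports, file.path(out_dir, "preprocess_report.tsv"))
  readr::write_tsv(sample_tags, file.path(out_dir, "tags.tsv"))
  readr::write_tsv(annotation$annotations, file.path(out_dir, "annotations.tsv"))
  readr::write_tsv(records, file.path(out_dir, "tsrna_records.tsv"))
  readr::write_tsv(counts, file.path(out_dir, "count_matrix.tsv"))
  readr::write_tsv(feature_counts, file.path(out_dir, "feature_counts.tsv"))
  readr::write_tsv(profile$type_fractions, file.path(out_dir, "type_fractions.tsv"))
  readr::write_tsv(profile$length_histogram, file.path(out_dir, "length_histogram.tsv"))
  if (!is.null(profile$class_fractions)) {
    readr::write_tsv(profile$class_fractions, file.path(out_dir, "class_fractions.tsv"))
  }

  manifest <- c(
    sprintf("sample\t%s\t%s\tmd5:%s", sample_sheet$sample_id, sample_sheet$fastq_path,
      unname(tools::md5sum(sample_sheet$fastq_path))
    ),
    sprintf("param\tadapter_3p\t%s", adapter_3p),
    sprintf("param\tadapter_5p\t%s", adapter_5p %||% "."),
    sprintf("param\tmax_mismatches\t%d", max_mismatches),
    sprintf("param\t%s\t%s", names(params), unlist(params)),
    sprintf("param\trun_de\t%s", run_de),
    sprintf(
      "conservation\t%s\tin=%d,no_adapter=%d,quality=%d,length=%d,retained=%d",
      reports$sample_id, reports$reads_in, reports$discarded_no_adapter,
      reports$discarded_quality, reports$discarded_length, reports$reads_retained
    )
  )
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))

  structure(
    list(
      reports = reports, sample_tags = sample_tags, annotation = annotation,
      records = records, counts = counts, feature_counts = feature_counts,
      library_sizes = library_sizes, profile = profile, de = de,
      out_dir = out_dir
    ),
    class = "tsrna_pipeline"
  )
}

#' @export
print.tsrna_pipeline <- function(x, ...) {
  cat(sprintf(
    "<tsrna_pipeline> %d samples, %d tsRNA species -> %s\n",
    nrow(x$reports), dplyr::n_distinct(x$counts$species_key), x$out_dir
  ))
  invisible(x)
}
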