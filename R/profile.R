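# Descriptive profiles: small-RNA class composition, tsRNA type fractions,
# isoacceptor origins, length distributions, CPM normalisation, replicate
# correlation and delta-delta-Ct arithmetic.
#
# All fractions are computed over weighted READ counts (the convention
# behind published composition percentages); species-level fractions are
# available via `weight_by = "species"`.

record_weights <- function(records, weight_by) {
  if (weight_by == "reads") records$weighted_count else records$weight
}

#' Composition profile of a tsRNA record set
#'
#' Computes the small-RNA class composition (when annotations are given),
#' the tsRNA type fractions over the three mature-derived classes
#' (`tRNA-5`, `tRNA-i`, `tRNA-3`), the full class partition including
#' `3pU-tRF` and `unclassified`, per-type isoacceptor fractions, and
#' per-type length histograms over the 16-40 nt insert window.
#'
#' @param records tsRNA record tibble from [classify_tags()].
#' @param annotations Optional annotation tibble (`tag_sequence`, `count`,
#'   `rna_class`) from [annotate_tags()] for the class composition.
#' @param weight_by `"reads"` (weighted read counts, default) or
#'   `"species"` (each tag counted once).
#' @return An object of class `tsrna_profile`: a list of tibbles
#'   `class_fractions`, `type_fractions`, `type_partition`,
#'   `isoacceptor_fractions`, `length_histogram`.
#' @export
composition_profile <- function(records, annotations = NULL, weight_by = c("reads", "species")) {
  weight_by <- match.arg(weight_by)
  if (nrow(records) == 0) {
    abort_msg("composition_profile: empty record set")
  }
  w <- record_weights(records, weight_by)

  class_fractions <- NULL
  if (!is.null(annotations)) {
    if (inherits(annotations, "tsrna_annotation")) annotations <- annotations$annotations
    class_fractions <- annotations |>
      group_by(.data$rna_class) |>
      summarise(weight = sum(.data$count), .groups = "drop") |>
      mutate(fraction = .data$weight / sum(.data$weight)) |>
      arrange(dplyr::desc(.data$fraction))
  }

  partition <- records |>
    mutate(.w = w) |>
    group_by(.data$ts_class) |>
    summarise(weight = sum(.data$.w), .groups = "drop") |>
    mutate(fraction = .data$weight / sum(.data$weight))

  mature_classes <- c("tRNA-5", "tRNA-i", "tRNA-3")
  type_fractions <- partition |>
    filter(.data$ts_class %in% mature_classes) |>
    mutate(
      ts_class = factor(.data$ts_class, levels = mature_classes),
      fraction = .data$weight / sum(.data$weight)
    ) |>
    arrange(.data$ts_class) |>
    tidyr::complete(.data$ts_class, fill = list(weight = 0, fraction = 0)) |>
    mutate(ts_class = as.character(.data$ts_class))

  iso <- records |>
    mutate(.w = w) |>
    filter(.data$ts_class %in% mature_classes, !is.na(.data$isoacceptor)) |>
    group_by(.data$ts_class, .data$isoacceptor) |>
    summarise(weight = sum(.data$.w), .groups = "drop_last") |>
    mutate(fraction = .data$weight / sum(.data$weight)) |>
    ungroup()

  hist <- length_distribution(records, weight_by = weight_by)

  structure(
    list(
      class_fractions = class_fractions,
      type_fractions = type_fractions,
      type_partition = partition,
      isoacceptor_fractions = iso,
      length_histogram = hist
    ),
    class = "tsrna_profile"
  )
}

#' @export
print.tsrna_profile <- function(x, ...) {
  cat("<tsrna_profile>\n")
  if (!is.null(x$class_fractions)) {
    cat("small-RNA classes:\n")
    print(x$class_fractions)
  }
  cat("tsRNA types (mature-derived):\n")
  print(x$type_fractions)
  invisible(x)
}

#' Isoacceptor origin breakdown for one tsRNA type
#'
#' @inheritParams composition_profile
#' @param type A tsRNA class, e.g. `"tRNA-5"`.
#' @return Tibble `isoacceptor`, `weight`, `fraction` (summing to 1).
#' @export
isoacceptor_breakdown <- function(records, type, weight_by = c("reads", "species")) {
  weight_by <- match.arg(weight_by)
  sel <- records |>
    mutate(.w = record_weights(records, weight_by)) |>
    filter(.data$ts_class == type, !is.na(.data$isoacceptor))
  if (nrow(sel) == 0) abort_msg("no records of type %s", type)
  sel |>
    group_by(.data$isoacceptor) |>
    summarise(weight = sum(.data$.w), .groups = "drop") |>
    mutate(fraction = .data$weight / sum(.data$weight)) |>
    arrange(dplyr::desc(.data$fraction))
}

#' Weighted length distribution of tsRNA records
#'
#' Integer-binned histogram over the 16-40 nt insert window (zero bins
#' included), per type or overall.
#'
#' @inheritParams composition_profile
#' @param type Optional tsRNA class to restrict to; `NULL` keeps all
#'   classes, binned per class.
#' @param bins Integer bin support (default `16:40`).
#' @return Tibble `ts_class`, `length`, `weight`, `fraction`; the modal
#'   length per class is in attribute `mode`.
#' @export
length_distribution <- function(records, type = NULL, bins = 16:40,
                                weight_by = c("reads", "species")) {
  weight_by <- match.arg(weight_by)
  sel <- records |> mutate(.w = record_weights(records, weight_by))
  if (!is.null(type)) sel <- filter(sel, .data$ts_class == type)
  if (nrow(sel) == 0) abort_msg("no records to bin")
  if (any(!sel$length %in% bins)) {
    abort_msg("record length outside the %d-%d nt window", min(bins), max(bins))
  }
  out <- sel |>
    group_by(
      ts_class = .data$ts_class,
      length = factor(.data$length, levels = bins)
    ) |>
    summarise(weight = sum(.data$.w), .groups = "drop_last") |>
    tidyr::complete(.data$length, fill = list(weight = 0)) |>
    mutate(fraction = .data$weight / sum(.data$weight)) |>
    ungroup() |>
    mutate(length = as.integer(as.character(.data$length)))
  modes <- out |>
    group_by(.data$ts_class) |>
    summarise(mode = .data$length[which.max(.data$weight)], .groups = "drop")
  attr(out, "mode") <- setNames(modes$mode, modes$ts_class)
  out
}

#' Counts-per-million normalisation
#'
#' Adds a `cpm` column: `count * 1e6 / library size`. The library size of
#' a sample defaults to its total count in `counts`, but should be the
#' sample's total annotated small-RNA count when `counts` holds a subset
#' (e.g. only tsRNA species).
#'
#' @param counts Long count tibble: `species_key`, `sample_id`, `count`.
#' @param library_sizes Optional named vector of per-sample library sizes.
#' @return `counts` with a `cpm` column.
#' @export
cpm_normalize <- function(counts, library_sizes = NULL) {
  if (is.null(library_sizes)) {
    library_sizes <- counts |>
      group_by(.data$sample_id) |>
      summarise(n = sum(.data$count), .groups = "drop")
    library_sizes <- setNames(library_sizes$n, library_sizes$sample_id)
  }
  if (any(library_sizes[unique(counts$sample_id)] <= 0)) {
    abort_msg("library sizes must be positive")
  }
  mutate(counts, cpm = .data$count * 1e6 / unname(library_sizes[.data$sample_id]))
}

#' Replicate correlation on log2(CPM + 1)
#'
#' Pearson correlation of two samples' log2(CPM + 1) over the union of
#' species present in either sample (a species absent from one sample
#' counts 0 there; intersecting instead would inflate r).
#'
#' @inheritParams cpm_normalize
#' @param sample_a,sample_b Sample ids present in `counts`.
#' @return Pearson r (single numeric).
#' @export
replicate_correlation <- function(counts, sample_a, sample_b, library_sizes = NULL) {
  sel <- filter(counts, .data$sample_id %in% c(sample_a, sample_b))
  if (length(unique(sel$sample_id)) < 2) {
    abort_msg("both samples must be present in the count table")
  }
  wide <- sel |>
    cpm_normalize(library_sizes) |>
    select("species_key", "sample_id", "cpm") |>
    tidyr::pivot_wider(
      names_from = "sample_id", values_from = "cpm", values_fill = 0
    )
  cor(log2(wide[[sample_a]] + 1), log2(wide[[sample_b]] + 1))
}

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-((Ct_target_case - Ct_ref_case) - (Ct_target_ctrl - Ct_ref_ctrl))`,
#' the standard qPCR relative quantification with a reference species
#' (e.g. miR-16) as normaliser.
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference in the
#'   condition of interest.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference in the
#'   control condition.
#' @return Fold change(s), vectorised over the inputs.
#' @export
#' @examples
#' ddct_fold_change(20, 15, 21, 15) # one cycle advantage -> 2
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  2^-((ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl))
}
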