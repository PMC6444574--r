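# Two-group differential tsRNA expression: low-expression filtering,
# per-species Welch t-tests on log2(CPM + 1), Benjamini-Hochberg FDR,
# and up/down calling.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_i = min_{p_(j) >= p_(i)} p_(j) * m / j`,
#' clipped to 1), delegated to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Remove species too weakly expressed to test
#'
#' Keeps species with CPM at least `min_cpm` in at least `min_samples`
#' samples (both bounds inclusive). `min_samples` defaults to the size of
#' the smaller group, so a species expressed consistently in one group
#' survives even if absent from the other.
#'
#' @param counts Long count tibble: `species_key`, `sample_id`, `count`.
#' @param samples Sample sheet tibble with `sample_id` and `group`.
#' @param min_cpm CPM threshold (default 5).
#' @param min_samples Number of samples required at or above `min_cpm`.
#' @param library_sizes Optional named per-sample library sizes (defaults
#'   to column sums of `counts`).
#' @return The filtered `counts`.
#' @export
filter_low_expression <- function(counts, samples, min_cpm = 5,
                                  min_samples = NULL, library_sizes = NULL) {
  if (is.null(min_samples)) {
    min_samples <- min(table(samples$group))
  }
  keep <- counts |>
    cpm_normalize(library_sizes) |>
    group_by(.data$species_key) |>
    summarise(n_expressed = sum(.data$cpm >= min_cpm), .groups = "drop") |>
    filter(.data$n_expressed >= min_samples)
  dplyr::semi_join(counts, keep, by = "species_key")
}

#' Two-group differential expression test
#'
#' Per-species two-sided Welch t-test on log2(CPM + 1) between the case
#' and control groups, after low-expression filtering; Benjamini-Hochberg
#' adjustment across the tested species (m is the post-filter count). The
#' log2 fold change is the difference of group means of log2(CPM + 1),
#' case minus control. Species with zero variance in both groups get
#' p = 1 when the means are equal and p = 0 (flagged `degenerate`) when
#' they differ.
#'
#' @inheritParams filter_low_expression
#' @param case,control Values of `samples$group` labelling the two groups
#'   (defaults `"case"` and `"control"`).
#' @param fdr,lfc Calling thresholds: a species is `up` iff
#'   `q <= fdr` and `log2FC >= lfc`, `down` symmetrically (defaults 0.05
#'   and 1).
#' @return An object of class `tsrna_de`; see [tidy.tsrna_de()] and
#'   [glance.tsrna_de()].
#' @export
de_test <- function(counts, samples, case = "case", control = "control",
                    min_cpm = 5, min_samples = NULL, fdr = 0.05, lfc = 1,
                    library_sizes = NULL) {
  samples <- filter(samples, .data$group %in% c(case, control))
  for (g in c(case, control)) {
    if (sum(samples$group == g) < 2) {
      abort_msg("group '%s' has fewer than 2 samples", g)
    }
  }
  counts <- filter(counts, .data$sample_id %in% samples$sample_id)
  filtered <- filter_low_expression(counts, samples, min_cpm, min_samples, library_sizes)
  if (nrow(filtered) == 0) abort_msg("no species pass the expression filter")
  cpm_wide <- filtered |>
    cpm_normalize(library_sizes) |>
    select("species_key", "sample_id", "cpm") |>
    tidyr::pivot_wider(
      names_from = "sample_id", values_from = "cpm", values_fill = 0
    )
  cpm_mat <- as.matrix(cpm_wide[, -1])
  case_ids <- samples$sample_id[samples$group == case]
  ctrl_ids <- samples$sample_id[samples$group == control]
  # samples absent from the (filtered) count table have all-zero counts
  missing <- setdiff(c(case_ids, ctrl_ids), colnames(cpm_mat))
  if (length(missing) > 0) {
    cpm_mat <- cbind(cpm_mat, matrix(0, nrow(cpm_mat), length(missing),
      dimnames = list(NULL, missing)
    ))
  }
  mat <- log2(cpm_mat + 1)
  x <- mat[, case_ids, drop = FALSE]
  y <- mat[, ctrl_ids, drop = FALSE]
  n1 <- ncol(x)
  n2 <- ncol(y)
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var)
  v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  novar <- se2 == 0
  p[novar] <- ifelse(m1[novar] == m2[novar], 1, 0)
  degenerate <- novar & m1 != m2
  q <- bh_adjust(p)
  log2fc <- m1 - m2
  results <- tibble(
    species_key = cpm_wide$species_key,
    mean_cpm_case = rowMeans(cpm_mat[, case_ids, drop = FALSE]),
    mean_cpm_control = rowMeans(cpm_mat[, ctrl_ids, drop = FALSE]),
    log2_fold_change = log2fc,
    p_value = p,
    q_value = q,
    degenerate = degenerate
  ) |>
    mutate(call = dplyr::case_when(
      .data$q_value <= fdr & .data$log2_fold_change >= lfc ~ "up",
      .data$q_value <= fdr & .data$log2_fold_change <= -lfc ~ "down",
      .default = "ns"
    )) |>
    select(
      "species_key", "mean_cpm_case", "mean_cpm_control",
      "log2_fold_change", "p_value", "q_value", "degenerate", "call"
    ) |>
    arrange(.data$q_value, .data$p_value, .data$species_key)
  structure(
    list(
      results = results,
      params = list(
        case = case, control = control, fdr = fdr, lfc = lfc,
        min_cpm = min_cpm, n_case = n1, n_control = n2,
        n_tested = nrow(results),
        n_input_species = dplyr::n_distinct(counts$species_key)
      )
    ),
    class = "tsrna_de"
  )
}

#' Call up- and down-regulated species
#'
#' Deterministic partition of a DE result by the calling rule
#' (`q <= fdr` and `|log2FC| >= lfc`).
#'
#' @param de A `tsrna_de` object (or its `results` tibble).
#' @param fdr,lfc Thresholds; default to those stored in the fit (or
#'   0.05 / 1 for a bare tibble).
#' @return List with character vectors `up` and `down` and the counts
#'   `n_up`, `n_down`.
#' @export
call_de <- function(de, fdr = NULL, lfc = NULL) {
  res <- if (inherits(de, "tsrna_de")) de$results else de
  fdr <- fdr %||% (if (inherits(de, "tsrna_de")) de$params$fdr else 0.05)
  lfc <- lfc %||% (if (inherits(de, "tsrna_de")) de$params$lfc else 1)
  up <- res$species_key[res$q_value <= fdr & res$log2_fold_change >= lfc]
  down <- res$species_key[res$q_value <= fdr & res$log2_fold_change <= -lfc]
  list(up = up, down = down, n_up = length(up), n_down = length(down))
}

#' @export
print.tsrna_de <- function(x, ...) {
  calls <- call_de(x)
  cat(sprintf(
    "<tsrna_de> %d species tested (%s vs %s): %d up, %d down at q<=%g, |log2FC|>=%g\n",
    x$params$n_tested, x$params$case, x$params$control,
    calls$n_up, calls$n_down, x$params$fdr, x$params$lfc
  ))
  invisible(x)
}
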