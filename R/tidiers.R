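# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-expression fit
#'
#' @param x A `tsrna_de`.
#' @param ... Unused.
#' @return The per-species results tibble (`species_key`, group mean CPMs,
#'   `log2_fold_change`, `p_value`, `q_value`, `degenerate`, `call`),
#'   sorted by q.
#' @export
tidy.tsrna_de <- function(x, ...) {
  x$results
}

#' One-row summary of a differential-expression fit
#'
#' @param x A `tsrna_de`.
#' @param ... Unused.
#' @return One-row tibble: group sizes, species counts before and after
#'   filtering, up/down call counts, thresholds.
#' @export
glance.tsrna_de <- function(x, ...) {
  calls <- call_de(x)
  tibble(
    n_case = x$params$n_case,
    n_control = x$params$n_control,
    n_input_species = x$params$n_input_species,
    n_tested = x$params$n_tested,
    n_up = calls$n_up,
    n_down = calls$n_down,
    fdr = x$params$fdr,
    lfc = x$params$lfc
  )
}

#' Tidy a preprocessing result
#'
#' @param x A `tsrna_preprocess`.
#' @param ... Unused.
#' @return The collapsed tag tibble.
#' @export
tidy.tsrna_preprocess <- function(x, ...) x$tags

#' One-row conservation summary of a preprocessing result
#'
#' @param x A `tsrna_preprocess`.
#' @param ... Unused.
#' @return The one-row conservation report.
#' @export
glance.tsrna_preprocess <- function(x, ...) x$report

#' Tidy a composition profile
#'
#' @param x A `tsrna_profile`.
#' @param ... Unused.
#' @return Long tibble with a `metric` column binding the profile's
#'   fraction tables.
#' @export
tidy.tsrna_profile <- function(x, ...) {
  parts <- list(
    type_fraction = x$type_fractions |> rename(label = "ts_class"),
    type_partition = x$type_partition |> rename(label = "ts_class"),
    isoacceptor_fraction = x$isoacceptor_fractions |>
      mutate(label = paste(.data$ts_class, .data$isoacceptor, sep = ":")) |>
      select("label", "weight", "fraction")
  )
  if (!is.null(x$class_fractions)) {
    parts$class_fraction <- x$class_fractions |> rename(label = "rna_class")
  }
  bind_rows(parts, .id = "metric")
}
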