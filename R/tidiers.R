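# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-splicing result
#' @param x A `splice_diff` tibble.
#' @param ... Unused.
#' @return A plain tibble (one row per event).
#' @export
tidy.splice_diff <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "splice_diff")
  out
}

#' One-row summary of a differential-splicing result
#' @param x A `splice_diff` tibble.
#' @param ... Unused.
#' @return Tibble with event counts at the standard thresholds.
#' @export
glance.splice_diff <- function(x, ...) {
  tibble(
    n_events = nrow(x),
    n_testable = sum(x$testable, na.rm = TRUE),
    n_significant_010 = sum(x$significant_010, na.rm = TRUE),
    n_significant_025 = sum(x$significant_025, na.rm = TRUE),
    n_novel = if ("novel" %in% names(x)) sum(x$novel, na.rm = TRUE)
    else NA_integer_
  )
}

#' Tidy a cryptic 3' splice-site signature
#' @param x An `"a3ss_signature"`.
#' @param ... Unused.
#' @return Tibble of per-event signed distances.
#' @export
tidy.a3ss_signature <- function(x, ...) x$distances

#' One-row summary of a cryptic 3' splice-site signature
#' @param x An `"a3ss_signature"`.
#' @param ... Unused.
#' @return Tibble with `n_events`, `mean_abs_d`, `mode_abs_d`,
#'   `p_downstream`, `n_excluded`.
#' @export
glance.a3ss_signature <- function(x, ...) {
  s <- x$summary
  tibble(n_events = s$n_events, mean_abs_d = s$mean_abs_d,
         mode_abs_d = s$mode_abs_d, p_downstream = s$p_downstream,
         n_excluded = x$n_excluded)
}

#' Tidy a phenotype clustering
#' @param x A `"pheno_cluster"`.
#' @param ... Unused.
#' @return Tibble of patient cluster assignments.
#' @export
tidy.pheno_cluster <- function(x, ...) x$clusters

#' One-row summary of a phenotype clustering
#' @param x A `"pheno_cluster"`.
#' @param ... Unused.
#' @return Tibble with patient/feature/cluster counts and the final merge
#'   height.
#' @export
glance.pheno_cluster <- function(x, ...) {
  tibble(
    n_patients = nrow(x$clusters),
    n_features = length(setdiff(names(x$data), c("patient", "variant"))),
    k = x$k,
    max_height = max(x$hclust$height)
  )
}

#' Tidy an overlap report
#' @param x An `"overlap_report"`.
#' @param ... Unused.
#' @return Tibble of exclusive subset sizes.
#' @export
tidy.overlap_report <- function(x, ...) {
  select(x$exclusive, "subset", "degree", "size")
}

#' One-row-per-condition summary of an overlap report
#' @param x An `"overlap_report"`.
#' @param ... Unused.
#' @return Tibble with totals and condition-specific counts.
#' @export
glance.overlap_report <- function(x, ...) {
  left_join(x$totals, x$specific, by = "condition")
}
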