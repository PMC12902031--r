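# Two-group differential splicing: delta PSI, binomial likelihood-ratio
# test, BH correction, threshold presets and per-gene deduplication.

#' Difference of group mean PSI
#'
#' Mean PSI difference (variant minus wild type) over defined values;
#' antisymmetric under group swap. `NA` when either group has no defined
#' PSI (untestable event).
#'
#' @param psi_wt,psi_var Numeric PSI vectors (NA = undefined).
#' @return Signed difference in `[-1, 1]`, or `NA`.
#' @examples
#' delta_psi(c(0.2, 0.2, 0.2), c(0.5, 0.5, 0.5))
#' @export
delta_psi <- function(psi_wt, psi_var) {
  if (all(is.na(psi_wt)) || all(is.na(psi_var))) return(NA_real_)
  mean(psi_var, na.rm = TRUE) - mean(psi_wt, na.rm = TRUE)
}

#' Binomial likelihood-ratio test for one splicing event
#'
#' Tests whether the read-level inclusion proportion differs between two
#' groups. Null model: one shared binomial proportion across all
#' replicates; alternative: one proportion per group. The statistic
#' `2 * (llik_alt - llik_null)` is referred to a chi-square with 1 df.
#' Replicate counts are pooled by the binomial MLE, making this the G-test
#' of the pooled 2x2 table; it is calibrated when within-group replicate
#' variation is binomial.
#'
#' @param inc,skip Integer vectors of inclusion/skipping read counts per
#'   replicate.
#' @param group Group labels (two levels) per replicate.
#' @return List with `statistic`, `p_value` (NA when untestable: all
#'   counts zero or a group fully undefined).
#' @export
test_event <- function(inc, skip, group) {
  stopifnot(length(inc) == length(skip), length(group) == length(inc))
  if (any(inc < 0) || any(skip < 0)) abort("Counts must be non-negative.")
  tot <- inc + skip
  g <- as.character(group)
  lv <- unique(g)
  if (length(lv) != 2) abort("Exactly two groups are required.")
  if (sum(tot) == 0 || sum(tot[g == lv[1]]) == 0 ||
      sum(tot[g == lv[2]]) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  ll <- function(i, n) {
    q <- sum(i) / sum(n)
    sum(dbinom(i, n, q, log = TRUE))
  }
  ll0 <- ll(inc, tot)
  ll1 <- ll(inc[g == lv[1]], tot[g == lv[1]]) +
    ll(inc[g == lv[2]], tot[g == lv[2]])
  lr <- max(0, 2 * (ll1 - ll0))
  list(statistic = lr, p_value = pchisq(lr, df = 1, lower.tail = FALSE))
}

#' Differential splicing analysis over all events
#'
#' Computes per-event group mean PSIs, delta PSI (variant minus wild
#' type), the likelihood-ratio p-value and BH-adjusted FDR (over testable
#' events only), plus significance flags at the conventional |delta PSI|
#' cutoffs 0.10 and 0.25 (both with max-group PSI >= 0.1 and FDR < 0.05).
#'
#' @param psi PSI records from [compute_psi()] with a `group` column (or
#'   supply `sample_groups`).
#' @param catalog Optional catalog tibble; joins class, novelty, gene and
#'   coordinate columns onto the result.
#' @param sample_groups Optional tibble (`sample`, `group`) if `psi` lacks
#'   a `group` column. Groups must be named `"wt"` and `"var"`.
#' @return A `splice_diff` tibble: one row per event with `mean_psi_wt`,
#'   `mean_psi_var`, `delta_psi`, `p_value`, `fdr`, `mean_reads`,
#'   `testable`, `significant_010`, `significant_025`.
#' @export
diff_splice <- function(psi, catalog = NULL, sample_groups = NULL) {
  if (!"group" %in% names(psi)) {
    if (is.null(sample_groups)) {
      abort("`psi` has no group column; supply `sample_groups`.")
    }
    psi <- left_join(psi, sample_groups, by = "sample")
  }
  if (!all(c("wt", "var") %in% unique(psi$group))) {
    abort('Groups must be labelled "wt" and "var".')
  }
  res <- psi %>%
    group_by(.data$event_id) %>%
    summarise(
      mean_psi_wt = if (all(is.na(.data$psi[.data$group == "wt"])))
        NA_real_ else mean(.data$psi[.data$group == "wt"], na.rm = TRUE),
      mean_psi_var = if (all(is.na(.data$psi[.data$group == "var"])))
        NA_real_ else mean(.data$psi[.data$group == "var"], na.rm = TRUE),
      mean_reads = mean(.data$inc_count + .data$skip_count),
      p_value = test_event(.data$inc_count, .data$skip_count,
                           .data$group)$p_value,
      .groups = "drop"
    ) %>%
    mutate(
      delta_psi = .data$mean_psi_var - .data$mean_psi_wt,
      testable = !is.na(.data$p_value) & !is.na(.data$delta_psi),
      p_value = ifelse(.data$testable, .data$p_value, NA_real_),
      fdr = bh_fdr(.data$p_value)
    )
  if (!is.null(catalog) && nrow(catalog) > 0) {
    res <- left_join(
      res,
      select(catalog, "event_id", "class", "contig", "strand", "gene_id",
             "novel", "donor", "acc_proximal", "acc_distal",
             "inc_junc", "skip_junc"),
      by = "event_id")
  }
  res <- res %>%
    mutate(
      significant_010 = sig_flag(res, min_psi = 0.1,
                                 min_abs_delta_psi = 0.1, max_fdr = 0.05),
      significant_025 = sig_flag(res, min_psi = 0.1,
                                 min_abs_delta_psi = 0.25, max_fdr = 0.05)
    ) %>%
    arrange(.data$event_id)
  class(res) <- c("splice_diff", class(res))
  res
}

sig_flag <- function(res, min_psi, min_abs_delta_psi, max_fdr,
                     min_mean_reads = 0) {
  with(res,
       testable &
         pmax(mean_psi_wt, mean_psi_var) >= min_psi &
         abs(delta_psi) >= min_abs_delta_psi &
         !is.na(fdr) & fdr < max_fdr &
         mean_reads >= min_mean_reads)
}

#' Threshold presets for declaring significant events
#'
#' * `"k562_default"` — max-group PSI >= 0.1, |delta PSI| >= 0.1,
#'   FDR < 0.05, mean coverage >= 10 (the transcriptome-wide cell-line
#'   preset).
#' * `"k562_strict"` — as above with |delta PSI| >= 0.25.
#' * `"lymphocyte"` — |delta PSI| >= 0.05, FDR < 0.1, mean coverage >= 10,
#'   one event per gene and class (the patient-lymphocyte preset).
#'
#' @param name Preset name, or use the arguments to build a custom preset.
#' @param min_psi,min_abs_delta_psi,max_fdr,min_mean_reads,dedup_per_gene
#'   Explicit overrides of the named preset's values.
#' @return A list of class `"threshold_preset"`.
#' @export
threshold_preset <- function(name = "k562_default", min_psi = NULL,
                             min_abs_delta_psi = NULL, max_fdr = NULL,
                             min_mean_reads = NULL, dedup_per_gene = NULL) {
  presets <- list(
    k562_default = list(min_psi = 0.1, min_abs_delta_psi = 0.1,
                        max_fdr = 0.05, min_mean_reads = 10,
                        dedup_per_gene = FALSE),
    k562_strict = list(min_psi = 0.1, min_abs_delta_psi = 0.25,
                       max_fdr = 0.05, min_mean_reads = 10,
                       dedup_per_gene = FALSE),
    lymphocyte = list(min_psi = 0, min_abs_delta_psi = 0.05,
                      max_fdr = 0.1, min_mean_reads = 10,
                      dedup_per_gene = TRUE)
  )
  if (!name %in% names(presets)) {
    abort(sprintf("Unknown threshold preset %s. Valid: %s.", deparse(name),
                  paste(names(presets), collapse = ", ")))
  }
  p <- presets[[name]]
  p$min_psi <- min_psi %||% p$min_psi
  p$min_abs_delta_psi <- min_abs_delta_psi %||% p$min_abs_delta_psi
  p$max_fdr <- max_fdr %||% p$max_fdr
  p$min_mean_reads <- min_mean_reads %||% p$min_mean_reads
  p$dedup_per_gene <- dedup_per_gene %||% p$dedup_per_gene
  assert_fraction(p$min_psi, "min_psi")
  assert_fraction(p$min_abs_delta_psi, "min_abs_delta_psi")
  assert_fraction(p$max_fdr, "max_fdr")
  if (p$min_mean_reads < 0) abort("`min_mean_reads` must be >= 0.")
  p$name <- name
  structure(p, class = "threshold_preset")
}

#' Apply a threshold preset to differential records
#'
#' Retains events with max-group mean PSI >= `min_psi`, |delta PSI| >=
#' `min_abs_delta_psi`, FDR < `max_fdr` and mean coverage >=
#' `min_mean_reads`; optionally keeps only the most significant event per
#' gene and class. Stricter delta-PSI presets always select subsets of
#' looser ones.
#'
#' @param diff A `splice_diff` tibble.
#' @param preset A [threshold_preset()].
#' @return The significant subset, same columns as `diff`.
#' @export
apply_thresholds <- function(diff, preset = threshold_preset()) {
  stopifnot(inherits(preset, "threshold_preset"))
  keep <- sig_flag(diff, preset$min_psi, preset$min_abs_delta_psi,
                   preset$max_fdr, preset$min_mean_reads)
  out <- diff[keep, , drop = FALSE]
  if (isTRUE(preset$dedup_per_gene)) out <- dedup_per_gene(out)
  out
}

#' Keep one event per gene and splicing class
#'
#' Within each (gene, class) pair, retains the record with the smallest
#' FDR, breaking ties by smaller p-value and then lexicographic event id.
#' Records without gene attribution are kept as-is.
#'
#' @param diff A `splice_diff` tibble with `gene_id` and `class` columns.
#' @return Deduplicated records.
#' @export
dedup_per_gene <- function(diff) {
  if (!all(c("gene_id", "class") %in% names(diff))) {
    abort("`diff` must carry gene_id and class columns (join a catalog).")
  }
  no_gene <- filter(diff, is.na(.data$gene_id))
  kept <- diff %>%
    filter(!is.na(.data$gene_id)) %>%
    arrange(.data$fdr, .data$p_value, .data$event_id) %>%
    group_by(.data$gene_id, .data$class) %>%
    dplyr::slice_head(n = 1L) %>%
    ungroup()
  bind_rows(kept, no_gene) %>% arrange(.data$event_id)
}
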