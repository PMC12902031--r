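# Cross-condition event-set overlap analysis and event-class proportion
# tests.

#' Multiway overlap report for per-condition event sets
#'
#' Events are compared across conditions by their coordinate-based keys
#' (see [event_key()]), not by gene symbols, so identical junction events
#' from independent runs over the same genome match exactly. The report
#' gives, for every non-empty subset of conditions, the number of events
#' whose membership pattern is exactly that subset (an UpSet-style
#' decomposition), plus per-condition totals, condition-specific counts
#' and pairwise shared fractions.
#'
#' @param sets Named list (>= 2, <= 12 conditions) of character vectors of
#'   event keys.
#' @return List of class `"overlap_report"`: `totals`, `exclusive`
#'   (tibble: subset label, member conditions, size), `pairwise` (tibble:
#'   `condition`, `reference`, `intersection`, `shared_fraction`),
#'   `specific` (events unique to each condition) and `membership`
#'   (events x conditions 0/1 tibble).
#' @examples
#' intersect_events(list(a = c("e1", "e2"), b = c("e2", "e3")))
#' @export
intersect_events <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list of event-key vectors.")
  }
  k <- length(sets)
  if (k < 2) abort("At least two conditions are required.")
  if (k > 12) abort("More than 12 conditions: refusing (2^k subsets).")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  conds <- names(sets)
  all_ev <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) all_ev %in% s,
                 logical(length(all_ev)))
  if (length(all_ev) == 1L) memb <- matrix(memb, nrow = 1L,
                                           dimnames = list(NULL, conds))
  pattern <- apply(memb, 1L, function(r) paste(conds[r], collapse = "&"))
  exclusive <- tibble(subset = pattern) %>%
    count(.data$subset, name = "size") %>%
    mutate(conditions = stringr::str_split(.data$subset, "&"),
           degree = lengths(.data$conditions)) %>%
    arrange(dplyr::desc(.data$degree), .data$subset)

  totals <- tibble(condition = conds,
                   total = vapply(sets, length, integer(1)))
  pairwise <- tidyr::expand_grid(condition = conds, reference = conds) %>%
    filter(.data$condition != .data$reference) %>%
    mutate(
      intersection = purrr::map2_int(.data$condition, .data$reference,
                                     function(a, b) {
        length(intersect(sets[[a]], sets[[b]]))
      }),
      shared_fraction = unname(
        .data$intersection /
          totals$total[match(.data$condition, totals$condition)])
    )
  specific <- tibble(
    condition = conds,
    specific = unname(vapply(conds, function(cn) {
      sum(pattern[memb[, cn]] == cn)
    }, integer(1)))
  )
  membership <- as_tibble(memb * 1L) %>%
    mutate(event = all_ev, .before = 1L)
  structure(list(totals = totals, exclusive = exclusive,
                 pairwise = pairwise, specific = specific,
                 membership = membership),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Event-set overlap report\n")
  print(left_join(x$totals, x$specific, by = "condition"))
  cat("Exclusive subset sizes:\n")
  print(select(x$exclusive, "subset", "size"))
  invisible(x)
}

#' UpSet membership matrix
#'
#' @param report An `"overlap_report"` (or a named list of sets, which is
#'   converted first).
#' @return Tibble of events x conditions with 0/1 membership, consumable
#'   by UpSet plotters.
#' @export
upset_matrix <- function(report) {
  if (!inherits(report, "overlap_report")) report <- intersect_events(report)
  report$membership
}

#' Compare event-class proportions between two conditions
#'
#' For each splicing class, tests whether the class's share of all
#' significant events differs between two conditions, with the 2x2
#' chi-square test (Yates continuity correction) and BH adjustment across
#' classes. Symmetric in the two conditions.
#'
#' @param counts Tibble with columns `class`, `n1`, `n2` (events of that
#'   class per condition). Totals are the column sums.
#' @return Tibble with per-class proportions, `p_value` and `fdr`;
#'   classes with a zero total in either condition are marked untestable
#'   (`NA` p).
#' @export
class_proportion_compare <- function(counts) {
  stopifnot(all(c("class", "n1", "n2") %in% names(counts)))
  t1 <- sum(counts$n1); t2 <- sum(counts$n2)
  if (t1 == 0 || t2 == 0) abort("Zero total events in a condition.")
  res <- counts %>%
    mutate(
      prop1 = .data$n1 / t1,
      prop2 = .data$n2 / t2,
      p_value = purrr::map2_dbl(.data$n1, .data$n2, function(k1, k2) {
        two_proportion_test(k1, t1, k2, t2)$p_value
      }),
      fdr = bh_fdr(.data$p_value)
    )
  res
}
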