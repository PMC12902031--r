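# Clinical phenotype matrix encoding and hierarchical clustering with
# missing data retained.

PHENO_LEVELS <- c(absent = 0, mild = 0.5, present = 1)

#' Encode a clinical feature table on the 0 / 0.5 / 1 scale
#'
#' Maps the categorical severity levels `absent` -> 0, `mild` (present,
#' mild) -> 0.5, `present` (moderate to severe) -> 1 and `unknown` (or
#' `NA`) -> missing. Any other level is an error naming the offending
#' patient and feature.
#'
#' @param raw Tibble with a `patient` column and one character column per
#'   clinical feature. An optional `variant` column (e.g. the
#'   missense/pLoF category of each patient) is carried through unchanged.
#' @return Tibble of class `"pheno_matrix"`: `patient` (and `variant`, if
#'   present) plus numeric feature columns with values in
#'   \{0, 0.5, 1, NA\}.
#' @export
encode_phenotypes <- function(raw) {
  if (!"patient" %in% names(raw)) abort("`raw` needs a `patient` column.")
  feats <- setdiff(names(raw), c("patient", "variant"))
  if (length(feats) == 0) abort("No feature columns found.")
  out <- raw
  for (f in feats) {
    v <- tolower(trimws(as.character(raw[[f]])))
    v[v %in% c("unknown", "na", "")] <- NA
    bad <- !is.na(v) & !v %in% names(PHENO_LEVELS)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("Unrecognised level %s for patient %s, feature %s.",
                    deparse(raw[[f]][i]), raw$patient[i], f))
    }
    out[[f]] <- unname(PHENO_LEVELS[v])
  }
  class(out) <- c("pheno_matrix", class(out))
  out
}

#' Decode an encoded phenotype matrix back to text levels
#'
#' Inverse of [encode_phenotypes()] (missing becomes `"unknown"`).
#'
#' @param encoded A `"pheno_matrix"` tibble.
#' @return Tibble of text levels.
#' @export
decode_phenotypes <- function(encoded) {
  feats <- setdiff(names(encoded), c("patient", "variant"))
  out <- as_tibble(encoded)
  lvl <- setNames(names(PHENO_LEVELS), as.character(PHENO_LEVELS))
  for (f in feats) {
    v <- lvl[as.character(out[[f]])]
    v[is.na(v)] <- "unknown"
    out[[f]] <- unname(v)
  }
  out
}

#' Drop features with too much missing data
#'
#' Removes features whose missing fraction across patients is strictly
#' greater than `max_missing` (default 0.30, the usual sensitivity-analysis
#' cutoff); the removed features are reported.
#'
#' @param encoded A `"pheno_matrix"` tibble.
#' @param max_missing Maximum tolerated missing fraction.
#' @return Filtered `"pheno_matrix"`, with attribute `removed_features`.
#' @export
missingness_filter <- function(encoded, max_missing = 0.30) {
  assert_fraction(max_missing, "max_missing")
  feats <- setdiff(names(encoded), c("patient", "variant"))
  miss <- vapply(feats, function(f) mean(is.na(encoded[[f]])), numeric(1))
  drop <- feats[miss > max_missing]
  if (length(drop) == length(feats)) {
    abort("All features exceed the missingness threshold.")
  }
  if (length(drop)) {
    inform(sprintf("Removed %d feature(s) with > %.0f%% missing: %s",
                   length(drop), 100 * max_missing,
                   paste(drop, collapse = ", ")))
  }
  out <- select(encoded, -all_of(drop))
  attr(out, "removed_features") <- drop
  class(out) <- unique(c("pheno_matrix", class(out)))
  out
}

#' Hierarchically cluster patients with missing data retained
#'
#' Pairwise distance is Euclidean over pairwise-complete features,
#' rescaled by `sqrt(n_features / n_shared)` (the behaviour of
#' [stats::dist()] with `NA`s), followed by Ward (`ward.D2`) linkage and a
#' cut at `k` groups. The partition is invariant to patient order (ties in
#' merge heights are resolved by the linkage algorithm on sorted input).
#'
#' @param encoded A `"pheno_matrix"` tibble.
#' @param k Number of patient groups to cut (default 3).
#' @return List of class `"pheno_cluster"`: `hclust` (the linkage tree),
#'   `clusters` (tibble `patient`, `cluster`), `dist`, `k`, `order`
#'   (patient ordering for heatmap display) and `data`.
#' @export
cluster_phenotypes <- function(encoded, k = 3) {
  feats <- setdiff(names(encoded), c("patient", "variant"))
  if (nrow(encoded) < 2) abort("At least two patients are required.")
  assert_count(k, "k")
  m <- as.matrix(encoded[feats])
  rownames(m) <- encoded$patient
  # stable ordering so the partition cannot depend on input row order
  m <- m[order(rownames(m)), , drop = FALSE]
  d <- dist(m, method = "euclidean")
  if (anyNA(d)) {
    pairs <- which(is.na(as.matrix(d)), arr.ind = TRUE)
    abort(sprintf(
      "Patients %s and %s share no observed feature; filter features first.",
      rownames(m)[pairs[1, 1]], rownames(m)[pairs[1, 2]]))
  }
  hc <- hclust(d, method = "ward.D2")
  cl <- cutree(hc, k = k)
  structure(
    list(
      hclust = hc,
      clusters = tibble(patient = names(cl), cluster = unname(cl)),
      dist = d, k = as.integer(k),
      order = rownames(m)[hc$order],
      data = encoded
    ),
    class = "pheno_cluster"
  )
}

#' @export
print.pheno_cluster <- function(x, ...) {
  cat(sprintf("Phenotype clustering: %d patients, k = %d (ward.D2)\n",
              nrow(x$clusters), x$k))
  print(count(x$clusters, .data$cluster))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster assignments of the same
#' items; 1 means identical partitions.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Missingness sensitivity re-clustering
#'
#' Reruns the clustering after removing features with more than
#' `max_missing` missing data and reports the adjusted Rand index between
#' the full and filtered partitions (the index is reported, not asserted:
#' it quantifies how comparable the two runs are).
#'
#' @inheritParams cluster_phenotypes
#' @param max_missing Missingness cutoff for the sensitivity run.
#' @return List with `full`, `filtered` (`"pheno_cluster"` objects),
#'   `removed_features` and `ari`.
#' @export
pheno_sensitivity <- function(encoded, k = 3, max_missing = 0.30) {
  full <- cluster_phenotypes(encoded, k = k)
  flt <- missingness_filter(encoded, max_missing = max_missing)
  filtered <- cluster_phenotypes(flt, k = k)
  joined <- inner_join(full$clusters, filtered$clusters, by = "patient",
                       suffix = c("_full", "_filtered"))
  list(
    full = full, filtered = filtered,
    removed_features = attr(flt, "removed_features"),
    ari = adjusted_rand_index(joined$cluster_full, joined$cluster_filtered)
  )
}
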