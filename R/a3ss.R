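# Cryptic 3' splice-site signature: canonical/alternative acceptor
# assignment, signed distances, distance densities, acceptor motif
# matrices and polypyrimidine-tract content.
#
# Distance convention: d = (alternative acceptor - canonical acceptor)
# measured along the transcription direction, so negative d means the
# alternative AG lies upstream of the canonical AG (inside the intron) and
# positive d downstream (inside the exon). Distances are measured between
# the intron-terminal boundaries of the two acceptors; both AGs shift
# equally, so anchoring on the A instead would change nothing.

#' Assign canonical and alternative acceptors to A3SS events
#'
#' The canonical acceptor is the annotation-supported one. When both
#' acceptors are annotated, the acceptor of the majority isoform in the
#' wild-type group is canonical (requires PSI records); when neither is
#' annotated the event is excluded, with the reason recorded.
#'
#' @param events Catalog (or catalog-joined `splice_diff`) rows of class
#'   A3SS, carrying `donor`, `acc_proximal`, `acc_distal`.
#' @param annotation Exon tibble.
#' @param psi Optional PSI records with `group` column (needed for the
#'   both-annotated case; inclusion form = proximal-acceptor junction).
#' @return The A3SS rows with added columns `canonical_acceptor`,
#'   `alternative_acceptor`, `assignment` (one of `"single_annotated"`,
#'   `"wt_majority"`, `"excluded_unannotated"`, `"excluded_no_wt_psi"`).
#'   Excluded rows are retained with `NA` acceptors so exclusions can be
#'   reported.
#' @export
canonical_assignment <- function(events, annotation, psi = NULL) {
  ev <- filter(as_tibble(events), .data$class == "A3SS")
  if (nrow(ev) == 0) {
    abort("No A3SS events supplied.")
  }
  joins <- annotation_joins(annotation)
  join_keys <- junc_key(joins$contig, joins$strand, joins$lo, joins$hi)
  acc_key <- function(contig, strand, donor, acc) {
    junc_key(contig, strand, pmin(donor, acc), pmax(donor, acc))
  }
  prox_ann <- acc_key(ev$contig, ev$strand, ev$donor,
                      ev$acc_proximal) %in% join_keys
  dist_ann <- acc_key(ev$contig, ev$strand, ev$donor,
                      ev$acc_distal) %in% join_keys

  wt_psi <- NULL
  if (!is.null(psi)) {
    wt_psi <- psi %>%
      filter(.data$group == "wt") %>%
      group_by(.data$event_id) %>%
      summarise(psi_wt = mean(.data$psi, na.rm = TRUE), .groups = "drop")
  }
  ev <- left_join(ev, wt_psi %||% tibble(event_id = character(),
                                         psi_wt = numeric()),
                  by = "event_id")

  assign_one <- function(prox_a, dist_a, prox, dist, psi_wt) {
    if (prox_a && !dist_a) {
      list(prox, dist, "single_annotated")
    } else if (dist_a && !prox_a) {
      list(dist, prox, "single_annotated")
    } else if (!prox_a && !dist_a) {
      list(NA_integer_, NA_integer_, "excluded_unannotated")
    } else if (is.na(psi_wt)) {
      list(NA_integer_, NA_integer_, "excluded_no_wt_psi")
    } else if (psi_wt >= 0.5) {
      # inclusion form uses the proximal acceptor; majority in WT wins
      list(prox, dist, "wt_majority")
    } else {
      list(dist, prox, "wt_majority")
    }
  }
  res <- purrr::pmap(
    list(prox_ann, dist_ann, ev$acc_proximal, ev$acc_distal,
         ev$psi_wt %||% NA_real_),
    assign_one)
  excluded <- sum(vapply(res, function(r) startsWith(r[[3]], "excluded"),
                         logical(1)))
  if (excluded > 0) {
    inform(sprintf(
      "%d A3SS event(s) excluded from the signature (no annotated acceptor or no wild-type PSI).",
      excluded))
  }
  ev %>%
    mutate(
      canonical_acceptor = purrr::map_int(res, function(r) as.integer(r[[1]])),
      alternative_acceptor = purrr::map_int(res, function(r) as.integer(r[[2]])),
      assignment = purrr::map_chr(res, 3L)
    ) %>%
    select(-"psi_wt")
}

#' Signed cryptic-to-canonical acceptor distance
#'
#' @param events Output of [canonical_assignment()] (excluded rows are
#'   dropped).
#' @return Tibble with `event_id`, `canonical_acceptor`,
#'   `alternative_acceptor`, `d` (signed nt, transcription direction) and
#'   `abs_d`.
#' @export
signed_distance <- function(events) {
  ev <- filter(as_tibble(events), !is.na(.data$canonical_acceptor))
  if (any(ev$alternative_acceptor == ev$canonical_acceptor)) {
    abort("Degenerate A3SS event: identical canonical and alternative acceptors.")
  }
  ev %>%
    mutate(
      d = ifelse(.data$strand == "+",
                 .data$alternative_acceptor - .data$canonical_acceptor,
                 -(.data$alternative_acceptor - .data$canonical_acceptor)),
      d = as.integer(.data$d),
      abs_d = abs(.data$d)
    ) %>%
    select("event_id", "contig", "strand", "donor", "canonical_acceptor",
           "alternative_acceptor", "d", "abs_d")
}

#' Distance histograms, mode, mean and direction bias
#'
#' Histograms at 1-nt bins of |d| and signed d; the modal |d| is the
#' smallest |d| maximising the histogram after 3-nt moving-average
#' smoothing; `p_downstream` is the fraction of events with the
#' alternative acceptor downstream of the canonical one (d > 0).
#'
#' @param distances Tibble from [signed_distance()].
#' @return List of class `"a3ss_distance_summary"`: `n_events`,
#'   `mean_abs_d`, `mode_abs_d`, `p_downstream`, `hist_abs` and
#'   `hist_signed` tibbles.
#' @export
distance_densities <- function(distances) {
  if (nrow(distances) == 0) {
    return(structure(list(n_events = 0L, mean_abs_d = NA_real_,
                          mode_abs_d = NA_integer_, p_downstream = NA_real_,
                          hist_abs = tibble(abs_d = integer(), n = integer()),
                          hist_signed = tibble(d = integer(), n = integer()),
                          empty = TRUE),
                     class = "a3ss_distance_summary"))
  }
  hist_abs <- tibble(abs_d = seq_len(max(distances$abs_d))) %>%
    left_join(count(distances, .data$abs_d), by = "abs_d") %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))
  sm <- moving_average(hist_abs$n, 1L)
  mode_abs <- hist_abs$abs_d[which.max(sm)]  # which.max: smallest argmax
  rng <- range(distances$d)
  hist_signed <- tibble(d = seq(rng[1], rng[2])) %>%
    left_join(count(distances, .data$d), by = "d") %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))
  structure(
    list(
      n_events = nrow(distances),
      mean_abs_d = mean(distances$abs_d),
      mode_abs_d = as.integer(mode_abs),
      p_downstream = mean(distances$d > 0),
      hist_abs = hist_abs,
      hist_signed = hist_signed,
      empty = FALSE
    ),
    class = "a3ss_distance_summary"
  )
}

# Extract 55-nt acceptor windows on the transcribed strand: 50 intronic nt
# upstream of the AG, the AG itself, and 3 exonic nt downstream. `acceptor`
# is the intron 3'-boundary coordinate (0-based half-open: the hi end on
# "+", the lo end on "-").
acceptor_windows <- function(acceptors, genome, upstream = 50L,
                             downstream = 3L) {
  if (nrow(acceptors) == 0) abort("Empty acceptor set.")
  seqs <- as.character(genome)
  w <- upstream + 2L + downstream
  res <- character(0); skipped <- 0L
  for (i in seq_len(nrow(acceptors))) {
    contig <- acceptors$contig[i]
    acc <- acceptors$acceptor[i]
    s <- seqs[[contig]]
    if (is.null(s)) { skipped <- skipped + 1L; next }
    L <- nchar(s)
    if (acceptors$strand[i] == "+") {
      from <- acc - upstream - 2L            # 0-based window start
      if (from < 0 || acc + downstream > L) { skipped <- skipped + 1L; next }
      res <- c(res, substr(s, from + 1L, from + w))
    } else {
      from <- acc - downstream
      if (from < 0 || acc + upstream + 2L > L) { skipped <- skipped + 1L; next }
      win <- substr(s, from + 1L, from + w)
      res <- c(res, as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(win))))
    }
  }
  list(windows = res, n_skipped = skipped)
}

#' Acceptor motif frequency matrix
#'
#' Strand-aware nucleotide frequency matrix over 55 positions anchored on
#' the acceptor AG: positions -50..-1 (intronic), the A and G, and +1..+3
#' (exonic). Frequencies at each position sum to 1; for genuine acceptors
#' the two anchor columns are pure A and pure G. Acceptors too close to a
#' contig edge are skipped and counted.
#'
#' @param acceptors Tibble with `contig`, `strand`, `acceptor` (intron
#'   3'-boundary coordinate, 0-based half-open).
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @return List of class `"motif_matrix"`: `freq` (4 x 55 matrix, rows
#'   A/C/G/T, columns labelled by anchored position), `n_sequences`,
#'   `n_skipped`.
#' @export
motif_matrix <- function(acceptors, genome) {
  aw <- acceptor_windows(acceptors, genome)
  if (length(aw$windows) == 0) {
    abort("No acceptor windows could be extracted (all out of bounds).")
  }
  dss <- Biostrings::DNAStringSet(aw$windows)
  cm <- Biostrings::consensusMatrix(dss, as.prob = TRUE,
                                    baseOnly = TRUE)[c("A", "C", "G", "T"), ]
  # renormalise in case of non-ACGT letters (baseOnly folds them to 'other')
  cm <- sweep(cm, 2L, colSums(cm), "/")
  colnames(cm) <- c(paste0(seq(-50L, -1L)), "A", "G", paste0("+", 1:3))
  structure(list(freq = cm, n_sequences = length(aw$windows),
                 n_skipped = aw$n_skipped),
            class = "motif_matrix")
}

#' Polypyrimidine-tract content upstream of acceptors
#'
#' Fraction of pyrimidines (C/T) on the transcribed strand over a window
#' relative to the acceptor A (default -20..-5, the usual polypyrimidine
#' tract), per acceptor and set-averaged.
#'
#' @inheritParams motif_matrix
#' @param window Integer `c(from, to)` of upstream positions (negative,
#'   inclusive; -1 = nucleotide immediately upstream of the A).
#' @return List with `per_acceptor` (tibble of fractions) and
#'   `mean_fraction`.
#' @export
ppt_content <- function(acceptors, genome, window = c(-20L, -5L)) {
  stopifnot(length(window) == 2L, window[1] <= window[2], window[2] <= -1L)
  aw <- acceptor_windows(acceptors, genome)
  if (length(aw$windows) == 0) {
    abort("No acceptor windows could be extracted (all out of bounds).")
  }
  # column index of upstream position -k (k in 1..50) is 51 - k
  idx <- seq(51L + window[1], 51L + window[2])
  sub <- substr(aw$windows, min(idx), max(idx))
  frac <- vapply(strsplit(sub, ""), function(ch) mean(ch %in% c("C", "T")),
                 numeric(1))
  list(
    per_acceptor = tibble(window_seq = sub, pyrimidine_fraction = frac),
    mean_fraction = mean(frac),
    n_skipped = aw$n_skipped
  )
}

#' Cryptic 3' splice-site signature of significant A3SS events
#'
#' Runs canonical/alternative acceptor assignment, signed distances,
#' distance densities and (when a genome is supplied) motif matrices and
#' polypyrimidine content for the cryptic and canonical acceptor sets.
#'
#' @param diff A catalog-joined `splice_diff` tibble (or any tibble of
#'   A3SS events with coordinates). Rows are pre-filtered to significant
#'   events by the caller, e.g. with [apply_thresholds()].
#' @param annotation Exon tibble.
#' @param genome Optional genome for motif/PPT analyses.
#' @param psi Optional PSI records (used when both acceptors are
#'   annotated).
#' @return List of class `"a3ss_signature"`: `distances`, `summary` (an
#'   `"a3ss_distance_summary"`), `motif_cryptic`, `motif_canonical`,
#'   `ppt_cryptic`, `ppt_canonical`, `n_excluded`.
#' @export
a3ss_signature <- function(diff, annotation, genome = NULL, psi = NULL) {
  assigned <- canonical_assignment(diff, annotation, psi = psi)
  usable <- filter(assigned, !is.na(.data$canonical_acceptor))
  distances <- signed_distance(usable)
  summary <- distance_densities(distances)
  out <- list(
    distances = distances,
    summary = summary,
    n_excluded = sum(is.na(assigned$canonical_acceptor)),
    motif_cryptic = NULL, motif_canonical = NULL,
    ppt_cryptic = NULL, ppt_canonical = NULL
  )
  if (!is.null(genome) && nrow(distances) > 0) {
    cryptic <- distances %>%
      select("contig", "strand", acceptor = "alternative_acceptor")
    canonical <- distances %>%
      select("contig", "strand", acceptor = "canonical_acceptor")
    out$motif_cryptic <- motif_matrix(cryptic, genome)
    out$motif_canonical <- motif_matrix(canonical, genome)
    out$ppt_cryptic <- ppt_content(cryptic, genome)
    out$ppt_canonical <- ppt_content(canonical, genome)
  }
  structure(out, class = "a3ss_signature")
}

#' @export
print.a3ss_signature <- function(x, ...) {
  s <- x$summary
  cat("Cryptic 3' splice-site signature\n")
  cat(sprintf("  events: %d (excluded: %d)\n", s$n_events, x$n_excluded))
  if (!s$empty) {
    cat(sprintf("  mean |d|: %.2f nt   modal |d|: %d nt   downstream: %.1f%%\n",
                s$mean_abs_d, s$mode_abs_d, 100 * s$p_downstream))
  }
  invisible(x)
}
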