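# Five-class alternative-splicing event catalog and PSI quantification.
#
# The catalog is built purely from splice-junction evidence plus an exon
# annotation, in the spirit of junction-count ("JC") event detection with
# novel splice sites enabled. Conventions:
#   * introns are [lo, hi) genomic, 0-based half-open;
#   * the donor is the lo end on "+" and the hi end on "-";
#   * inclusion forms: SE = exon included, A3SS/A5SS = shorter-intron
#     junction (the "long exon" form), RI = retained, MXE = 5'-proximal
#     alternative exon path;
#   * retained-intron inclusion evidence consists of 2-nt pseudo-junction
#     records straddling each intron boundary (junction records shorter
#     than 20 nt are treated as such evidence, never as introns).

RI_PSEUDO_MAX <- 20L

# exon-exon joins (annotated introns) implied by a transcript annotation
annotation_joins <- function(annotation) {
  annotation %>%
    arrange(.data$contig, .data$transcript_id, .data$start) %>%
    group_by(.data$contig, .data$strand, .data$gene_id,
             .data$transcript_id) %>%
    dplyr::reframe(lo = head(.data$end, -1L), hi = .data$start[-1L]) %>%
    distinct(.data$contig, .data$strand, .data$lo, .data$hi,
             .keep_all = TRUE) %>%
    select("contig", "strand", "lo", "hi", "gene_id")
}

#' Build the alternative-splicing event catalog
#'
#' Detects SE, A5SS, A3SS, RI and MXE events from observed junctions and
#' the annotation. Any observed junction end absent from the annotation is
#' treated as a candidate (novel) splice site; an event is flagged `novel`
#' when at least one defining junction is not an annotation-derived
#' exon-exon join (for retained introns: when no annotated exon spans the
#' intron). Event ids are deterministic functions of sorted coordinates, so
#' the catalog is independent of input ordering.
#'
#' @param annotation Exon tibble (see [parse_annotation()]).
#' @param junctions Junction tibble (`contig`, `strand`, `lo`, `hi`,
#'   `count`, optionally `sample`).
#' @return Catalog tibble: `event_id`, `class`, `contig`, `strand`,
#'   `gene_id`, `novel`, junction list-columns `inc_junc`/`skip_junc`,
#'   effective lengths `l_inc`/`l_skip`, and for A3SS/A5SS the `donor`,
#'   `acc_proximal`, `acc_distal` boundary coordinates.
#' @export
build_event_catalog <- function(annotation, junctions) {
  obs <- junctions %>%
    group_by(.data$contig, .data$strand, .data$lo, .data$hi) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    filter(.data$count > 0)
  pseudo <- filter(obs, .data$hi - .data$lo <= RI_PSEUDO_MAX)
  real <- filter(obs, .data$hi - .data$lo > RI_PSEUDO_MAX)
  joins <- annotation_joins(annotation)
  join_keys <- junc_key(joins$contig, joins$strand, joins$lo, joins$hi)

  groups <- real %>%
    distinct(.data$contig, .data$strand)
  res <- purrr::pmap(groups, function(contig, strand) {
    catalog_one_contig(
      contig, strand,
      j = filter(real, .data$contig == !!contig, .data$strand == !!strand),
      pseudo = filter(pseudo, .data$contig == !!contig,
                      .data$strand == !!strand),
      ann_introns = filter(joins, .data$contig == !!contig,
                           .data$strand == !!strand),
      annotation = filter(annotation, .data$contig == !!contig,
                          .data$strand == !!strand)
    )
  })
  cat_tbl <- bind_rows(res)
  if (nrow(cat_tbl) == 0) return(cat_tbl)

  # novelty: any defining (real) junction absent from annotated joins
  cat_tbl <- cat_tbl %>%
    mutate(novel = purrr::map2_lgl(.data$inc_junc, .data$skip_junc,
                                   function(i, s) {
      keys <- c(i, s)
      keys <- keys[parse_junc_key(keys)$hi -
                     parse_junc_key(keys)$lo > RI_PSEUDO_MAX]
      any(!keys %in% join_keys)
    }))
  # RI novelty: no annotated exon spans the retained intron
  ri <- cat_tbl$class == "RI"
  if (any(ri)) {
    cat_tbl$novel[ri] <- purrr::map_lgl(which(ri), function(i) {
      iv <- parse_junc_key(cat_tbl$skip_junc[[i]])
      !any(annotation$contig == cat_tbl$contig[i] &
             annotation$strand == cat_tbl$strand[i] &
             annotation$start <= iv$lo & annotation$end >= iv$hi)
    })
  }

  # gene attribution: gene with an exon overlapping the event span
  spans <- cat_tbl %>%
    mutate(span = purrr::map(.data$event_id, function(id) {
      co <- as.integer(stringr::str_split_1(
        stringr::str_split_1(id, ":")[4], "-"))
      c(min(co), max(co))
    }),
    span_lo = purrr::map_int(.data$span, 1L),
    span_hi = purrr::map_int(.data$span, 2L)) %>%
    select(-"span")
  gene_of <- function(contig, strand, lo, hi) {
    hit <- annotation$contig == contig & annotation$strand == strand &
      annotation$start < hi + 1L & annotation$end > lo - 1L
    if (any(hit)) annotation$gene_id[hit][1] else NA_character_
  }
  spans %>%
    mutate(gene_id = purrr::pmap_chr(
      list(.data$contig, .data$strand, .data$span_lo, .data$span_hi),
      gene_of)) %>%
    select(-"span_lo", -"span_hi") %>%
    arrange(.data$event_id)
}

# endpoints of real junctions on one contig/strand, for the "no junction
# end strictly inside" plausibility rule
catalog_one_contig <- function(contig, strand, j, pseudo, ann_introns,
                               annotation) {
  ends <- sort(unique(c(j$lo, j$hi)))
  no_end_inside <- function(a, b) {
    !any(ends > a & ends < b)
  }
  key <- function(lo, hi) junc_key(contig, strand, lo, hi)
  out <- list()

  donor_col <- if (strand == "+") "lo" else "hi"
  acc_col <- if (strand == "+") "hi" else "lo"

  # ---- A3SS: junction pairs sharing a donor --------------------------------
  by_donor <- split(j, j[[donor_col]])
  for (grp in by_donor) {
    if (nrow(grp) < 2) next
    accs <- sort(grp[[acc_col]])
    for (pair in combn_pairs(accs)) {
      a1 <- pair[1]; a2 <- pair[2]
      if (!no_end_inside(a1, a2)) next
      donor <- grp[[donor_col]][1]
      # proximal acceptor = closer to the donor (shorter intron)
      prox <- if (strand == "+") a1 else a2
      dist <- if (strand == "+") a2 else a1
      inc <- if (strand == "+") key(donor, prox) else key(prox, donor)
      skp <- if (strand == "+") key(donor, dist) else key(dist, donor)
      out[[length(out) + 1L]] <- tibble(
        event_id = event_key("A3SS", contig, strand, c(donor, a1, a2)),
        class = "A3SS", contig = contig, strand = strand,
        inc_junc = list(inc), skip_junc = list(skp),
        l_inc = 1L, l_skip = 1L,
        donor = donor, acc_proximal = prox, acc_distal = dist
      )
    }
  }

  # ---- A5SS: junction pairs sharing an acceptor ----------------------------
  by_acc <- split(j, j[[acc_col]])
  for (grp in by_acc) {
    if (nrow(grp) < 2) next
    dons <- sort(grp[[donor_col]])
    for (pair in combn_pairs(dons)) {
      d1 <- pair[1]; d2 <- pair[2]
      if (!no_end_inside(d1, d2)) next
      acc <- grp[[acc_col]][1]
      # proximal donor = closer to the acceptor (shorter intron)
      prox <- if (strand == "+") d2 else d1
      dist <- if (strand == "+") d1 else d2
      inc <- if (strand == "+") key(prox, acc) else key(acc, prox)
      skp <- if (strand == "+") key(dist, acc) else key(acc, dist)
      out[[length(out) + 1L]] <- tibble(
        event_id = event_key("A5SS", contig, strand, c(acc, d1, d2)),
        class = "A5SS", contig = contig, strand = strand,
        inc_junc = list(inc), skip_junc = list(skp),
        l_inc = 1L, l_skip = 1L,
        donor = NA_integer_, acc_proximal = NA_integer_,
        acc_distal = NA_integer_
      )
    }
  }

  # ---- SE and MXE: exon paths between shared flanks ------------------------
  # candidate exon (a, b): junction (*, a) and (b, *) observed, a < b, and
  # no junction end strictly inside (a, b)
  flank_paths <- list()
  for (r1 in seq_len(nrow(j))) {
    for (r2 in seq_len(nrow(j))) {
      D <- j$lo[r1]; a <- j$hi[r1]   # junction D -> a
      b <- j$lo[r2]; A <- j$hi[r2]   # junction b -> A
      if (a >= b || !no_end_inside(a, b)) next
      fk <- paste(D, A)
      flank_paths[[fk]] <- c(flank_paths[[fk]],
                             list(c(D = D, a = a, b = b, A = A)))
    }
  }
  skip_keys <- junc_key(contig, strand, j$lo, j$hi)
  have_junc <- function(lo, hi) key(lo, hi) %in% skip_keys
  for (fk in names(flank_paths)) {
    paths <- flank_paths[[fk]]
    D <- paths[[1]]["D"]; A <- paths[[1]]["A"]
    if (have_junc(D, A)) {
      for (p in paths) {
        out[[length(out) + 1L]] <- tibble(
          event_id = event_key("SE", contig, strand,
                               c(D, p["a"], p["b"], A)),
          class = "SE", contig = contig, strand = strand,
          inc_junc = list(c(key(D, p["a"]), key(p["b"], A))),
          skip_junc = list(key(D, A)),
          l_inc = 2L, l_skip = 1L,
          donor = NA_integer_, acc_proximal = NA_integer_,
          acc_distal = NA_integer_
        )
      }
    } else if (length(paths) >= 2) {
      for (pp in combn_pairs(seq_along(paths))) {
        p1 <- paths[[pp[1]]]; p2 <- paths[[pp[2]]]
        if (p1["a"] > p2["a"]) { tmp <- p1; p1 <- p2; p2 <- tmp }
        if (p1["b"] > p2["a"]) next              # overlapping exons
        if (have_junc(p1["b"], p2["a"])) next    # exons co-included
        # inclusion = 5'-proximal exon along transcription
        first <- if (strand == "+") p1 else p2
        second <- if (strand == "+") p2 else p1
        out[[length(out) + 1L]] <- tibble(
          event_id = event_key("MXE", contig, strand,
                               c(D, p1["a"], p1["b"], p2["a"], p2["b"], A)),
          class = "MXE", contig = contig, strand = strand,
          inc_junc = list(c(key(D, first["a"]), key(first["b"], A))),
          skip_junc = list(c(key(D, second["a"]), key(second["b"], A))),
          l_inc = 2L, l_skip = 2L,
          donor = NA_integer_, acc_proximal = NA_integer_,
          acc_distal = NA_integer_
        )
      }
    }
  }

  # ---- RI: annotated introns with boundary-spanning evidence ---------------
  if (nrow(ann_introns) > 0 && nrow(pseudo) > 0) {
    pseudo_keys <- junc_key(contig, strand, pseudo$lo, pseudo$hi)
    for (r in seq_len(nrow(ann_introns))) {
      lo <- ann_introns$lo[r]; hi <- ann_introns$hi[r]
      b1 <- key(lo - 1L, lo + 1L); b2 <- key(hi - 1L, hi + 1L)
      if (!have_junc(lo, hi)) next
      if (!(b1 %in% pseudo_keys && b2 %in% pseudo_keys)) next
      out[[length(out) + 1L]] <- tibble(
        event_id = event_key("RI", contig, strand, c(lo, hi)),
        class = "RI", contig = contig, strand = strand,
        inc_junc = list(c(b1, b2)), skip_junc = list(key(lo, hi)),
        l_inc = 2L, l_skip = 1L,
        donor = NA_integer_, acc_proximal = NA_integer_,
        acc_distal = NA_integer_
      )
    }
  }

  bind_rows(out)
}

combn_pairs <- function(x) {
  if (length(x) < 2) return(list())
  m <- combn(x, 2L)
  lapply(seq_len(ncol(m)), function(i) m[, i])
}

#' Compute per-sample PSI records
#'
#' Length-adjusted junction-count PSI: with inclusion reads `I` over
#' `L_inc` supporting junctions and skipping reads `S` over `L_skip`,
#' `psi = (I / L_inc) / (I / L_inc + S / L_skip)`; undefined (`NA`) when
#' `I + S = 0`. Junctions absent from the count table contribute 0.
#'
#' @param catalog Catalog tibble from [build_event_catalog()].
#' @param junctions Junction tibble with a `sample` column.
#' @return Tibble of PSI records: `event_id`, `sample`, (`group` if
#'   present in `junctions`), `inc_count`, `skip_count`, `psi`.
#' @export
compute_psi <- function(catalog, junctions) {
  if (nrow(catalog) == 0) {
    return(tibble(event_id = character(), sample = character(),
                  inc_count = integer(), skip_count = integer(),
                  psi = numeric()))
  }
  counts <- junctions %>%
    mutate(junc = junc_key(.data$contig, .data$strand, .data$lo, .data$hi)) %>%
    group_by(.data$sample, .data$junc) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  samples <- distinct(junctions, .data$sample)
  if ("group" %in% names(junctions)) {
    samples <- distinct(junctions, .data$sample, .data$group)
  }

  long <- bind_rows(
    catalog %>%
      select("event_id", "l_inc", "l_skip", junc = "inc_junc") %>%
      tidyr::unnest_longer("junc") %>%
      mutate(form = "inc"),
    catalog %>%
      select("event_id", "l_inc", "l_skip", junc = "skip_junc") %>%
      tidyr::unnest_longer("junc") %>%
      mutate(form = "skip")
  )
  grid <- tidyr::crossing(long, samples) %>%
    left_join(counts, by = c("sample", "junc")) %>%
    mutate(count = tidyr::replace_na(.data$count, 0L))
  grid %>%
    group_by(.data$event_id, .data$sample,
             dplyr::across(dplyr::any_of("group")),
             .data$l_inc, .data$l_skip) %>%
    summarise(
      inc_count = sum(.data$count[.data$form == "inc"]),
      skip_count = sum(.data$count[.data$form == "skip"]),
      .groups = "drop"
    ) %>%
    mutate(
      psi = ifelse(
        .data$inc_count + .data$skip_count == 0, NA_real_,
        (.data$inc_count / .data$l_inc) /
          (.data$inc_count / .data$l_inc + .data$skip_count / .data$l_skip))
    ) %>%
    select(-"l_inc", -"l_skip") %>%
    arrange(.data$event_id, .data$sample)
}

#' Filter events by mean read coverage
#'
#' Retains events whose mean total event reads (`inc_count + skip_count`)
#' across all samples is at least `min_mean_reads` (default 10, the usual
#' "average reads covering the splice event" filter).
#'
#' @param psi PSI records from [compute_psi()].
#' @param min_mean_reads Non-negative threshold.
#' @return Filtered PSI records (all samples of retained events).
#' @export
coverage_filter <- function(psi, min_mean_reads = 10) {
  if (min_mean_reads < 0) abort("`min_mean_reads` must be >= 0.")
  keep <- psi %>%
    group_by(.data$event_id) %>%
    summarise(mean_reads = mean(.data$inc_count + .data$skip_count),
              .groups = "drop") %>%
    filter(.data$mean_reads >= min_mean_reads)
  semi_join(psi, keep, by = "event_id")
}
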