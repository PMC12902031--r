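# Toy genome, annotation and ground-truth event construction.
#
# Each gene lives on its own contig and is laid out in transcription-strand
# coordinates first (exon 1 leftmost), then mirrored for minus-strand genes.
# All internal coordinates are 0-based half-open; introns are stored as
# [lo, hi) genomic intervals and junctions keyed "contig:strand:lo:hi".

junc_key <- function(contig, strand, lo, hi) {
  sprintf("%s:%s:%d:%d", contig, strand, as.integer(lo), as.integer(hi))
}

parse_junc_key <- function(key) {
  parts <- stringr::str_split_fixed(key, ":", 4L)
  tibble(contig = parts[, 1], strand = parts[, 2],
         lo = as.integer(parts[, 3]), hi = as.integer(parts[, 4]))
}

#' Deterministic event identifier
#'
#' Events are keyed by class, contig, strand and the sorted unique genomic
#' boundary coordinates of their defining junctions (for retained introns,
#' the intron boundaries). Identical events detected from different inputs
#' over the same genome therefore share identifiers.
#'
#' @param class Event class (`SE`, `A5SS`, `A3SS`, `RI`, `MXE`).
#' @param contig,strand Location of the event.
#' @param coords Integer vector of defining coordinates (any order).
#' @return Character scalar id.
#' @export
event_key <- function(class, contig, strand, coords) {
  sprintf("%s:%s:%s:%s", class, contig, strand,
          paste(sort(unique(as.integer(coords))), collapse = "-"))
}

# reverse complement for a character vector of single bases
revcomp_letters <- function(x) rev(chartr("ACGT", "TGCA", x))

# map a tx-space half-open interval to genomic space on a contig of length L
tx2gen <- function(a, b, L, strand) {
  if (strand == "+") c(a, b) else c(L - b, L - a)
}

sample_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

sample_pyrimidine <- function(n, frac) {
  pyr <- runif(n) < frac
  out <- character(n)
  out[pyr] <- sample(c("C", "T"), sum(pyr), replace = TRUE)
  out[!pyr] <- sample(c("A", "G"), sum(!pyr), replace = TRUE)
  out
}

#' Build a seeded toy genome with planted splicing events
#'
#' Generates, deterministically from the configuration seed, a toy genome
#' (one contig per gene), a transcript annotation, and a ground-truth table
#' of planted alternative-splicing events. Every canonical intron starts
#' with GT and ends with AG on the transcribed strand; the 50 intronic nt
#' upstream of each canonical acceptor AG are drawn with the configured
#' pyrimidine fraction; cryptic acceptors are planted AG dinucleotides at
#' the drawn signed offset from the canonical AG (negative = upstream, into
#' the intron; positive = downstream, into the exon; measured along the
#' transcription direction).
#'
#' Ground-truth PSI values follow the catalog's inclusion-form convention
#' (see [build_event_catalog()]): for A3SS/A5SS the inclusion form is the
#' shorter-intron junction, for SE the exon-included form, for RI the
#' retained form, for MXE the 5'-proximal exon path.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `"splice_sim"` with elements `genome` (a
#'   [Biostrings::DNAStringSet]), `annotation` (exon tibble: contig, start,
#'   end, strand, gene_id, transcript_id), `truth` (one row per planted
#'   event), `constitutive` (junction tibble for non-event introns) and
#'   `config`.
#' @examples
#' sim <- build_toy_genome(simulation_config(
#'   n_events_per_class = c(A3SS = 2), seed = 5))
#' sim$truth
#' @export
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), build_toy_genome_impl(config))
}

build_toy_genome_impl <- function(config) {
  ev_counts <- config$n_events_per_class
  events <- rep(names(ev_counts), times = ev_counts)
  n_genes <- config$n_genes
  pad <- 100L

  seqs <- vector("list", n_genes)
  contigs <- character(n_genes)
  ann <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  consti <- vector("list", n_genes)

  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("g%04d", g)
    contig <- sprintf("chr_%s", gene_id)
    contigs[g] <- contig
    strand <- if (g %% 2L == 1L) "+" else "-"
    cls <- if (g <= length(events)) events[g] else "none"

    ne <- config$exons_per_gene
    ex_len <- sample(seq(config$exon_len[1], config$exon_len[2]), ne,
                     replace = TRUE)
    in_len <- sample(seq(config$intron_len[1], config$intron_len[2]), ne - 1L,
                     replace = TRUE)
    starts <- integer(ne); ends <- integer(ne)
    pos <- pad
    for (i in seq_len(ne)) {
      starts[i] <- pos
      ends[i] <- pos + ex_len[i]
      pos <- ends[i] + if (i < ne) in_len[i] else pad
    }
    L <- pos

    # --- event geometry in tx space ---------------------------------------
    d <- NA_integer_
    if (cls %in% c("A3SS", "A5SS")) {
      max_abs <- min(config$a3ss_offset$max, ex_len[3] - 10L, in_len[2] - 60L)
      if (config$a3ss_offset$dispersion == 0 &&
          config$a3ss_offset$center > max_abs) {
        abort(sprintf(
          "Configured offset %d nt does not fit the flanking exon/intron of event gene %s (max %d nt).",
          config$a3ss_offset$center, gene_id, max_abs))
      }
      d <- sample_offsets(1L, config$a3ss_offset, max_abs = max_abs,
                          min_abs = 2L)
    }

    # tx-space intron list of the canonical transcript
    introns_tx <- lapply(seq_len(ne - 1L),
                         function(i) c(ends[i], starts[i + 1L]))

    # --- sequence ----------------------------------------------------------
    letters_tx <- sample_bases(L)
    plant_intron <- function(lo, hi) {
      letters_tx[(lo + 1L):(lo + 2L)] <<- c("G", "T")
      win_lo <- hi - 52L
      letters_tx[(win_lo + 1L):(hi - 2L)] <<-
        sample_pyrimidine(50L, config$intron3p_pyrimidine_frac)
      letters_tx[(hi - 1L):hi] <<- c("A", "G")
    }
    for (iv in introns_tx) plant_intron(iv[1], iv[2])

    # cryptic sites (planted after canonical windows so they survive)
    if (cls == "A3SS") {
      hc <- starts[3] + d           # alternative intron end, tx space
      letters_tx[(hc - 1L):hc] <- c("A", "G")
    }
    if (cls == "A5SS") {
      dc <- ends[2] + d             # alternative intron start, tx space
      letters_tx[(dc + 1L):(dc + 2L)] <- c("G", "T")
    }

    # --- transcripts, junctions, truth -------------------------------------
    exon_tbl <- function(tx_id, exon_list) {
      purrr::map_dfr(exon_list, function(e) {
        gen <- tx2gen(e[1], e[2], L, strand)
        tibble(contig = contig, start = gen[1], end = gen[2],
               strand = strand, gene_id = gene_id, transcript_id = tx_id)
      })
    }
    jk <- function(iv) {            # tx intron -> genomic junction key
      gen <- tx2gen(iv[1], iv[2], L, strand)
      junc_key(contig, strand, gen[1], gen[2])
    }
    canon_exons <- lapply(seq_len(ne), function(i) c(starts[i], ends[i]))
    tx_rows <- list(exon_tbl(paste0(gene_id, ".t1"), canon_exons))
    consti_keys <- vapply(introns_tx, jk, character(1))
    truth_row <- NULL

    if (cls != "none") {
      novel <- runif(1) < config$fraction_novel_events
      is_diff <- runif(1) >= config$fraction_null_events
      alt_wt <- runif(1, config$baseline_psi[1], config$baseline_psi[2])
      eff <- runif(1, config$delta_psi_effect[1], config$delta_psi_effect[2])
      alt_var <- if (is_diff) min(alt_wt + eff, 0.95) else alt_wt

      i2 <- introns_tx[[2]]         # event intron: between exons 2 and 3
      if (cls == "SE") {
        inc <- c(jk(introns_tx[[1]]), jk(introns_tx[[2]]))
        skip <- jk(c(ends[1], starts[3]))
        keep_consti <- consti_keys[-c(1L, 2L)]
        psi_wt <- 1 - alt_wt; psi_var <- 1 - alt_var
        if (!novel) {
          tx_rows <- c(tx_rows, list(exon_tbl(paste0(gene_id, ".t2"),
                                              canon_exons[-2L])))
        }
      } else if (cls == "A3SS") {
        hc <- starts[3] + d
        can_j <- jk(i2); alt_j <- jk(c(i2[1], hc))
        # inclusion = shorter intron; cryptic intron shorter iff d < 0
        if (d < 0) { inc <- alt_j; skip <- can_j
                     psi_wt <- alt_wt; psi_var <- alt_var }
        else       { inc <- can_j; skip <- alt_j
                     psi_wt <- 1 - alt_wt; psi_var <- 1 - alt_var }
        keep_consti <- consti_keys[-2L]
        if (!novel) {
          alt_exons <- canon_exons
          alt_exons[[3]] <- c(hc, ends[3])
          tx_rows <- c(tx_rows, list(exon_tbl(paste0(gene_id, ".t2"),
                                              alt_exons)))
        }
      } else if (cls == "A5SS") {
        dc <- ends[2] + d
        can_j <- jk(i2); alt_j <- jk(c(dc, i2[2]))
        # alternative donor downstream (d > 0) shortens the intron
        if (d > 0) { inc <- alt_j; skip <- can_j
                     psi_wt <- alt_wt; psi_var <- alt_var }
        else       { inc <- can_j; skip <- alt_j
                     psi_wt <- 1 - alt_wt; psi_var <- 1 - alt_var }
        keep_consti <- consti_keys[-2L]
        if (!novel) {
          alt_exons <- canon_exons
          alt_exons[[2]] <- c(starts[2], dc)
          tx_rows <- c(tx_rows, list(exon_tbl(paste0(gene_id, ".t2"),
                                              alt_exons)))
        }
      } else if (cls == "RI") {
        # retention evidence: 2-nt pseudo-junctions straddling each boundary
        b1 <- jk(c(i2[1] - 1L, i2[1] + 1L))
        b2 <- jk(c(i2[2] - 1L, i2[2] + 1L))
        inc <- c(b1, b2); skip <- jk(i2)
        keep_consti <- consti_keys[-2L]
        psi_wt <- alt_wt; psi_var <- alt_var   # inclusion = retained form
        if (!novel) {
          ri_exons <- c(canon_exons[1], list(c(starts[2], ends[3])),
                        canon_exons[seq(4, ne)])
          tx_rows <- c(tx_rows, list(exon_tbl(paste0(gene_id, ".t2"),
                                              ri_exons)))
        }
      } else if (cls == "MXE") {
        # exons 2 and 3 mutually exclusive, flanks 1 and 4
        jA <- c(jk(c(ends[1], starts[2])), jk(c(ends[2], starts[4])))
        jB <- c(jk(c(ends[1], starts[3])), jk(c(ends[3], starts[4])))
        inc <- jA; skip <- jB      # inclusion = 5'-proximal exon path
        keep_consti <- if (ne > 4L) consti_keys[seq(4L, ne - 1L)] else character()
        psi_wt <- 1 - alt_wt; psi_var <- 1 - alt_var
        txA <- c(canon_exons[1], canon_exons[2], canon_exons[seq(4, ne)])
        tx_rows <- list(exon_tbl(paste0(gene_id, ".t1"), txA))
        if (!novel) {
          txB <- c(canon_exons[1], canon_exons[3], canon_exons[seq(4, ne)])
          tx_rows <- c(tx_rows, list(exon_tbl(paste0(gene_id, ".t2"), txB)))
        }
      }

      all_j <- c(inc, skip)
      coords <- if (cls == "RI") {
        iv <- parse_junc_key(skip); c(iv$lo, iv$hi)
      } else {
        real <- parse_junc_key(all_j)
        c(real$lo, real$hi)
      }
      if (cls == "RI") {
        # pseudo-records are evidence, not defining coordinates
      }
      id <- event_key(cls, contig, strand, coords)

      # transcription-direction sign convention already holds for d: it was
      # drawn in tx space (negative = upstream/into intron)
      truth_row <- tibble(
        event_id = id, class = cls, gene_id = gene_id, contig = contig,
        strand = strand, novel = novel, is_differential = is_diff,
        psi_wt = psi_wt, psi_var = psi_var,
        d_true = if (cls %in% c("A3SS", "A5SS")) d else NA_integer_,
        inc_junc = list(inc), skip_junc = list(skip),
        l_inc = length(inc), l_skip = length(skip)
      )
      consti_keys <- keep_consti
    }

    if (strand == "-") letters_tx <- revcomp_letters(letters_tx)
    seqs[[g]] <- paste(letters_tx, collapse = "")
    ann[[g]] <- bind_rows(tx_rows)
    truth[[g]] <- truth_row
    consti[[g]] <- if (length(consti_keys)) {
      mutate(parse_junc_key(consti_keys), gene_id = gene_id)
    } else NULL
  }

  genome <- Biostrings::DNAStringSet(setNames(unlist(seqs), contigs))
  structure(
    list(
      genome = genome,
      annotation = bind_rows(ann),
      truth = bind_rows(truth),
      constitutive = bind_rows(consti),
      config = config
    ),
    class = "splice_sim"
  )
}
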