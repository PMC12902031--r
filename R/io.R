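# Readers and writers for the external formats: FASTA, GTF, SJ-tab junction
# files, and the rMATS *.MATS.JC.txt dialect.
#
# Internal convention everywhere: 0-based half-open intervals. GTF I/O is
# 1-based closed; SJ-tab files give the first and last intronic base
# (1-based).

#' Write a genome to FASTA
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  # strip description part of headers
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write an exon annotation to GTF
#'
#' Emits one `exon` feature per row, converting the internal 0-based
#' half-open coordinates to the 1-based closed GTF convention, with
#' `gene_id`/`transcript_id` attributes. Rows are sorted so identical
#' annotations yield byte-identical files.
#'
#' @param annotation Exon tibble (`contig`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  ann <- arrange(annotation, .data$contig, .data$transcript_id, .data$start)
  lines <- sprintf(
    '%s\tsplicesig\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ann$contig, ann$start + 1L, ann$end, ann$strand,
    ann$gene_id, ann$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse a GTF annotation
#'
#' Reads exon features (via `rtracklayer`) and returns the internal
#' 0-based half-open exon tibble. Exons lacking a transcript attribution
#' trigger an error.
#'
#' @param path GTF file.
#' @return Exon tibble (`contig`, `start`, `end`, `strand`, `gene_id`,
#'   `transcript_id`).
#' @export
parse_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) abort(sprintf("No exon features found in %s.", path))
  if (anyNA(gr$transcript_id) || anyNA(gr$gene_id)) {
    abort("Exon records without gene_id/transcript_id attribution.")
  }
  df <- as.data.frame(gr)
  tibble(
    contig = as.character(df$seqnames),
    start = df$start - 1L,
    end = df$end,
    strand = as.character(df$strand),
    gene_id = df$gene_id,
    transcript_id = df$transcript_id
  )
}

sj_strand_code <- function(strand) c("+" = 1L, "-" = 2L)[strand]

#' Write per-sample SJ-tab junction files
#'
#' One STAR `SJ.out.tab`-style file per sample: contig, first intronic base
#' (1-based), last intronic base, strand code (1 = `+`, 2 = `-`), intron
#' motif and annotation columns (written as 0), unique-read count, multi-map
#' count (0) and overhang (0). Retained-intron boundary pseudo-records are
#' written like ordinary rows.
#'
#' @param junctions Junction tibble from [simulate_junction_counts()] (or
#'   same shape).
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths (one per sample).
#' @export
write_sj_dir <- function(junctions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (s in sort(unique(junctions$sample))) {
    j <- junctions %>%
      filter(.data$sample == s) %>%
      arrange(.data$contig, .data$lo, .data$hi)
    lines <- sprintf("%s\t%d\t%d\t%d\t0\t0\t%d\t0\t0",
                     j$contig, j$lo + 1L, j$hi,
                     sj_strand_code(j$strand), j$count)
    p <- file.path(dir, paste0(s, ".SJ.out.tab"))
    writeLines(lines, p)
    paths[s] <- p
  }
  paths
}

#' Read SJ-tab junction files
#'
#' Parses the SJ-tab dialect (columns 1-4 and 7 are used). Records with
#' strand code 0 (undefined strand) are skipped; their number is reported
#' with a warning.
#'
#' @param paths Character vector of files; names (or file basenames with
#'   the `.SJ.out.tab` suffix stripped) become sample ids.
#' @return Junction tibble (`sample`, `contig`, `strand`, `lo`, `hi`,
#'   `count`).
#' @export
read_sj <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.SJ\\.out\\.tab$", "", basename(paths))
  }
  n_skipped <- 0L
  out <- purrr::imap(paths, function(p, nm) {
    raw <- readr::read_tsv(p, col_names = FALSE, col_types = readr::cols(
      .default = readr::col_double(), X1 = readr::col_character()))
    if (nrow(raw) == 0) {
      return(tibble(sample = character(), contig = character(),
                    strand = character(), lo = integer(), hi = integer(),
                    count = integer()))
    }
    if (ncol(raw) < 7) abort(sprintf("%s: expected >= 7 SJ-tab columns.", p))
    bad <- !(raw$X4 %in% c(1, 2))
    n_skipped <<- n_skipped + sum(bad)
    raw <- raw[!bad, ]
    tibble(
      sample = nm,
      contig = raw$X1,
      strand = c("+", "-")[raw$X4],
      lo = as.integer(raw$X2) - 1L,
      hi = as.integer(raw$X3),
      count = as.integer(raw$X7)
    )
  })
  if (n_skipped > 0) {
    warn(sprintf("Skipped %d junction records with undefined strand code 0.",
                 n_skipped))
  }
  bind_rows(out)
}

# required columns of the *.MATS.JC.txt dialect, by event class
mats_coord_cols <- list(
  A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  SE = c("exonStart_0base", "exonEnd", "upstreamES", "upstreamEE",
         "downstreamES", "downstreamEE")
)
mats_core_cols <- c("ID", "GeneID", "chr", "strand",
                    "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2",
                    "SJC_SAMPLE_2", "IncFormLen", "SkipFormLen",
                    "PValue", "FDR", "IncLevel1", "IncLevel2",
                    "IncLevelDifference")

parse_inc_list <- function(x) {
  lapply(stringr::str_split(x, ","), function(v) {
    suppressWarnings(as.numeric(ifelse(v %in% c("NA", "nan", ""), NA, v)))
  })
}

#' Ingest an rMATS junction-count event table
#'
#' Reads a `*.MATS.JC.txt`-style file (as written by rMATS turbo v4.1+,
#' both v4.1.2 and v4.3.0 column sets are accepted) and converts it into
#' the package's native event, PSI and differential-splicing records, so
#' real rMATS output can feed the cryptic 3' splice-site signature stage
#' directly. Sample group 1 is mapped to condition `"var"` and sample group
#' 2 to `"wt"`, matching the variant-minus-wild-type orientation of
#' `IncLevelDifference`.
#'
#' @param path File in the MATS.JC dialect.
#' @param event_class One of `"A3SS"`, `"A5SS"`, `"SE"`.
#' @return A list with `events` (catalog-shaped tibble), `psi` (per-sample
#'   PSI records) and `diff` (a `splice_diff` tibble).
#' @export
ingest_rmats <- function(path, event_class = "A3SS") {
  if (!event_class %in% names(mats_coord_cols)) {
    abort(sprintf("Unsupported event class %s for rMATS ingestion.",
                  deparse(event_class)))
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  needed <- c(mats_core_cols, mats_coord_cols[[event_class]])
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    abort(sprintf("rMATS file %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  num <- function(col) suppressWarnings(as.numeric(tbl[[col]]))
  int <- function(col) suppressWarnings(as.integer(tbl[[col]]))
  n_in <- nrow(tbl)

  if (event_class %in% c("A3SS", "A5SS")) {
    plus <- tbl$strand == "+"
    if (event_class == "A3SS") {
      donor <- ifelse(plus, int("flankingEE"), int("flankingES"))
      acc_long <- ifelse(plus, int("longExonStart_0base"), int("longExonEnd"))
      acc_short <- ifelse(plus, int("shortES"), int("shortEE"))
    } else {
      donor <- ifelse(plus, int("longExonEnd"), int("longExonStart_0base"))
      donor_short <- ifelse(plus, int("shortEE"), int("shortES"))
      acc <- ifelse(plus, int("flankingES"), int("flankingEE"))
    }
  }

  mk_junc <- function(contig, strand, a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    junc_key(contig, strand, lo, hi)
  }

  if (event_class == "A3SS") {
    inc_j <- mk_junc(tbl$chr, tbl$strand, donor, acc_long)
    skip_j <- mk_junc(tbl$chr, tbl$strand, donor, acc_short)
    coords <- purrr::map(seq_len(n_in), function(i) {
      c(donor[i], acc_long[i], acc_short[i])
    })
    donor_col <- donor
    acc_prox <- acc_long   # long exon form = acceptor proximal to the donor
    acc_dist <- acc_short
  } else if (event_class == "A5SS") {
    inc_j <- mk_junc(tbl$chr, tbl$strand, donor, acc)
    skip_j <- mk_junc(tbl$chr, tbl$strand, donor_short, acc)
    coords <- purrr::map(seq_len(n_in), function(i) {
      c(donor[i], donor_short[i], acc[i])
    })
    donor_col <- NA_integer_
    acc_prox <- NA_integer_; acc_dist <- NA_integer_
  } else {  # SE
    es <- int("exonStart_0base"); ee <- int("exonEnd")
    ues <- int("upstreamES"); uee <- int("upstreamEE")
    des <- int("downstreamES"); dee <- int("downstreamEE")
    j1 <- mk_junc(tbl$chr, tbl$strand, uee, es)
    j2 <- mk_junc(tbl$chr, tbl$strand, ee, des)
    skip_j <- mk_junc(tbl$chr, tbl$strand, uee, des)
    inc_j <- purrr::map2(j1, j2, c)
    coords <- purrr::map(seq_len(n_in), function(i) {
      c(uee[i], es[i], ee[i], des[i])
    })
    donor_col <- NA_integer_
    acc_prox <- NA_integer_; acc_dist <- NA_integer_
  }
  if (!is.list(inc_j)) inc_j <- as.list(inc_j)
  if (!is.list(skip_j)) skip_j <- as.list(skip_j)

  ids <- purrr::pmap_chr(
    list(tbl$chr, tbl$strand, coords),
    function(contig, strand, co) event_key(event_class, contig, strand, co))

  events <- tibble(
    event_id = ids, class = event_class, contig = tbl$chr,
    strand = tbl$strand, gene_id = tbl$GeneID,
    inc_junc = inc_j, skip_junc = skip_j,
    l_inc = int("IncFormLen"), l_skip = int("SkipFormLen"),
    novel = NA,
    donor = if (event_class == "A3SS") donor_col else NA_integer_,
    acc_proximal = acc_prox, acc_distal = acc_dist
  )

  inc1 <- parse_inc_list(tbl$IncLevel1); inc2 <- parse_inc_list(tbl$IncLevel2)
  ijc1 <- parse_inc_list(tbl$IJC_SAMPLE_1); sjc1 <- parse_inc_list(tbl$SJC_SAMPLE_1)
  ijc2 <- parse_inc_list(tbl$IJC_SAMPLE_2); sjc2 <- parse_inc_list(tbl$SJC_SAMPLE_2)
  psi_rows <- function(lists, group) {
    purrr::imap_dfr(lists$psi, function(v, i) {
      tibble(event_id = ids[i], sample = sprintf("%s_%d", group, seq_along(v)),
             group = group, inc_count = lists$i[[i]][seq_along(v)],
             skip_count = lists$s[[i]][seq_along(v)], psi = v)
    })
  }
  psi <- bind_rows(
    psi_rows(list(psi = inc1, i = ijc1, s = sjc1), "var"),
    psi_rows(list(psi = inc2, i = ijc2, s = sjc2), "wt")
  )

  mean_def <- function(lst) vapply(lst, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  diff <- tibble(
    event_id = ids, class = event_class,
    gene_id = tbl$GeneID, novel = NA,
    mean_psi_wt = mean_def(inc2), mean_psi_var = mean_def(inc1),
    delta_psi = num("IncLevelDifference"),
    p_value = num("PValue"), fdr = num("FDR"),
    testable = !is.na(num("PValue"))
  )
  bad <- is.na(diff$delta_psi) &
    !(tbl$IncLevelDifference %in% c("NA", "nan", "") |
        is.na(tbl$IncLevelDifference))
  if (any(bad)) {
    warn(sprintf("Skipped %d rMATS records with malformed numerics.",
                 sum(bad)))
    keep <- !bad
    events <- events[keep, ]; diff <- diff[keep, ]
    psi <- filter(psi, .data$event_id %in% events$event_id)
  }
  class(diff) <- c("splice_diff", class(diff))
  list(events = events, psi = psi, diff = diff)
}

#' Write native differential-splicing records in the MATS.JC dialect
#'
#' Exports A3SS differential records so they can be re-ingested with
#' [ingest_rmats()] or consumed by rMATS-aware tooling. Exon extents that
#' the junction-level model does not track (flanking/long/short exon outer
#' bounds) are emitted as fixed-width placeholders consistent with the
#' junction coordinates; [ingest_rmats()] keys events on the junction
#' coordinates only.
#'
#' @param diff A `splice_diff` tibble restricted to A3SS events.
#' @param events Matching catalog tibble (for coordinates).
#' @param psi Per-sample PSI records.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mats_jc <- function(diff, events, psi, path) {
  ev <- events %>%
    filter(.data$class == "A3SS", .data$event_id %in% diff$event_id) %>%
    inner_join(select(diff, "event_id", "mean_psi_wt", "mean_psi_var",
                      "delta_psi", "p_value", "fdr"), by = "event_id")
  if (nrow(ev) == 0) abort("No A3SS records to write.")
  plus <- ev$strand == "+"
  exon_w <- 60L
  long_start <- ifelse(plus, ev$acc_proximal, ev$acc_proximal - exon_w)
  long_end <- ifelse(plus, ev$acc_proximal + exon_w, ev$acc_proximal)
  short_start <- ifelse(plus, ev$acc_distal, ev$acc_distal - exon_w)
  short_end <- ifelse(plus, ev$acc_distal + exon_w, ev$acc_distal)
  flank_start <- ifelse(plus, ev$donor - exon_w, ev$donor)
  flank_end <- ifelse(plus, ev$donor, ev$donor + exon_w)

  fmt_grp <- function(event_ids, col, grp) {
    p <- psi %>%
      filter(.data$group == grp) %>%
      arrange(.data$sample)
    vapply(event_ids, function(id) {
      v <- p[[col]][p$event_id == id]
      paste(ifelse(is.na(v), "NA",
                   ifelse(col == "psi", sprintf("%.6g", v),
                          format(v, trim = TRUE))), collapse = ",")
    }, character(1))
  }
  header <- c("ID", "GeneID", "geneSymbol", "chr", "strand",
              "longExonStart_0base", "longExonEnd", "shortES", "shortEE",
              "flankingES", "flankingEE", "ID.1",
              "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
              "IncFormLen", "SkipFormLen", "PValue", "FDR",
              "IncLevel1", "IncLevel2", "IncLevelDifference")
  body <- sprintf(
    "%s\t%s\t%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s",
    ev$event_id, ev$gene_id, ev$gene_id, ev$contig, ev$strand,
    long_start, long_end, short_start, short_end, flank_start, flank_end,
    ev$event_id,
    fmt_grp(ev$event_id, "inc_count", "var"),
    fmt_grp(ev$event_id, "skip_count", "var"),
    fmt_grp(ev$event_id, "inc_count", "wt"),
    fmt_grp(ev$event_id, "skip_count", "wt"),
    ev$l_inc, ev$l_skip,
    sprintf("%.10g", ev$p_value), sprintf("%.10g", ev$fdr),
    fmt_grp(ev$event_id, "psi", "var"),
    fmt_grp(ev$event_id, "psi", "wt"),
    sprintf("%.10g", ev$delta_psi)
  )
  writeLines(c(paste(header, collapse = "\t"), body), path)
  invisible(path)
}
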