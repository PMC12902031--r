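# Hand-built A3SS fixtures on both strands plus preset-recovery checks.

# one plus-strand event: donor 1000, canonical acceptor 1199+1 = 1200,
# alternative 1217 (downstream, d = +17); and its minus-strand mirror
fixture_events <- function() {
  tibble::tibble(
    event_id = c("A3SS:chrP:+:1000-1200-1217", "A3SS:chrM:-:2000-2783-2800"),
    class = "A3SS",
    contig = c("chrP", "chrM"),
    strand = c("+", "-"),
    donor = c(1000L, 4000L),
    acc_proximal = c(1200L, 2800L),
    acc_distal = c(1217L, 2783L)
  )
}

fixture_annotation <- function() {
  # canonical acceptors annotated: junction (1000,1200) on +, (2800,4000) on -
  tibble::tibble(
    contig = c("chrP", "chrP", "chrM", "chrM"),
    start = c(900L, 1200L, 2700L, 4000L),
    end = c(1000L, 1300L, 2800L, 4100L),
    strand = c("+", "+", "-", "-"),
    gene_id = c("gp", "gp", "gm", "gm"),
    transcript_id = c("tp", "tp", "tm", "tm")
  )
}

test_that("signed distances follow the transcription-direction convention", {
  assigned <- canonical_assignment(fixture_events(), fixture_annotation())
  expect_true(all(assigned$assignment == "single_annotated"))
  d <- signed_distance(assigned)
  # plus strand: canonical 1200 -> alternative 1217 = +17 (downstream)
  expect_equal(d$d[d$contig == "chrP"], 17L)
  # minus-strand mirror: alternative genomically upstream, but downstream
  # along transcription: also +17
  expect_equal(d$d[d$contig == "chrM"], 17L)
  expect_equal(d$abs_d, c(17L, 17L))

  # swapping canonical/alternative roles flips the sign exactly
  swapped <- assigned
  swapped$canonical_acceptor <- assigned$alternative_acceptor
  swapped$alternative_acceptor <- assigned$canonical_acceptor
  expect_equal(signed_distance(swapped)$d, c(-17L, -17L))

  # degenerate event errors
  degen <- assigned
  degen$alternative_acceptor <- degen$canonical_acceptor
  expect_error(signed_distance(degen), "Degenerate")
})

test_that("canonical assignment prefers annotation, then wild-type majority", {
  ev <- fixture_events()
  ann <- fixture_annotation()
  one <- canonical_assignment(ev, ann)
  expect_equal(one$canonical_acceptor, c(1200L, 2800L))

  # both acceptors annotated: wild-type majority decides
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(
    contig = "chrP", start = c(900L, 1217L), end = c(1000L, 1300L),
    strand = "+", gene_id = "gp", transcript_id = "tp2"))
  psi <- tibble::tibble(
    event_id = ev$event_id[1], sample = c("w1", "w2"), group = "wt",
    inc_count = c(90L, 88L), skip_count = c(10L, 12L),
    psi = c(0.9, 0.88))   # proximal (inclusion) form dominates WT
  both <- canonical_assignment(ev[1, ], ann2, psi = psi)
  expect_equal(both$assignment, "wt_majority")
  expect_equal(both$canonical_acceptor, 1200L)
  psi$psi <- c(0.1, 0.12) # distal form dominates
  both2 <- canonical_assignment(ev[1, ], ann2, psi = psi)
  expect_equal(both2$canonical_acceptor, 1217L)

  # neither acceptor annotated: excluded with a logged reason
  expect_message(
    none <- canonical_assignment(ev[1, ],
                                 dplyr::filter(ann, contig == "chrM")),
    "excluded")
  expect_equal(none$assignment, "excluded_unannotated")
  expect_true(is.na(none$canonical_acceptor))
})

test_that("distance densities report mean, smoothed mode and direction", {
  d <- tibble::tibble(d = rep(-17L, 40), abs_d = 17L)
  s <- distance_densities(d)
  expect_equal(s$mean_abs_d, 17)
  expect_equal(s$mode_abs_d, 17L)
  expect_equal(s$p_downstream, 0)
  expect_equal(sum(s$hist_abs$n), 40)
  expect_equal(sum(s$hist_signed$n), 40)

  empty <- distance_densities(tibble::tibble(d = integer(),
                                             abs_d = integer()))
  expect_true(empty$empty)
})

test_that("motif matrices equal naive letter counting and are anchored", {
  sim <- build_toy_genome(simulation_config(
    n_events_per_class = c(A3SS = 6), seed = 19))
  joins <- splicesig:::annotation_joins(sim$annotation)
  acc <- tibble::tibble(
    contig = joins$contig, strand = joins$strand,
    acceptor = ifelse(joins$strand == "+", joins$hi, joins$lo))
  mm <- motif_matrix(acc, sim$genome)
  expect_equal(dim(mm$freq), c(4L, 55L))
  expect_equal(unname(colSums(mm$freq)), rep(1, 55), tolerance = 1e-9)
  # genuine acceptors: anchor columns are pure A and pure G
  expect_equal(unname(mm$freq["A", "A"]), 1)
  expect_equal(unname(mm$freq["G", "G"]), 1)

  # independent per-position string-count oracle
  wins <- splicesig:::acceptor_windows(acc, sim$genome)$windows
  chars <- do.call(rbind, strsplit(wins, ""))
  for (pos in c(1, 25, 51, 52, 55)) {
    for (base in c("A", "C", "G", "T")) {
      expect_equal(unname(mm$freq[base, pos]),
                   mean(chars[, pos] == base))
    }
  }

  # single sequence gives a one-hot matrix
  one <- motif_matrix(acc[1, ], sim$genome)
  expect_true(all(one$freq %in% c(0, 1)))
  expect_error(motif_matrix(acc[0, ], sim$genome), "Empty")
})

test_that("polypyrimidine content recovers the generator parameter", {
  # all cryptic sites downstream so the canonical upstream window is clean
  cfg <- simulation_config(
    n_events_per_class = c(A3SS = 40),
    a3ss_offset = list(center = 10, dispersion = 0.5, p_downstream = 1,
                       max = 30),
    intron3p_pyrimidine_frac = 0.8, seed = 23)
  sim <- build_toy_genome(cfg)
  joins <- splicesig:::annotation_joins(sim$annotation)
  acc <- tibble::tibble(
    contig = joins$contig, strand = joins$strand,
    acceptor = ifelse(joins$strand == "+", joins$hi, joins$lo))
  pp <- ppt_content(acc, sim$genome)
  expect_gte(pp$mean_fraction, 0.75)
  expect_lte(pp$mean_fraction, 0.85)

  # window of pure T reads 1.0
  g <- Biostrings::DNAStringSet(c(chrX = paste(
    c(rep("T", 60), "AG", rep("C", 10)), collapse = "")))
  accX <- tibble::tibble(contig = "chrX", strand = "+", acceptor = 62L)
  expect_equal(ppt_content(accX, g)$mean_fraction, 1)

  # uniform background is close to one half
  cfg2 <- simulation_config(n_events_per_class = c(SE = 0), n_genes = 40,
                            intron3p_pyrimidine_frac = 0.5, seed = 29)
  sim2 <- build_toy_genome(cfg2)
  joins2 <- splicesig:::annotation_joins(sim2$annotation)
  acc2 <- tibble::tibble(
    contig = joins2$contig, strand = joins2$strand,
    acceptor = ifelse(joins2$strand == "+", joins2$hi, joins2$lo))
  expect_equal(ppt_content(acc2, sim2$genome)$mean_fraction, 0.5,
               tolerance = 0.05)
})

test_that("strand symmetry: a reverse-complemented fixture gives identical results", {
  # build a plus-strand toy contig and its explicit reverse complement
  cfg <- simulation_config(n_events_per_class = c(A3SS = 4), seed = 37)
  sim <- build_toy_genome(cfg)
  plus_truth <- dplyr::filter(sim$truth, strand == "+")
  minus_truth <- dplyr::filter(sim$truth, strand == "-")
  counts <- simulate_junction_counts(sim)
  catalog <- build_event_catalog(sim$annotation, counts)
  psi <- compute_psi(catalog, counts)
  sig <- a3ss_signature(
    dplyr::inner_join(catalog,
                      dplyr::select(sim$truth, event_id, d_true),
                      by = "event_id"),
    sim$annotation, genome = sim$genome, psi = psi)
  d <- dplyr::inner_join(sig$distances,
                         dplyr::select(sim$truth, event_id, d_true),
                         by = "event_id")
  # identical signed distances on both strands, equal to the planted offset
  expect_equal(d$d, d$d_true)
  expect_true(all(c("+", "-") %in% d$strand))
  # motif matrices from each strand separately agree at the anchors
  for (st in c("+", "-")) {
    accs <- dplyr::filter(sig$distances,
                          event_id %in% sim$truth$event_id[
                            sim$truth$strand == st])
    mm <- motif_matrix(
      dplyr::transmute(accs, contig, strand,
                       acceptor = alternative_acceptor),
      sim$genome)
    expect_equal(unname(mm$freq["A", "A"]), 1)
    expect_equal(unname(mm$freq["G", "G"]), 1)
  }
})

test_that("preset geometry is recovered through the full pipeline", {
  cancer <- cached_run("cancer_like", n_events = 150, seed = 3)
  expect_lte(abs(cancer$signature$summary$mean_abs_d - 17), 1)
  expect_lte(cancer$signature$summary$p_downstream, 0.2)
  ndd <- cached_run("ndd_like", n_events = 150, seed = 3)
  expect_equal(ndd$signature$summary$mode_abs_d, 7L)
  expect_gte(ndd$signature$summary$p_downstream, 0.8)
})
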