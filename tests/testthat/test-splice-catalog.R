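test_that("GTF coordinates convert to 0-based half-open introns", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), gtf)
  ann <- parse_annotation(gtf)
  expect_equal(ann$start, c(0, 200))
  expect_equal(ann$end, c(100, 300))
  joins <- splicesig:::annotation_joins(ann)
  expect_equal(joins$lo, 100)
  expect_equal(joins$hi, 200)
})

test_that("annotation written to GTF round-trips exactly", {
  sim <- build_toy_genome(tiny_config(seed = 12))
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(sim$annotation, gtf)
  back <- parse_annotation(gtf)
  orig <- dplyr::arrange(sim$annotation, contig, transcript_id, start)
  back <- dplyr::arrange(back, contig, transcript_id, start)
  expect_equal(back, orig)
})

test_that("empty junction input is tolerated", {
  p <- tempfile()
  writeLines(character(), p)
  expect_equal(nrow(read_sj(p)), 0)
})

test_that("a shared-donor junction pair is classified as A3SS", {
  junctions <- tibble::tibble(
    contig = "chr1", strand = "+", lo = 1000L, hi = c(1200L, 1217L),
    count = 10L, sample = "s1")
  ann <- tibble::tibble(contig = "chr1", start = c(900L, 1200L),
                        end = c(1000L, 1300L), strand = "+",
                        gene_id = "g1", transcript_id = "t1")
  cat1 <- build_event_catalog(ann, junctions)
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$class, "A3SS")
  expect_equal(cat1$donor, 1000)
  expect_equal(cat1$acc_proximal, 1200)
  expect_equal(cat1$acc_distal, 1217)
  # the 1217 acceptor matches no annotated join, so the event is novel
  expect_true(cat1$novel)
})

test_that("catalog equals ground truth and a brute-force pair oracle", {
  cfg <- simulation_config(
    n_events_per_class = c(SE = 1, A5SS = 1, A3SS = 1, RI = 1, MXE = 1),
    n_genes = 5, seed = 8)
  sim <- simulate_splicing(cfg)
  catalog <- build_event_catalog(sim$annotation, sim$junctions)
  expect_setequal(catalog$event_id, sim$truth$event_id)
  by_id <- dplyr::inner_join(
    dplyr::select(catalog, event_id, class, contig, strand),
    dplyr::select(sim$truth, event_id, class, contig, strand),
    by = "event_id", suffix = c("_cat", "_truth"))
  expect_equal(by_id$class_cat, by_id$class_truth)
  expect_equal(by_id$strand_cat, by_id$strand_truth)

  # naive oracle for A3SS/A5SS: loop over all real junction pairs
  real <- sim$junctions |>
    dplyr::distinct(contig, strand, lo, hi) |>
    dplyr::filter(hi - lo > 20)
  found <- character()
  for (i in seq_len(nrow(real))) {
    for (j in seq_len(nrow(real))) {
      if (i >= j) next
      a <- real[i, ]; b <- real[j, ]
      if (a$contig != b$contig) next
      donor_a <- if (a$strand == "+") a$lo else a$hi
      donor_b <- if (b$strand == "+") b$lo else b$hi
      acc_a <- if (a$strand == "+") a$hi else a$lo
      acc_b <- if (b$strand == "+") b$hi else b$lo
      between <- function(p, q) {
        ends <- c(real$lo[real$contig == a$contig],
                  real$hi[real$contig == a$contig])
        any(ends > min(p, q) & ends < max(p, q))
      }
      if (donor_a == donor_b && !between(acc_a, acc_b)) {
        found <- c(found, event_key("A3SS", a$contig, a$strand,
                                    c(donor_a, acc_a, acc_b)))
      }
      if (acc_a == acc_b && !between(donor_a, donor_b)) {
        found <- c(found, event_key("A5SS", a$contig, a$strand,
                                    c(acc_a, donor_a, donor_b)))
      }
    }
  }
  expect_setequal(found,
                  catalog$event_id[catalog$class %in% c("A3SS", "A5SS")])
})

test_that("event ids do not depend on input row order", {
  sim <- simulate_splicing(tiny_config(seed = 14))
  cat1 <- build_event_catalog(sim$annotation, sim$junctions)
  withr::with_seed(1, {
    shuffled <- sim$junctions[sample(nrow(sim$junctions)), ]
  })
  cat2 <- build_event_catalog(sim$annotation, shuffled)
  expect_identical(cat1$event_id, cat2$event_id)
  expect_identical(cat1$novel, cat2$novel)
})

test_that("PSI follows the length-adjusted junction-count formula", {
  catalog <- tibble::tibble(
    event_id = "SE:chr1:+:1", class = "SE", contig = "chr1", strand = "+",
    inc_junc = list(c("chr1:+:100:200", "chr1:+:260:340")),
    skip_junc = list("chr1:+:100:340"), l_inc = 2L, l_skip = 1L)
  junctions <- tibble::tibble(
    contig = "chr1", strand = "+",
    lo = c(100L, 260L, 100L), hi = c(200L, 340L, 340L),
    count = c(12L, 8L, 20L), sample = "s1")
  psi <- compute_psi(catalog, junctions)
  # I = 20, S = 20, L_inc = 2, L_skip = 1 -> 10 / (10 + 20)
  expect_equal(psi$psi, 1 / 3)

  junctions$count <- c(5L, 7L, 0L)   # S = 0 -> PSI 1
  expect_equal(compute_psi(catalog, junctions)$psi, 1)

  junctions$count <- c(0L, 0L, 0L)   # undefined
  expect_true(is.na(compute_psi(catalog, junctions)$psi))
})

test_that("PSI is monotone nondecreasing in inclusion reads", {
  catalog <- tibble::tibble(
    event_id = "A3SS:chr1:+:1", class = "A3SS", contig = "chr1",
    strand = "+", inc_junc = list("chr1:+:100:200"),
    skip_junc = list("chr1:+:100:240"), l_inc = 1L, l_skip = 1L)
  psis <- vapply(c(0L, 5L, 50L, 500L), function(i) {
    junctions <- tibble::tibble(
      contig = "chr1", strand = "+", lo = c(100L, 100L),
      hi = c(200L, 240L), count = c(i, 30L), sample = "s1")
    compute_psi(catalog, junctions)$psi
  }, numeric(1))
  expect_true(all(diff(psis) >= 0))
  expect_true(all(psis >= 0 & psis <= 1))
})

test_that("coverage filter keeps events by mean reads, not minimum", {
  psi <- tibble::tibble(
    event_id = rep(c("e1", "e2"), c(6, 3)),
    sample = c(paste0("s", 1:6), paste0("s", 1:3)),
    inc_count = c(rep(4L, 6), 0L, 0L, 30L),
    skip_count = c(rep(5L, 6), 0L, 0L, 30L),
    psi = 0.5)
  kept <- coverage_filter(psi, 10)
  expect_setequal(unique(kept$event_id), "e2")  # mean 9 dropped, mean 20 kept
  expect_equal(nrow(coverage_filter(psi, 0)), nrow(psi))

  sim <- simulate_splicing(tiny_config(seed = 31, mean_event_coverage = 12))
  catalog <- build_event_catalog(sim$annotation, sim$junctions)
  p <- compute_psi(catalog, sim$junctions)
  kept <- coverage_filter(p, 10)
  # independent recount
  manual <- tapply(p$inc_count + p$skip_count, p$event_id, mean)
  expect_setequal(unique(kept$event_id), names(manual)[manual >= 10])
})

test_that("strand symmetry: events on minus-strand genes behave like plus", {
  sim <- simulate_splicing(tiny_config(seed = 44))
  catalog <- build_event_catalog(sim$annotation, sim$junctions)
  # genes alternate strands; both strands must be represented and recovered
  expect_setequal(unique(catalog$strand), c("+", "-"))
  expect_setequal(catalog$event_id, sim$truth$event_id)
})
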