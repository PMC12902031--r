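test_that("configuration invariants are enforced", {
  expect_error(simulation_config(fraction_null_events = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(intron_len = c(80, 100)), ">= 120")
  expect_error(simulation_config(
    a3ss_offset = list(center = 0, dispersion = 0.5, p_downstream = 0.5)),
    ">= 1")
  expect_error(simulation_config(n_events_per_class = c(A3SS = 10),
                                 n_genes = 5), "n_genes")
  expect_error(sim_preset("nope"), "Valid presets")
  cfg <- simulation_config(n_events_per_class = c(A3SS = 1))
  expect_error(simulate_junction_counts(
    structure(list(config = cfg), class = "splice_sim"),
    utils::modifyList(cfg, list(mean_event_coverage = 0))),
    "coverage")
})

test_that("presets encode the documented cryptic-acceptor geometries", {
  ndd <- sim_preset("ndd_like")
  expect_equal(ndd$a3ss_offset$center, 7)
  expect_gte(ndd$a3ss_offset$p_downstream, 0.8)
  cancer <- sim_preset("cancer_like")
  expect_equal(cancer$a3ss_offset$center, 17)
  expect_lte(cancer$a3ss_offset$p_downstream, 0.2)
  null <- sim_preset("null")
  expect_equal(null$fraction_null_events, 1)
  sim <- build_toy_genome(sim_preset("null", n_events = 20, seed = 3))
  expect_false(any(sim$truth$is_differential))
})

test_that("identical seeds give byte-identical genome, annotation and counts", {
  cfg <- tiny_config(seed = 17)
  s1 <- simulate_splicing(cfg)
  s2 <- simulate_splicing(tiny_config(seed = 17))
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$junctions, s2$junctions)
  s3 <- simulate_splicing(tiny_config(seed = 18))
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("all planted acceptors read AG (and donors GT) on the transcribed strand", {
  sim <- build_toy_genome(tiny_config(seed = 5))
  seqs <- as.character(sim$genome)
  joins <- splicesig:::annotation_joins(sim$annotation)
  # independent brute-force string lookup on the emitted sequences
  for (r in seq_len(nrow(joins))) {
    s <- seqs[[joins$contig[r]]]
    lo <- joins$lo[r]; hi <- joins$hi[r]
    if (joins$strand[r] == "+") {
      expect_identical(substr(s, lo + 1, lo + 2), "GT")
      expect_identical(substr(s, hi - 1, hi), "AG")
    } else {
      # transcribed-strand GT/AG are genomic CT/AC reverse-complemented
      expect_identical(substr(s, hi - 1, hi), "AC")
      expect_identical(substr(s, lo + 1, lo + 2), "CT")
    }
  }
  # cryptic acceptors too: every A3SS truth junction end is an AG
  a3 <- dplyr::filter(sim$truth, class == "A3SS")
  keys <- splicesig:::parse_junc_key(unlist(c(a3$inc_junc, a3$skip_junc)))
  for (r in seq_len(nrow(keys))) {
    s <- seqs[[keys$contig[r]]]
    if (keys$strand[r] == "+") {
      expect_identical(substr(s, keys$hi[r] - 1, keys$hi[r]), "AG")
    } else {
      expect_identical(substr(s, keys$lo[r] + 1, keys$lo[r] + 2), "CT")
    }
  }
})

test_that("fixed offset configuration plants every cryptic site at -17 nt", {
  cfg <- simulation_config(
    n_events_per_class = c(A3SS = 8),
    a3ss_offset = list(center = 17, dispersion = 0, p_downstream = 0),
    seed = 9)
  sim <- build_toy_genome(cfg)
  expect_true(all(sim$truth$d_true == -17))
})

test_that("zero planted events yields a constitutive-only annotation", {
  cfg <- simulation_config(n_events_per_class = c(SE = 0), n_genes = 3,
                           seed = 2)
  sim <- build_toy_genome(cfg)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(dplyr::n_distinct(sim$annotation$transcript_id), 3)
  counts <- simulate_junction_counts(sim)
  expect_gt(nrow(counts), 0)
})

test_that("empirical PSI concentrates around the truth at high coverage", {
  cfg <- simulation_config(
    n_events_per_class = c(SE = 2), baseline_psi = c(0.5, 0.5),
    fraction_null_events = 1, mean_event_coverage = 10000,
    coverage_size = 1e6, seed = 21)
  sim <- simulate_splicing(cfg)
  catalog <- build_event_catalog(sim$annotation, sim$junctions)
  psi <- compute_psi(catalog, sim$junctions)
  expect_true(all(psi$psi >= 0.48 & psi$psi <= 0.52))
})

test_that("averaged empirical PSI converges to ground truth", {
  cfg <- simulation_config(
    n_events_per_class = c(SE = 3, A3SS = 4, RI = 2, MXE = 2, A5SS = 3),
    replicates_per_group = 6, mean_event_coverage = 300, seed = 33)
  sim <- simulate_splicing(cfg)
  catalog <- build_event_catalog(sim$annotation, sim$junctions)
  psi <- compute_psi(catalog, sim$junctions)
  means <- psi |>
    dplyr::inner_join(sim$truth, by = "event_id") |>
    dplyr::group_by(event_id, group) |>
    dplyr::summarise(
      est = mean(psi, na.rm = TRUE),
      truth = ifelse(group[1] == "wt", psi_wt[1], psi_var[1]),
      n = sum(inc_count + skip_count), .groups = "drop")
  # binomial CI check: estimate within ~4 SE of truth for >= 95% of events
  ok <- with(means, abs(est - truth) <= 4 * sqrt(truth * (1 - truth) / n)
             + 0.01)
  expect_gte(mean(ok), 0.95)
})
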