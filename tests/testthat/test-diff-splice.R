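test_that("delta PSI is the mean difference and is antisymmetric", {
  expect_equal(delta_psi(c(0.2, 0.2, 0.2), c(0.5, 0.5, 0.5)), 0.3)
  expect_equal(delta_psi(c(0.4, 0.6), c(0.4, 0.6)), 0)
  a <- c(0.1, 0.3, NA); b <- c(0.6, 0.7, 0.8)
  expect_equal(delta_psi(a, b), -delta_psi(b, a))
  expect_true(is.na(delta_psi(c(NA, NA), c(0.5))))
})

test_that("the likelihood-ratio test is null-calibrated and matches exact tests", {
  # identical groups: statistic 0, p = 1
  res <- test_event(inc = c(10, 10, 10, 10), skip = c(5, 5, 5, 5),
                    group = c("wt", "wt", "var", "var"))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # group-swap invariance
  inc <- c(12, 9, 30, 25); skip <- c(20, 22, 11, 14)
  g1 <- c("wt", "wt", "var", "var"); g2 <- c("var", "var", "wt", "wt")
  expect_equal(test_event(inc, skip, g1)$p_value,
               test_event(inc, skip, g2)$p_value)

  # all-zero counts are untestable
  expect_true(is.na(test_event(c(0, 0), c(0, 0), c("wt", "var"))$p_value))

  # agreement with an exact conditional test on a pooled 2x2 with large
  # counts (compared at moderate p, where the relative scale is stable)
  withr::with_seed(5, {
    n_checked <- 0
    while (n_checked < 5) {
      i_wt <- rbinom(3, 400, 0.3); s_wt <- 400 - i_wt
      i_var <- rbinom(3, 400, 0.3); s_var <- 400 - i_var
      p_lrt <- test_event(c(i_wt, i_var), c(s_wt, s_var),
                          rep(c("wt", "var"), each = 3))$p_value
      tab <- matrix(c(sum(i_wt), sum(s_wt), sum(i_var), sum(s_var)), 2)
      p_exact <- fisher.test(tab)$p.value
      if (p_exact < 0.05 || p_exact > 0.95) next
      expect_lt(abs(p_lrt - p_exact) / p_exact, 0.10)
      n_checked <- n_checked + 1
    }
  })
})

test_that("type-I error is near nominal under a binomial null", {
  withr::with_seed(1234, {
    n_events <- 2000
    pvals <- vapply(seq_len(n_events), function(e) {
      psi <- runif(1, 0.2, 0.8)
      tot <- rnbinom(6, mu = 100, size = 20) + 1
      inc <- rbinom(6, tot, psi)
      test_event(inc, tot - inc, rep(c("wt", "var"), each = 3))$p_value
    }, numeric(1))
  })
  alpha_hat <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gte(alpha_hat, 0.03)
  expect_lte(alpha_hat, 0.07)
})

test_that("threshold presets filter correctly and are nested", {
  diff <- tibble::tibble(
    event_id = sprintf("e%02d", 1:8),
    mean_psi_wt = c(0.05, 0.3, 0.3, 0.05, 0.5, 0.02, 0.3, 0.4),
    mean_psi_var = c(0.14, 0.6, 0.39, 0.02, 0.22, 0.05, 0.7, 0.1),
    mean_reads = c(50, 50, 50, 50, 50, 50, 5, 50),
    p_value = c(1e-4, 1e-5, 1e-3, 0.5, 1e-4, 1e-6, 1e-5, 1e-4),
    testable = TRUE)
  diff$delta_psi <- diff$mean_psi_var - diff$mean_psi_wt
  diff$fdr <- bh_fdr(diff$p_value)
  diff$significant_010 <- NA; diff$significant_025 <- NA
  class(diff) <- c("splice_diff", class(diff))

  loose <- apply_thresholds(diff, threshold_preset("k562_default"))
  strict <- apply_thresholds(diff, threshold_preset("k562_strict"))
  # |delta| = 0.09 excluded under the 0.10 preset
  expect_false("e01" %in% loose$event_id)
  # low coverage excluded despite large effect
  expect_false("e07" %in% loose$event_id)
  # nestedness of presets
  expect_true(all(strict$event_id %in% loose$event_id))

  # independent brute-force re-filter
  manual <- with(diff, pmax(mean_psi_wt, mean_psi_var) >= 0.1 &
                   abs(delta_psi) >= 0.1 & fdr < 0.05 & mean_reads >= 10)
  expect_setequal(loose$event_id, diff$event_id[manual])
})

test_that("per-gene deduplication keeps the most significant event", {
  diff <- tibble::tibble(
    event_id = c("a", "b", "c", "d", "e"),
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    class = c("SE", "SE", "SE", "A3SS", "RI"),
    fdr = c(0.2, 0.01, 0.05, 0.04, 0.9),
    p_value = c(0.1, 0.001, 0.01, 0.008, 0.8))
  out <- dedup_per_gene(diff)
  expect_setequal(out$event_id, c("b", "c", "d", "e"))
  # single-event genes are untouched; size = distinct (gene, class) pairs
  expect_equal(nrow(out),
               nrow(dplyr::distinct(diff, gene_id, class)))
  single <- diff[3:5, ]
  expect_equal(nrow(dedup_per_gene(single)), 3)
})

test_that("untestable events are excluded from the BH denominator", {
  psi <- tibble::tibble(
    event_id = rep(c("e1", "e2", "e3"), each = 4),
    sample = rep(c("w1", "w2", "v1", "v2"), 3),
    group = rep(c("wt", "wt", "var", "var"), 3),
    inc_count = c(10, 12, 30, 28, 5, 6, 5, 7, 0, 0, 0, 0),
    skip_count = c(20, 18, 5, 6, 15, 14, 15, 13, 0, 0, 0, 0)) |>
    dplyr::mutate(psi = ifelse(inc_count + skip_count == 0, NA,
                               inc_count / (inc_count + skip_count)))
  d <- diff_splice(psi)
  expect_false(d$testable[d$event_id == "e3"])
  testable_p <- d$p_value[d$testable]
  expect_equal(d$fdr[d$testable], p.adjust(testable_p, "BH"))
  expect_true(is.na(d$fdr[d$event_id == "e3"]))
})

test_that("differential A3SS events are recovered with high power", {
  run <- cached_run("ndd_like", n_events = 200, seed = 7)
  truth <- run$sim$truth
  called <- run$significant$event_id
  power <- mean(truth$event_id[truth$is_differential] %in% called)
  expect_gte(power, 0.8)
  # empirical FDR among declared events at most twice nominal
  if (length(called) > 0) {
    fdp <- mean(!called %in% truth$event_id[truth$is_differential])
    expect_lte(fdp, 0.10)
  }
})

test_that("a null simulation yields about the nominal significant fraction", {
  run <- cached_run("null", n_events = 300, seed = 13)
  frac <- nrow(run$significant) / nrow(run$diff)
  expect_lte(frac, 3 * 0.05)
})
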