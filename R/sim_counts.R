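# Per-sample junction count simulation.

#' Simulate per-sample splice-junction counts
#'
#' For every planted event, replicate and condition, the total event
#' coverage is drawn from a negative binomial around
#' `mean_event_coverage`, and inclusion reads from a binomial with the
#' condition's length-adjusted true inclusion proportion
#' `q = psi * L_inc / (psi * L_inc + (1 - psi) * L_skip)`, so that the
#' length-adjusted PSI estimator is unbiased for the true PSI. Reads are
#' split uniformly among the junctions of each form. Constitutive introns
#' receive independent negative-binomial counts.
#'
#' @param sim A `"splice_sim"` object from [build_toy_genome()].
#' @param config Optional override of `sim$config`.
#' @return A tibble of junction records: `sample`, `group` (`"wt"`/`"var"`),
#'   `contig`, `strand`, `lo`, `hi` (0-based half-open intron interval),
#'   `count`. Retained-intron evidence appears as 2-nt boundary-straddling
#'   pseudo-junction records.
#' @examples
#' sim <- build_toy_genome(simulation_config(
#'   n_events_per_class = c(SE = 1), seed = 2))
#' simulate_junction_counts(sim)
#' @export
simulate_junction_counts <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "splice_sim"), inherits(config, "sim_config"))
  if (config$mean_event_coverage <= 0) {
    abort("Requested zero or negative event coverage.")
  }
  with_seed(child_seed(config$seed, 2L),
            simulate_junction_counts_impl(sim, config))
}

simulate_junction_counts_impl <- function(sim, config) {
  nrep <- config$replicates_per_group
  samples <- tibble(
    sample = c(sprintf("wt_%d", seq_len(nrep)),
               sprintf("var_%d", seq_len(nrep))),
    group = rep(c("wt", "var"), each = nrep)
  )
  truth <- sim$truth
  out <- vector("list", nrow(samples))

  for (s in seq_len(nrow(samples))) {
    grp <- samples$group[s]
    rows <- vector("list", nrow(truth) + 1L)
    if (nrow(truth) > 0) {
      for (e in seq_len(nrow(truth))) {
        psi <- if (grp == "wt") truth$psi_wt[e] else truth$psi_var[e]
        l_inc <- truth$l_inc[e]; l_skip <- truth$l_skip[e]
        q <- psi * l_inc / (psi * l_inc + (1 - psi) * l_skip)
        total <- rnbinom(1L, mu = config$mean_event_coverage,
                         size = config$coverage_size)
        i_reads <- rbinom(1L, total, q)
        s_reads <- total - i_reads
        split_counts <- function(n, k) {
          if (k == 1L) return(n)
          as.integer(stats::rmultinom(1L, n, rep(1 / k, k)))
        }
        keys <- c(truth$inc_junc[[e]], truth$skip_junc[[e]])
        cnts <- c(split_counts(i_reads, l_inc), split_counts(s_reads, l_skip))
        rows[[e]] <- mutate(parse_junc_key(keys), count = cnts)
      }
    }
    if (nrow(sim$constitutive) > 0) {
      rows[[nrow(truth) + 1L]] <- sim$constitutive %>%
        select(-"gene_id") %>%
        mutate(count = rnbinom(dplyr::n(), mu = config$mean_event_coverage,
                               size = config$coverage_size))
    }
    out[[s]] <- bind_rows(rows) %>%
      mutate(sample = samples$sample[s], group = grp)
  }

  bind_rows(out) %>%
    select("sample", "group", "contig", "strand", "lo", "hi", "count") %>%
    arrange(.data$sample, .data$contig, .data$lo, .data$hi)
}

#' Run the full simulation (genome + counts)
#'
#' Convenience wrapper combining [build_toy_genome()] and
#' [simulate_junction_counts()].
#'
#' @inheritParams simulate_junction_counts
#' @param config A [simulation_config()] object.
#' @return The `"splice_sim"` list with an added `junctions` tibble and
#'   `samples` table.
#' @export
simulate_splicing <- function(config) {
  sim <- build_toy_genome(config)
  sim$junctions <- simulate_junction_counts(sim, config)
  sim$samples <- distinct(sim$junctions, .data$sample, .data$group)
  sim
}
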