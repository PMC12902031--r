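# Simulation configuration and named presets.

#' Build a simulation configuration
#'
#' Collects and validates every tunable of the synthetic splice-junction
#' generator. The generator plants one alternative-splicing event per gene
#' on a toy genome (one contig per gene), so `n_genes` must be at least the
#' total number of requested events; by default it is chosen automatically
#' with a few purely constitutive filler genes.
#'
#' @param n_events_per_class Named integer vector with entries `SE`, `A5SS`,
#'   `A3SS`, `RI`, `MXE`: number of planted events per splicing class.
#' @param n_genes Number of genes/contigs; `NULL` (default) auto-sizes to
#'   the event total plus three constitutive genes.
#' @param exons_per_gene Exons per gene (>= 4; mutually-exclusive-exon
#'   events need two alternative internal exons plus flanks).
#' @param exon_len,intron_len Length ranges (nt), `c(min, max)`. Introns
#'   must be at least 120 nt so that acceptor motif windows (50 nt of
#'   intron) never leave the intron.
#' @param replicates_per_group Biological replicates per condition (the
#'   study design this emulates used 3 vs 3).
#' @param mean_event_coverage Mean total junction-read coverage per event
#'   and replicate (negative-binomial total, binomial inclusion split).
#' @param coverage_size Negative-binomial size (inverse dispersion) of the
#'   per-replicate event coverage.
#' @param fraction_null_events Fraction of planted events with identical
#'   true PSI in the two conditions.
#' @param fraction_novel_events Fraction of events whose alternative
#'   isoform is left out of the emitted annotation (novel junctions).
#' @param delta_psi_effect Range `c(min, max)` of |true delta PSI| for
#'   differential events (uniform draw).
#' @param baseline_psi Range `c(min, max)` of the condition-1 usage of the
#'   alternative (cryptic) isoform.
#' @param a3ss_offset List with `center` (nt, >= 1), `dispersion` (geometric
#'   decay rate in `[0, 1)`; 0 gives a point mass at `center`),
#'   `p_downstream` (probability the cryptic site lies downstream of the
#'   canonical site, i.e. inside the exon) and `max` (hard cap on |offset|).
#'   Also used, mirrored, for alternative 5' splice-site donors.
#' @param intron3p_pyrimidine_frac Pyrimidine (C/T) fraction of the 50
#'   intronic nt upstream of each canonical acceptor AG.
#' @param seed Integer seed; identical configurations (including seed)
#'   yield byte-identical FASTA/GTF/count outputs.
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- simulation_config(n_events_per_class = c(SE = 2, A3SS = 2), seed = 7)
#' @export
simulation_config <- function(n_events_per_class = c(SE = 10, A5SS = 10,
                                                     A3SS = 10, RI = 10,
                                                     MXE = 10),
                              n_genes = NULL,
                              exons_per_gene = 4,
                              exon_len = c(80, 150),
                              intron_len = c(150, 400),
                              replicates_per_group = 3,
                              mean_event_coverage = 100,
                              coverage_size = 20,
                              fraction_null_events = 0.5,
                              fraction_novel_events = 0.6,
                              delta_psi_effect = c(0.25, 0.35),
                              baseline_psi = c(0.05, 0.2),
                              a3ss_offset = list(center = 7, dispersion = 0.7,
                                                 p_downstream = 0.8, max = 40),
                              intron3p_pyrimidine_frac = 0.8,
                              seed = 1) {
  classes <- c("SE", "A5SS", "A3SS", "RI", "MXE")
  ev <- setNames(rep(0L, 5L), classes)
  if (length(n_events_per_class)) {
    if (is.null(names(n_events_per_class)) ||
        !all(names(n_events_per_class) %in% classes)) {
      abort("`n_events_per_class` must be named with classes SE/A5SS/A3SS/RI/MXE.")
    }
    ev[names(n_events_per_class)] <- as.integer(n_events_per_class)
  }
  if (any(ev < 0)) abort("Event counts must be non-negative.")
  n_events <- sum(ev)
  if (is.null(n_genes)) n_genes <- n_events + 3L
  assert_count(n_genes, "n_genes")
  if (n_genes < n_events) {
    abort(sprintf("`n_genes` (%d) must be >= total planted events (%d).",
                  n_genes, n_events))
  }
  assert_count(exons_per_gene, "exons_per_gene")
  if (exons_per_gene < 4) abort("`exons_per_gene` must be >= 4.")
  stopifnot(length(exon_len) == 2L, length(intron_len) == 2L,
            exon_len[1] <= exon_len[2], intron_len[1] <= intron_len[2])
  if (exon_len[1] < 60) abort("Minimum exon length must be >= 60 nt.")
  if (intron_len[1] < 120) {
    abort("Minimum intron length must be >= 120 nt so motif windows fit.")
  }
  assert_count(replicates_per_group, "replicates_per_group")
  if (mean_event_coverage <= 0) abort("`mean_event_coverage` must be > 0.")
  if (coverage_size <= 0) abort("`coverage_size` must be > 0.")
  assert_fraction(fraction_null_events, "fraction_null_events")
  assert_fraction(fraction_novel_events, "fraction_novel_events")
  stopifnot(length(delta_psi_effect) == 2L,
            delta_psi_effect[1] <= delta_psi_effect[2])
  assert_fraction(delta_psi_effect[1], "delta_psi_effect[1]")
  assert_fraction(delta_psi_effect[2], "delta_psi_effect[2]")
  stopifnot(length(baseline_psi) == 2L, baseline_psi[1] <= baseline_psi[2])
  off <- a3ss_offset
  off$max <- off$max %||% 40L
  if (!all(c("center", "dispersion", "p_downstream") %in% names(off))) {
    abort("`a3ss_offset` needs elements center, dispersion, p_downstream.")
  }
  if (off$center < 1) abort("`a3ss_offset$center` must be >= 1 nt.")
  if (off$dispersion < 0 || off$dispersion >= 1) {
    abort("`a3ss_offset$dispersion` must lie in [0, 1).")
  }
  assert_fraction(off$p_downstream, "a3ss_offset$p_downstream")
  assert_fraction(intron3p_pyrimidine_frac, "intron3p_pyrimidine_frac")
  assert_count(seed, "seed", positive = FALSE)

  structure(
    list(
      n_genes = as.integer(n_genes),
      exons_per_gene = as.integer(exons_per_gene),
      exon_len = as.integer(exon_len),
      intron_len = as.integer(intron_len),
      n_events_per_class = ev,
      replicates_per_group = as.integer(replicates_per_group),
      mean_event_coverage = mean_event_coverage,
      coverage_size = coverage_size,
      fraction_null_events = fraction_null_events,
      fraction_novel_events = fraction_novel_events,
      delta_psi_effect = delta_psi_effect,
      baseline_psi = baseline_psi,
      a3ss_offset = off,
      intron3p_pyrimidine_frac = intron3p_pyrimidine_frac,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Named simulation presets
#'
#' Three ready-made configurations emulating the cryptic 3' splice-site
#' geometries reported for splicing-factor variant classes:
#'
#' * `"ndd_like"` — cryptic acceptors peaked 7 nt from the canonical AG,
#'   predominantly downstream (inside the exon), as seen for
#'   neurodevelopmental-disorder-associated variants.
#' * `"cancer_like"` — cryptic acceptors with mean absolute distance 17 nt,
#'   predominantly upstream (inside the intron), as seen for the K700E-class
#'   somatic variants.
#' * `"null"` — no differential events (all true delta PSI are zero); used
#'   for calibration runs.
#'
#' All presets plant A3SS events only, with 3 replicates per condition and
#' mean event coverage 100.
#'
#' @param name One of `"ndd_like"`, `"cancer_like"`, `"null"`.
#' @param n_events Number of planted A3SS events (default 500).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [simulation_config()] to override
#'   preset defaults.
#' @return A `"sim_config"` object.
#' @examples
#' sim_preset("ndd_like", n_events = 50, seed = 3)
#' @export
sim_preset <- function(name, n_events = 500, seed = 1, ...) {
  valid <- c("ndd_like", "cancer_like", "null")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    abort(sprintf("Unknown preset %s. Valid presets: %s.",
                  deparse(name), paste(valid, collapse = ", ")))
  }
  base <- list(
    n_events_per_class = c(A3SS = as.integer(n_events)),
    replicates_per_group = 3,
    mean_event_coverage = 100,
    fraction_novel_events = 1,   # cryptic sites are unannotated by definition
    seed = seed
  )
  preset <- switch(
    name,
    ndd_like = list(
      a3ss_offset = list(center = 7, dispersion = 0.7,
                         p_downstream = 0.85, max = 40),
      fraction_null_events = 0.2
    ),
    cancer_like = list(
      a3ss_offset = list(center = 17, dispersion = 0.7,
                         p_downstream = 0.1, max = 40),
      fraction_null_events = 0.2
    ),
    null = list(
      a3ss_offset = list(center = 7, dispersion = 0.7,
                         p_downstream = 0.85, max = 40),
      fraction_null_events = 1
    )
  )
  args <- utils::modifyList(c(base, preset), list(...))
  do.call(simulation_config, args)
}

# draw signed offsets: |d| ~ discretized two-sided geometric around `center`
# (P(m) proportional to dispersion^|m - center|), truncated to
# [min_abs, max_abs]; sign is +1 (downstream) with probability p_downstream.
# min_abs = 2 in the genome builder: the cryptic and canonical AG boxes must
# not overlap, which rules out |d| = 1.
sample_offsets <- function(n, offset, max_abs = NULL, min_abs = 1L) {
  max_abs <- min(offset$max, max_abs %||% offset$max)
  if (max_abs < min_abs) {
    abort("No room for a cryptic site offset within the flanking features.")
  }
  support <- seq(min_abs, max_abs)
  w <- if (offset$dispersion == 0) {
    as.numeric(support == min(offset$center, max_abs))
  } else {
    offset$dispersion^abs(support - offset$center)
  }
  if (sum(w) == 0) w <- as.numeric(support == max_abs)
  mag <- support[sample.int(length(support), n, replace = TRUE,
                            prob = w / sum(w))]
  sgn <- ifelse(runif(n) < offset$p_downstream, 1L, -1L)
  as.integer(sgn * mag)
}
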