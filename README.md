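# splicesig

Junction-level alternative-splicing analysis and cryptic 3' splice-site
signatures for two-condition RNA-seq designs.

## The problem

Missense variants in core spliceosome factors (SF3B1 is the canonical
example) do not simply break splicing — they *shift* it. By perturbing
branch-point recognition they change which 3' splice-site AG the U2 snRNP
selects, producing alternative 3' splice-site (A3'SS) events whose cryptic
acceptor AG' sits a characteristic distance and direction away from the
canonical AG: cancer-associated hotspot variants favour cryptic AG'
upstream of the canonical site (mean |d| around 17 nt, inside the intron),
whereas the germline, neurodevelopmental-disorder-associated variants
favour nearby downstream AG' (distance distribution peaked near 7 nt,
inside the exon). Detecting and quantifying that signature requires a
junction-level pipeline: event detection, percent-spliced-in (PSI)
estimation, differential testing, and sequence analysis around the
competing acceptors.

`splicesig` implements that pipeline end to end for anyone analysing
splicing-factor variants (or benchmarking tools that do), together with a
seeded synthetic splice-junction generator so every stage can be exercised
and validated at desk scale, a cross-condition event-overlap module, a
clinical phenotype clustering module, and the exact small-sample
statistics the accompanying assays need.

## The model

* **PSI** — for an event with inclusion reads `I` spread over `L_inc`
  supporting junctions and skipping reads `S` over `L_skip`:

  `psi = (I / L_inc) / (I / L_inc + S / L_skip)`

  (undefined when `I + S = 0`). Events come in the five standard classes
  SE, A5'SS, A3'SS, RI, MXE, detected from junction evidence with novel
  splice sites allowed.
* **Differential splicing** — per event, a binomial likelihood-ratio test
  (df = 1) of a shared versus per-group read-level inclusion proportion,
  BH-adjusted over testable events; `delta PSI = mean PSI(var) - mean
  PSI(wt)`; threshold presets at |dPSI| >= 0.1 / 0.25 (FDR < 0.05,
  max-group PSI >= 0.1, mean coverage >= 10) and a lymphocyte preset
  (|dPSI| >= 0.05, FDR < 0.1, one event per gene).
* **A3'SS signature** — signed distance `d` = alternative minus canonical
  acceptor along the transcription direction (negative = upstream/intronic),
  distance histograms with smoothed mode, direction bias `p_downstream`,
  55-position acceptor motif matrices (50 intronic nt + AG + 3 exonic nt)
  and polypyrimidine-tract content over [-20, -5].
* **Phenotype clustering** — clinical features encoded 0 / 0.5 / 1 with
  missing values retained, pairwise-complete Euclidean distance
  (rescaled), Ward (`ward.D2`) linkage, and a >30%-missingness
  sensitivity reanalysis.
* **Exact statistics** — a fully enumerated two-sided Mann-Whitney test
  (mid-ranks under ties; for n = m = 4 the smallest achievable two-sided
  p is 2/70 ≈ 0.0286), BH FDR, and the Yates-corrected two-proportion
  chi-square test.

## Worked example

```r
library(splicesig)

run <- run_pipeline(sim_preset("ndd_like", n_events = 200, seed = 42))
run
#> splicesig pipeline run
#> # A tibble: 6 × 2
#>   stage                  n
#>   <chr>              <int>
#> 1 events_planted       200
#> 2 events_detected      200
#> 3 events_covered       200
#> 4 events_testable      200
#> 5 events_significant   166
#> 6 a3ss_significant     166
#> Cryptic 3' splice-site signature
#>   events: 166 (excluded: 0)
#>   mean |d|: 7.75 nt   modal |d|: 7 nt   downstream: 88.6%
```

All 200 planted A3'SS events are re-detected from the simulated junction
tables; 166 pass the default significance preset (the remainder are
planted null events). The signature stage recovers the generator's
NDD-like geometry: modal cryptic-to-canonical distance 7 nt with ~89% of
cryptic acceptors downstream of the canonical AG. `autoplot(run$diff)`
draws the volcano plot, `plot_distance_density(...)` the distance
densities, and `autoplot(run$signature$motif_cryptic)` the acceptor motif
profile.

Clinical phenotype clustering on the bundled synthetic cohort:

```r
raw <- readr::read_tsv(system.file("extdata",
  "synthetic_cohort_phenotypes.tsv", package = "splicesig"))
cl <- cluster_phenotypes(encode_phenotypes(raw), k = 3)
cl
#> Phenotype clustering: 26 patients, k = 3 (ward.D2)
#> # A tibble: 3 × 2
#>   cluster     n
#>     <int> <int>
#> 1       1     9
#> 2       2    10
#> 3       3     7
```

Real rMATS `*.MATS.JC.txt` tables can be fed into the signature stage
directly with `ingest_rmats()`; a synthetic example file ships in
`inst/extdata/`.

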