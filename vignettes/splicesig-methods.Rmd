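---
title: "Methods: junction-level splicing signatures in splicesig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-level splicing signatures in splicesig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicesig)
```

`splicesig` analyses how splicing-factor perturbations shift splice-site
choice. This vignette documents the statistical model, the conventions
and numerical choices behind each stage, what the synthetic generator
does and does not emulate, and the known limitations. It states no
empirical result beyond what the package's tests and acceptance script
themselves compute.

## Coordinates and event conventions

All internal coordinates are 0-based half-open; GTF I/O converts to the
1-based closed convention, and SJ-tab junction files give the first and
last intronic base (1-based). An intron is a genomic interval `[lo, hi)`;
the donor is the `lo` end on `+` and the `hi` end on `-`.

Events are detected from junction evidence plus an exon annotation:

* **A3'SS / A5'SS** — two junctions sharing a donor (acceptor) with no
  other junction end strictly between the two acceptors (donors). That
  "no end inside" rule is what separates a genuine alternative splice
  site from the acceptor pair formed by an exon-skipping triple; it is a
  deliberate junction-only approximation of exon-structure-aware
  detection. The *inclusion* form is the shorter-intron junction (the
  "long exon" form, matching rMATS orientation).
* **SE** — a skipping junction `(D, A)` together with two inclusion
  junctions `(D, a)` and `(b, A)` bounding a plausible exon `[a, b)` (no
  junction end strictly inside). Inclusion = exon included.
* **MXE** — two disjoint plausible exon paths between shared flanks, no
  direct flank junction, and no junction joining the two exons (never
  co-included). Inclusion = the 5'-proximal exon along transcription.
* **RI** — an annotated intron whose spliced junction is observed
  together with boundary-spanning evidence. Because the package works
  from junction tables rather than alignments, retention evidence is
  represented as 2-nt pseudo-junction records straddling each intron
  boundary (any record of 20 nt or less is treated as such evidence,
  never as an intron). Inclusion = retained.

Event identifiers are `class:contig:strand:` plus the sorted defining
coordinates, so ids are deterministic, independent of input row order,
and comparable across runs over the same genome. Cross-condition overlap
analysis keys on these coordinates rather than gene symbols, which keeps
matching robust to annotation naming.

Any observed junction end absent from the annotation is accepted as a
candidate novel splice site, without a distance cap; an event is `novel`
when at least one defining junction is not an annotation-derived
exon-exon join (for RI, when no annotated exon spans the intron). The
original tooling's internal limits for novel splice sites are not
documented, so this catalogue is deliberately permissive and records the
divergence here.

## PSI and the differential test

With inclusion reads `I` over `L_inc` supporting junctions and skipping
reads `S` over `L_skip` (`L_inc`/`L_skip` count junctions: 2/1 for SE and
RI, 1/1 for A3'SS and A5'SS, 2/2 for MXE),

$$\psi = \frac{I / L_{inc}}{I / L_{inc} + S / L_{skip}},$$

undefined when `I + S = 0`. The per-event test is a binomial
likelihood-ratio test with one degree of freedom on the read-level
inclusion proportion: null, one shared proportion across replicates;
alternative, one per group. Pooling replicates by the binomial MLE makes
this the G-test of the pooled 2x2 table. It assumes within-group
replicate variation is binomial at fixed proportion — adequate for the
generator's data and calibrated there (the test suite checks type-I error
within [0.03, 0.07] at alpha 0.05 on a 2000-event null) — but it is *not*
the hierarchical replicate model of rMATS, and it will be anticonservative
on strongly overdispersed real replicates. This is a documented design
divergence chosen to keep the pipeline self-contained and auditable.

Untestable events (a group with no defined PSI, or all-zero counts) are
excluded from the Benjamini-Hochberg denominator. `delta PSI` is the
difference of group means over defined replicate PSIs (variant minus
wild type).

Threshold presets: the default transcriptome preset keeps events with
max-group mean PSI >= 0.1, |dPSI| >= 0.1, FDR < 0.05 and mean event
coverage >= 10; a strict variant raises |dPSI| to 0.25; the lymphocyte
preset uses |dPSI| >= 0.05, FDR < 0.1, coverage >= 10 and keeps one event
per gene and class (smallest FDR, ties by p then id). The "PSI >= 0.1"
filter is read as *max-group* mean PSI — the alternative transcript must
represent at least 10% of transcripts in some condition; this reading is
one of several possible and is recorded in the output metadata. All
comparisons use `>=` / `<` consistently, so records exactly at a cutoff
(e.g. |dPSI| = 0.09 under the 0.10 preset) are excluded, and stricter
delta presets always select subsets of looser ones.

## The cryptic 3' splice-site signature

The canonical acceptor of an A3'SS event is the annotation-supported one;
if both acceptors are annotated, the acceptor of the wild-type majority
isoform (group mean PSI of the proximal form >= 0.5); if neither, the
event is excluded from the signature and counted. The signed distance is

$$d = \text{alternative} - \text{canonical acceptor boundary}$$

measured along the transcription direction (genomic difference negated on
`-`), so `d < 0` means the cryptic AG' lies upstream of the canonical AG,
inside the intron, and `d > 0` downstream, inside the exon. Distances are
measured between the intron-terminal boundaries of the acceptors; both
AGs shift equally, so anchoring on the A would change nothing. `d = 0` is
degenerate and raises an error.

Summary statistics: 1-nt histograms of |d| and of signed d; the modal
|d| is the smallest value maximising the histogram after a 3-nt moving
average (a fixed smoother chosen to give a stable "peak" without a
bandwidth choice; `which.max` resolves ties toward the smaller distance);
`p_downstream` is the fraction of events with `d > 0`.

Motif matrices are 55-position nucleotide frequency matrices anchored on
the acceptor AG: positions -50..-1 are intronic, then the A and G, then
+1..+3 exonic. Whether "50 nt upstream of the AG" includes the AG itself
is ambiguous; here the AG occupies its own two anchor columns in addition
to the 50 upstream positions. Windows are extracted strand-aware
(reverse-complemented on `-`); acceptors too close to a contig edge are
skipped and counted. Every column sums to 1 (tolerance 1e-9 in tests).
Polypyrimidine-tract content is the C/T fraction over transcribed-strand
positions [-20, -5] (the usual tract location between branch point and
acceptor), per acceptor and set-averaged.

## The synthetic generator

The generator's defaults define the study conditions; they are not tuned
per run. Each gene occupies its own contig (100-nt pads), with 4 exons of
80–150 nt and introns of 150–400 nt (introns must be >= 120 nt so motif
windows never leave the intron). Strands alternate deterministically so
both orientations are always exercised. Sequence is uniform ACGT except:
every intron starts GT and ends AG on the transcribed strand, and the 50
intronic nt upstream of each canonical acceptor are drawn with a
configurable pyrimidine fraction (default 0.8, a typical polypyrimidine
tract enrichment). Cryptic acceptors are planted AG dinucleotides at a
signed offset from the canonical AG.

Offsets are drawn from a discretised two-sided geometric distribution
around `center` (`P(m) ∝ dispersion^|m - center|`), truncated to
magnitudes in [2, 40] — |d| = 1 is geometrically impossible because the
two AG boxes would overlap — and further truncated to fit the flanking
exon/intron; a fixed offset that cannot fit raises a configuration error
naming the gene. The sign is downstream with probability `p_downstream`.
The distribution family is a package choice: the source material for the
presets gives only a peak (7 nt, downstream-biased, for the NDD-like
preset) and a mean (17 nt, upstream-biased, for the cancer-like preset),
not a density; the geometric decay rate (default 0.7) is therefore a free
parameter documented here, chosen to give a clear mode with a modest
tail. The `null` preset sets the differential fraction to zero and is
used for calibration.

Counts: per event, replicate and condition, total coverage is negative
binomial (mean `mean_event_coverage`, size `coverage_size` = 20 —
overdispersion of totals only) and inclusion reads binomial with the
length-adjusted proportion `q = psi L_inc / (psi L_inc + (1-psi) L_skip)`,
which makes the PSI estimator unbiased for the planted PSI. Reads are
split uniformly among the junctions of a form; constitutive introns get
independent negative-binomial counts. Baseline usage of the alternative
isoform is uniform on [0.05, 0.2]; differential events move it by a
uniform [0.25, 0.35] effect in the variant group (3 vs 3 replicates,
coverage 100 by default — the replicate structure of the emulated
design). Ground-truth PSIs are recorded in the catalog's inclusion-form
convention so recovery can be compared directly.

What the generator does **not** emulate: read-level artefacts (no FASTQ,
no alignment, no mapping bias), exon-body reads (RI quantification from
alignments), overdispersion of the inclusion *proportion* across
replicates, linked events sharing a gene, expression-level variation
between conditions, and NMD feedback on transcript abundance. Passing
tests therefore demonstrate correctness of the event algebra, the
estimators and the statistics under the stated model — not robustness to
the full messiness of real RNA-seq.

## Phenotype clustering

Clinical features are encoded absent = 0, mild = 0.5, present = 1,
unknown = missing, and missing values are retained through clustering:
the patient distance is Euclidean over pairwise-complete features
rescaled by `sqrt(n_features / n_shared)` (the documented `stats::dist()`
behaviour with `NA`), followed by Ward (`ward.D2`) linkage. The exact
distance the original heatmap tooling uses with missing values retained
is not documented; the pairwise-complete choice is recorded here as a
divergence-in-the-open. A pair of patients sharing no observed feature
has no defined distance and raises an error advising feature filtering.
Patients are sorted by id before linkage so the partition cannot depend
on input row order. `k` defaults to 3 (the emulated analysis read three
groups off a dendrogram rather than using a selection criterion). The
sensitivity analysis removes features with more than 30% missing values
(strict inequality: 8/26 = 30.8% is removed) and *reports* the adjusted
Rand index between full and filtered partitions rather than asserting a
threshold, since "comparable" is a qualitative judgement.

## Exact statistics

The two-sided Mann-Whitney test enumerates all `choose(n + m, n)` group
assignments of the pooled sample (combined n <= 20), computes U from
mid-ranks, and reports the fraction of assignments with
`|U - E[U]| >= observed` (tolerance 1e-9 against floating-point rank
sums). Ties are handled by mid-ranks inside the enumeration — no normal
approximation — because the motivating proliferation assays have n = m =
4, where the smallest achievable two-sided p is exactly 2/70. The
two-proportion test is the Yates-continuity-corrected 2x2 chi-square via
`stats::prop.test`; BH adjustment via `stats::p.adjust`.

## Problem sizes and determinism

The packaged analyses run at desk scale by design: presets use 500 A3'SS
events (tests use 150–300), calibration uses 2000 simulated null events,
and toy catalogues use 5–16 genes — sizes at which every stage completes
in seconds to a couple of minutes on one CPU while keeping Monte-Carlo
error well inside the asserted tolerances. All randomness flows through
the configuration seed (restored afterwards), and identical
configurations produce byte-identical FASTA/GTF/SJ/TSV outputs; every
output directory carries a YAML run report with the resolved
configuration, its hash and the seed.

## Known limitations

* The binomial LRT understates uncertainty under replicate-level
  overdispersion; real-data p-values will be optimistic relative to
  hierarchical models.
* Junction-only RI evidence is a simulator convention; real retained
  introns need alignment-based quantification.
* The A3'SS/A5'SS "no junction end inside" rule can merge or split events
  in pathological junction configurations that the generator never
  produces.
* rMATS ingestion accepts the junction-count (`JC`) dialect of v4.1.2 and
  v4.3.0; other dialects are rejected with an explicit column error
  rather than guessed.
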