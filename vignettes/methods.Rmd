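---
title: "Characterizing unknown transgene insertions from enrichment-anchored long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing unknown transgene insertions from enrichment-anchored long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alfpipe)
```

## The problem

A genetically modified (GM) plant event is only fully characterized when
the junction between the inserted construct and the host genome is known
at base resolution. For unauthorized events found on the market — such
as the GM petunias discovered in Europe in 2017 — no reference sequence
exists, so the junction must be recovered *de novo*. A practical route
is gene-walking enrichment (ALF: amplification of linearly-enriched
fragments): fragments are anchored at a primer inside a known GM element
and extend into unknown flanking sequence, then are sequenced on a
long-read (nanopore-type) platform. Most of the resulting reads are
useless — off-target genomic fragments, reads lying wholly inside known
elements, or reads from already-characterized events — and the analysis
problem is to filter, cluster and polish the few reads that cross the
junction, and to turn the recovered junction into an event-specific
real-time PCR assay with validated performance.

`alfpipe` implements this workflow end to end on synthetic data with
known ground truth:

1. **Simulation** (`make_host_genome()`, `build_construct()`,
   `create_event()`, `simulate_alf_reads()`) — hosts, constructs,
   insertion events and ALF-enriched read sets.
2. **Read cascade** (`run_pipeline()`) — QC → primer selection →
   known-event subtraction → element-coverage subtraction → clustering →
   consensus → annotation → junction calling.
3. **In-silico PCR** (`predict_amplicons()`, `specificity_matrix()`) —
   verification of event-specific assays.
4. **qPCR validation arithmetic** (`copies_from_mass()`,
   `fit_calibration()`, `lod_from_table()`, `validate_assay()`).
5. **Decision support** (`classify_panel()`) — assignment of screening
   PCR panels to GM groups.

## What the simulator emulates — and what it does not

`simulate_alf_reads()` models the *composition* of an enrichment run:
on-target molecules that start at the anchor primer site and extend in
the enrichment direction, plus off-target reads drawn from random host
positions, from single GM elements, and optionally from a second,
already-characterized background event. The defaults are chosen to be
realistic for nanopore-style chemistry:

* **Read lengths** are log-normal (`meanlog = 7.0`, `sdlog = 0.45`,
  median ≈ 1.1 kb) truncated to [200, 8000] nt. No length distribution
  is published for the original runs; the log-normal family is standard
  nanopore practice.
* **Errors** are per-base substitutions/insertions/deletions at
  (0.03, 0.02, 0.03) — 8% total, matching older R9-class flow cells on
  which this type of experiment was run.
* **On-target fraction** defaults to 0.3. The real runs report
  per-stage counts spanning roughly 1–40% primer-selected reads across
  libraries; 30% of 1,000 reads puts the simulated cascade in the same
  regime at desk scale (real flow cells produced 40,000–54,000 reads —
  we scale down by ~40× to keep the full 20-seed recovery suite in
  minutes on one CPU).
* **Quality scores** are a constant per-read placeholder (Q12); the
  cascade's QC consumes only mean quality, so base-resolved quality
  modeling would add nothing the pipeline reads.

Not modeled: signal-level artifacts, chimeras, adapters, ploidy. Passing
tests therefore demonstrate that the *selection logic and coordinate
arithmetic* recover planted truths at realistic error rates; they do not
demonstrate robustness to chimeric reads or basecaller-specific error
motifs, which real data would add.

All randomness flows from one explicit seed per call; the RNG state is
saved and restored, so calls are reproducible and order-independent.

## The alignment core

Every matching step (coverage, clustering, consensus, annotation) runs
on one primitive: affine-gap local alignment (match 2, mismatch −3, gap
open −5, gap extend −2; a gap of length L costs `open + L·extend`).
Small problems are solved by full dynamic programming; long pairs are
seeded with exact 11-mers, grouped into diagonal bands (clusters with a
single seed are treated as noise on long inputs), and aligned by banded
DP with a 60 nt margin. Defaults `min_identity = 0.75`,
`min_length = 50` are chosen for ~10% long-read error; all thresholds
are exposed. Tie-breaks are fixed (smallest end coordinates, fixed
traceback order), so results are deterministic. Correctness is anchored
to an independent brute-force DP oracle on exhaustive small cases and
cross-checked against `Biostrings::pairwiseAlignment()` on planted
homologies.

The primitive deliberately has no E-values or seed chaining; it replaces
an interactive external similarity search, and correctness is defined by
the DP oracle, not by throughput on genome-scale databases.

## The read cascade and its defaults

* **QC**: length in [200, 8000], mean quality ≥ 7. The original
  analysis cites external QC software without parameters; these bounds
  mirror common long-read defaults.
* **Primer selection** keeps reads carrying the enrichment primer
  within a 150 nt window at the molecule start (or end, on the other
  strand, in which case the read is re-oriented so all kept reads run
  primer→unknown). Matching allows up to 2 *edits* — substitutions or
  indels. An earlier substitution-only design was rejected: at ~5%/base
  indel rates the probability that a 20 nt primer survives without an
  indel is only ~0.36, so Hamming matching silently discards most
  genuinely enriched reads; edit-distance matching keeps ≳ 70% at 8%
  total error while random sequence still essentially never matches
  (the package's general-purpose `match_with_mismatches()` primitive
  remains substitution-only for probe/primer site analysis, where the
  3'-exactness rule applies).
* **Known-event subtraction** removes a read when ≥ 80% of it is
  covered by known construct-and-flanking references at identity ≥
  0.75. The looser coverage (vs. element subtraction) reflects that a
  construct-plus-flank match explains a read's whole provenance.
* **Element subtraction** removes reads ≥ 95% covered by single known
  GM elements — the operational reading of "fully covered", left
  configurable because no number is published. Junction-spanning reads
  keep their genome-side tail uncovered and survive.
* **Clustering** is greedy and seed-based: the longest unassigned read
  seeds a cluster; reads join when they align to the seed at ≥ 0.75
  identity over ≥ 150 nt. Only clusters with **more than 5** members are
  retained — the published cluster counts are titled "> 5 reads per
  cluster" and we read that literally (a 5-read cluster is dropped).
* **Consensus** is a seed-anchored pileup: aligned columns vote by
  summed base quality; majority-gap columns are dropped (seed insertion
  errors) and majority-insertion columns are added (seed deletion
  errors). Ties break by summed quality, then by the fixed precedence
  A < C < G < T — the output is deterministic by construction.
* **Annotation** labels best-scoring non-overlapping intervals against
  the element database, optional vector references and the host genome;
  unmatched stretches ≥ 30 nt become `unknown`. Candidates overlapping
  an already-selected interval by ≤ 100 nt are trimmed rather than
  dropped: adjacent features' alignment boundaries jitter by a few
  nucleotides at long-read error rates, and without trimming a 500 nt
  marker segment can be discarded for a 5 nt overlap with the host
  match.
* **Junction calling** requires a construct/vector anchor and a host
  anchor, each ≥ 100 nt at ≥ 0.8 identity, adjacent up to an `unknown`
  spacer of ≤ 2,000 nt (sized to accommodate the observed ~150 nt
  plasmid + ~1,300 nt rearranged filler in the purple-flower group).
  Gaps < 50 nt count as direct transitions (`confidence = "high"`);
  anything larger is reported as a spacer with `confidence = "low"`.
  The host breakpoint is the host coordinate at the start of the
  host-side anchor, strand-aware.

Stage counts are conserved exactly (`input = kept + removed`, kept of
stage *i* feeds stage *i+1*) and the whole cascade is monotone
non-increasing — both are asserted, not assumed.

## In-silico PCR

Primer sites are substitution-only matches (budget 2) whose 3'-terminal
3 bases must match exactly — the polymerase-extension end dominates
specificity, and indel-tolerant matching at 17–18 nt primer lengths
produces spurious sites. Amplicons are reported for convergent pairs up
to 3,000 nt; a hydrolysis probe must match inside the amplicon (either
strand, budget 2) for a template to count as *detected*. The bundled G1
and G2 assays are the published oligo sequences; because the full
junction templates are only available as figures, the package builds
synthetic demonstration events (`demo_g1_event()`, `demo_g2_event()`)
whose junction neighbourhoods embed each assay's amplicon at its
declared length (93 bp and 100 bp), with the genome-side half planted in
the wild-type host. The assays therefore detect exactly their own event
fixture and neither the other group's event nor wild-type hosts —
mirroring the mutually exclusive behaviour of the real assays on market
samples.

## qPCR validation arithmetic

Copy numbers derive from first principles:
`copies = round(mass_ng × 1000 / 1C_pg)` with the petunia 1C of
1.43 pg. The published copy series for the dilution ladder is internally
inconsistent with that 1C (150 ng gives 104,895 copies, not 105,634);
both series are stored (`petunia_calibration_series()`) and computations
use the recomputed one — only the 20-copy point, which the two series
share, is treated as a fixed reference.

Calibration fits are least squares of mean Cq on log10(copies), with R²
on replicate means (samples are run in duplicate; per-replicate R² is
available by option). Efficiency is `(10^(−1/slope) − 1) × 100`. The
replicate simulator delivers Poisson-distributed template counts (zero
templates → no detection), then
`Cq = intercept − log(n)/log(1 + efficiency) + N(0, sd)`, censored at 45
cycles; detection probability at c copies therefore converges to
`1 − e^(−c)`, which the tests check with binomial error bars. The LOD
rule is: the lowest copy level positive in *all* replicates, provided
every higher level is also all-positive; a non-monotone table yields the
conservative answer plus a warning flag. Default acceptance windows —
efficiency 90–110%, R² ≥ 0.98 — follow standard GMO-method verification
guidance and are configurable, since the underlying guidance document's
numbers are not restated in the source material.

## Decision support

The classifier maps a tri-state panel (positive / negative / not-tested
per target) to one of {G1, G2, non-GM, legacy-dfr-event, GM-unassigned,
invalid}. The rule order is: failed actin control → `invalid`; positive
G1 or G2 event assay → that group; all *tested* GM targets negative →
`non-GM`; P-35S positive without T-nos and without the G1 junction →
`legacy-dfr-event` (the research-line RL01 pattern — note that T-ocs can
read negative in RL01-17 because the element is truncated there);
anything else → `GM-unassigned`. Two reconstruction choices are worth
flagging: the published decision-tree figure is not machine-readable, so
the order above is reconstructed from the screening-table patterns; and
the legacy rule treats "not tested" like "not positive" (the reference
RL01 rows record T-nos as n.d., not negative). The rules live in
`inst/extdata/dss_rules.json` with their literature keys and can be
amended without code changes. "Not tested" is never coerced to
"negative", and adding not-tested targets never changes a label — both
are property-tested.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; reports (JSON/TSV) use
  1-based inclusive coordinates and say so in a header field.
* Empty alignments score 0 rather than erroring; empty read sets flow
  through the cascade and produce empty reports.
* The seeded aligner is a heuristic on long pairs: matches shorter than
  ~50 nt at the identity floor can lack the two 11-mer seeds required
  for a banded candidate. Such marginal matches are below the
  annotation/coverage thresholds in every cascade role; exactness is
  guaranteed (and tested) in the full-DP regime.
* All stochastic tests fix their seeds; tolerance bands use 3·SE for
  binomial checks and stated absolute bands elsewhere.

## Problem sizes

The bundled suites run, per scenario, 1,000 simulated reads against a
20 kb host segment with ~3.5 kb constructs; the parameter-recovery suite
repeats this over 20 seeds and requires the called host breakpoint to be
within ±5 nt of truth in ≥ 95% of runs. These sizes were chosen so the
entire recovery suite completes in a few minutes on a single CPU while
leaving every stage of the cascade non-trivially exercised (hundreds of
reads survive primer selection; dozens of element-only and background
reads are subtracted).

## Known limitations

* One junction per cluster/consensus; no joint multi-sample calling and
  no assembly of the full insert from overlapping enrichment reactions.
* The consensus is a pileup against a single seed read, not a partial
  order alignment; at error rates well above ~10% the seed choice can
  limit polish quality before depth does.
* In-silico PCR has no thermodynamic model (no Tm, no secondary
  structure): a predicted amplicon is a sequence-level statement only.
* The DSS is rule-based by design; it reports a rationale and
  literature keys, not posterior probabilities.
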