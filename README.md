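# alfpipe

Characterization of unknown transgene insertion events from
enrichment-anchored long reads, with in-silico verification and
validation arithmetic for the resulting event-specific real-time PCR
assays, and a rule-based decision support system for GM screening
panels.

## The problem

A genetically modified (GM) plant event is only identifiable when the
junction between the inserted construct and the host genome is known.
For unauthorized events found on the market — the GM petunia case is
the motivating example — no reference exists: screening PCRs
(P-35S, T-nos, nptII, …) can flag a plant as GM, but recovering the
junction requires gene-walking enrichment (ALF: amplification of
linearly-enriched fragments) combined with long-read sequencing, and
then a selection cascade that discards the overwhelming majority of
reads which carry no new information.

`alfpipe` implements that workflow on synthetic data with known ground
truth:

* **Simulation** — synthetic host genomes, element databases
  (`gm_element_db()`), multi-part constructs (`build_construct()`,
  `construct_g1()`, `construct_g2()`), insertion events with optional
  site deletions and rearranged fillers (`create_event()`), and
  ALF-enriched nanopore-style read sets with hidden truth labels
  (`simulate_alf_reads()`).
* **Read cascade** (`run_pipeline()`) — quality control → enrichment
  primer selection → subtraction of reads matching known events (CaF:
  construct and flanking) → subtraction of reads fully covered by known
  GM elements → greedy clustering (clusters of **more than 5 reads**
  are kept) → per-cluster consensus → annotation against
  elements/vector/host → junction calling with breakpoint coordinates
  and a high/low confidence label.
* **In-silico PCR** — primer-site finding with a 3'-exactness rule,
  amplicon prediction, probe containment, and cross-event specificity
  matrices (`predict_amplicons()`, `specificity_matrix()`); the
  published G1/G2 event-specific assays ship as a TSV fixture
  (`petunia_assays()`).
* **qPCR validation** — genome copies from DNA mass
  (`copies_from_mass()`, 1C = 1.43 pg), calibration-curve fitting with
  efficiency `E = (10^(-1/slope) - 1) × 100` and R²
  (`fit_calibration()`), a Poisson-delivery replicate simulator
  (`simulate_qpcr_replicates()`), and the all-replicates-positive LOD
  rule (`lod_from_table()`, `validate_assay()`).
* **Decision support** — a tri-state screening-panel classifier
  (`classify_panel()`) with rules in an editable JSON file, the full
  interlaboratory screening table as a fixture
  (`petunia_panel_table()`), and rationale rendering (`explain()`).

The alignment core (affine-gap local alignment with k-mer seeded
banding, written in C++ via Rcpp) is exposed as `local_align()`,
`find_all_local_matches()`, `coverage_fraction()` and
`match_with_mismatches()`.

## Worked example

Simulate a G1-like event (dfr cassette, direct construct–genome
transition at host coordinate 12,000), enrich upstream from a P-35S
anchor primer, and run the cascade:

```r
library(alfpipe)
db     <- gm_element_db()
host   <- make_host_genome(48, 20000, gc = 0.37)
event  <- create_event(host, construct_g1(db), insertion_pos = 12000, seed = 3)
anchor <- substr(db[["P-35S"]]$sequence, 101, 120)
reads  <- simulate_alf_reads(event, anchor, "up", n_reads = 1000,
                             on_target_frac = 0.3, seed = 3)
report <- run_pipeline(reads, pipeline_config(anchor, "up", event$host_genome))
report
#> <pipeline_report>
#>                    stage input kept removed
#>                       qc  1000  997       3
#>            primer_select   997  235     762
#>  known_event_subtraction   235  235       0
#>      element_subtraction   235  208      27
#> 1 retained cluster(s), 1 junction call(s)
report$junctions[[1]]
#> <junction_call> bla|host host breakpoint 12000 (consensus 620), spacer 0 nt, confidence high
```

Reading the output: of 1,000 simulated reads, 997 pass QC, 235 carry
the enrichment primer, none match a known event (none were supplied),
and 27 element-only reads are subtracted. The survivors form one
cluster (> 5 reads); its consensus is annotated as partial *bla* marker
followed by host genome, and the called host breakpoint, 12000, equals
the planted insertion coordinate exactly, with a direct (high
confidence) transition.

The bundled event-specific assays detect exactly their own synthetic
event fixture — neither the other group's event nor wild-type host:

```r
specificity_matrix(list(petunia_assays()$PxhG1, petunia_assays()$PxhG2),
                   demo_templates())
#>       G1_event G2_event G1_host G2_host
#> PxhG1     TRUE    FALSE   FALSE   FALSE
#> PxhG2    FALSE     TRUE   FALSE   FALSE
```

And a simulated duplicate dilution series (105,634 … 20 copies)
validates like a wet-lab assay:

```r
series <- petunia_calibration_series()
cq <- unlist(lapply(series$copies_recomputed, function(cp)
  simulate_qpcr_replicates(cp, amplification_efficiency = 0.97,
                           cq_intercept = 38, noise_sd = 0.12,
                           n_replicates = 2, seed = cp, poisson = FALSE)))
curve <- fit_calibration(data.frame(copies = rep(series$copies_recomputed, each = 2),
                                    cq = cq))
validate_assay(curve, detection_table(c(20, 10, 5, 1), c(10, 10, 9, 4)))
#> <validation_report> PASS
#>   efficiency 95.7% in [90, 110]: pass
#>   R2 1.0000 >= 0.98: pass
#>   LOD: 10 copies
```

A command-line surface (`alf_main()`, launcher in
`inst/scripts/alfpipe`) wraps the same functions as `simulate`,
`pipeline`, `pcr`, `validate`, `classify` and `demo` subcommands.

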