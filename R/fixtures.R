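# Synthetic demonstration events for the two GM petunia groups.  The
# junction neighbourhoods are constructed so that the bundled
# event-specific assays amplify across them with their declared amplicon
# lengths; everything else (host, elements, fillers) is the synthetic
# stand-in world.  The wild-type host carries only the genome-side half
# of each amplicon, so assays are negative on it.

# Assemble an assay's amplicon with seeded random spacers so that
# F + spacer1 + probe + spacer2 + revcomp(R) has the declared length.
.assay_amplicon <- function(ps, seed, spacer1_len = 5L) {
  total <- ps$declared_length
  core <- nchar(ps$forward) + spacer1_len + nchar(ps$probe) +
    nchar(ps$reverse)
  spacer2_len <- total - core
  stopifnot(spacer2_len >= 0)
  .with_seed(seed, paste0(ps$forward, .random_seq(spacer1_len, 0.45),
                          ps$probe, .random_seq(spacer2_len, 0.45),
                          revcomp(ps$reverse)))
}

.replace_substr <- function(x, start0, replacement) {
  # overwrite x[start0, start0 + nchar(replacement)) (0-based)
  paste0(substr(x, 1, start0),
         replacement,
         substr(x, start0 + nchar(replacement) + 1L, nchar(x)))
}

#' Synthetic G1-like demonstration event
#'
#' A dfr-cassette insertion with a direct construct-genome transition at
#' the 5' (left) junction. The G1 event-specific amplicon spans the
#' junction: its genome-side half (forward primer and probe) lies in the
#' host flank and its construct-side half starts the insert, so the
#' bundled G1 assay detects the event but not the wild-type host. ALF
#' enrichment for this event anchors in P-35S and runs upstream across
#' bla into the genome.
#'
#' @param seed integer seed
#' @param host_len host segment length (nt)
#' @param insertion_pos 0-based insertion coordinate
#' @return list: `event` (a `synthetic_event`), `assay` (the G1
#'   [primer_set()]), `anchor_primer`, `direction`, `wt_host` (the
#'   insertion-free host template)
#' @export
demo_g1_event <- function(seed = 2001L, host_len = 20000L,
                          insertion_pos = 12000L) {
  db <- gm_element_db()
  assay <- petunia_assays()$PxhG1
  amp <- .assay_amplicon(assay, seed + 7L)
  host_half_len <- nchar(assay$forward) + 5L + nchar(assay$probe) # F+s1+P
  host_half <- substr(amp, 1, host_half_len)
  border <- substr(amp, host_half_len + 1L, nchar(amp))

  host <- make_host_genome(seed, host_len, gc = 0.37)
  host <- .replace_substr(host, insertion_pos - nchar(host_half), host_half)

  construct <- build_construct(c(
    list(list(element = element_def("G1-border", border, "unknown-filler"))),
    list(list(element = "bla", interval = c(361L, 861L)),
         list(element = "P-35S"),
         list(element = "dfr"),
         list(element = "T-ocs"),
         list(element = "P-nos"),
         list(element = "nptII"),
         list(element = "T-35S"))), db = db)
  event <- create_event(host, construct, insertion_pos, seed = seed)
  anchor <- substr(db[["P-35S"]]$sequence, 101, 120)
  list(event = event, assay = assay, anchor_primer = anchor,
       direction = "up", wt_host = host)
}

#' Synthetic G2-like demonstration event
#'
#' An F3'5'H-cassette insertion whose 3' junction region carries a filler
#' of ~150 nt generic vector sequence plus unidentified rearranged
#' sequence between the final T-nos and the genome, as seen in the
#' purple-flowering group. The G2 event-specific amplicon spans the
#' filler-genome boundary (probe half in the filler, reverse-primer half
#' in the host flank). ALF enrichment anchors in the terminal T-nos and
#' runs downstream across the filler into the genome.
#'
#' @param seed integer seed
#' @param host_len host segment length (nt)
#' @param insertion_pos 0-based insertion coordinate
#' @param filler_random_len length of the unidentified (random) filler
#'   part between the vector stretch and the amplicon half
#' @return list as in [demo_g1_event()]
#' @export
demo_g2_event <- function(seed = 2002L, host_len = 20000L,
                          insertion_pos = 8000L,
                          filler_random_len = 550L) {
  db <- gm_element_db()
  assay <- petunia_assays()$PxhG2
  amp <- .assay_amplicon(assay, seed + 7L)
  construct_half_len <- nchar(assay$forward) + 5L + nchar(assay$probe)
  construct_half <- substr(amp, 1, construct_half_len)
  host_half <- substr(amp, construct_half_len + 1L, nchar(amp))

  host <- make_host_genome(seed, host_len, gc = 0.37)
  host <- .replace_substr(host, insertion_pos, host_half)

  vec_stretch <- substr(db[["vector"]]$sequence, 501, 650) # ~150 nt plasmid
  filler <- paste0(vec_stretch,
                   .with_seed(seed + 13L,
                              .random_seq(filler_random_len, 0.40)),
                   construct_half)
  construct <- construct_g2(db)
  event <- create_event(host, construct, insertion_pos,
                        right_filler = filler, seed = seed)
  anchor <- substr(db[["T-nos"]]$sequence, 41, 60)
  list(event = event, assay = assay, anchor_primer = anchor,
       direction = "down", wt_host = host)
}

#' Specificity templates for the bundled assays
#'
#' The two demonstration events plus their wild-type hosts, named for use
#' with [specificity_matrix()].
#'
#' @param g1,g2 outputs of [demo_g1_event()] / [demo_g2_event()]
#' @return named character vector of templates
#' @export
demo_templates <- function(g1 = demo_g1_event(), g2 = demo_g2_event()) {
  c(G1_event = g1$event$event_sequence,
    G2_event = g2$event$event_sequence,
    G1_host = g1$wt_host,
    G2_host = g2$wt_host)
}
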