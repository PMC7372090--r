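# Shared simulation scenarios: a G1-like event (direct construct-genome
# transition, enrichment anchored in P-35S running upstream across bla
# into the genome) and a G2-like event (700 nt rearranged filler between
# the terminal T-nos and the genome, enrichment running downstream).

g1_scenario <- function(seed, host_len = 20000L, insertion_pos = 12000L,
                        n_reads = 1000L, on_target_frac = 0.3) {
  db <- gm_element_db()
  host <- make_host_genome(seed * 37L + 11L, host_len, 0.37)
  event <- create_event(host, construct_g1(db), insertion_pos, seed = seed)
  anchor <- substr(db[["P-35S"]]$sequence, 101, 120)
  reads <- simulate_alf_reads(event, anchor, "up", n_reads = n_reads,
                              on_target_frac = on_target_frac, seed = seed)
  list(event = event, anchor = anchor, direction = "up", reads = reads,
       config = pipeline_config(anchor, "up", event$host_genome,
                                element_db = db))
}

g2_scenario <- function(seed, host_len = 20000L, insertion_pos = 8000L,
                        filler_len = 700L, n_reads = 1000L,
                        on_target_frac = 0.3) {
  db <- gm_element_db()
  host <- make_host_genome(seed * 41L + 13L, host_len, 0.37)
  event <- create_event(host, construct_g2(db), insertion_pos,
                        right_filler = filler_len, seed = seed)
  anchor <- substr(db[["T-nos"]]$sequence, 41, 60)
  reads <- simulate_alf_reads(event, anchor, "down", n_reads = n_reads,
                              on_target_frac = on_target_frac, seed = seed)
  list(event = event, anchor = anchor, direction = "down", reads = reads,
       config = pipeline_config(anchor, "down", event$host_genome,
                                element_db = db))
}

# read_set from explicit sequences with constant quality
toy_read_set <- function(seqs, quality = 12L, origin = "host_random") {
  qual <- vapply(nchar(seqs),
                 function(n) strrep(intToUtf8(33L + quality), n), "")
  read_set(data.frame(
    read_id = sprintf("toy_%03d", seq_along(seqs)),
    sequence = seqs, quality = qual,
    truth_origin = rep_len(origin, length(seqs)),
    truth_start = 0L, stringsAsFactors = FALSE))
}
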