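test_that("host genome generation is seeded, GC-controlled and validated", {
  h1 <- make_host_genome(1, 10000, 0.5)
  h2 <- make_host_genome(1, 10000, 0.5)
  expect_identical(h1, h2)
  expect_false(identical(make_host_genome(2, 10000, 0.5), h1))

  h <- make_host_genome(1, 50000, 0.37)
  gc <- sum(strsplit(h, "")[[1]] %in% c("G", "C")) / nchar(h)
  expect_gte(gc, 0.35)
  expect_lte(gc, 0.39)

  expect_error(make_host_genome(1, 500), ">= 1000")
  expect_error(make_host_genome(1, -5), ">= 1000")
})

test_that("element database is deterministic with valid, unique elements", {
  db1 <- gm_element_db()
  db2 <- gm_element_db()
  expect_identical(db1, db2)
  expect_false(anyDuplicated(names(db1)) > 0)
  for (e in db1) {
    expect_gt(nchar(e$sequence), 0)
    expect_false(grepl("[^ACGT]", e$sequence))
  }
  expect_error(element_def("bad", "ACGU", "coding"), "outside ACGT")
})

test_that("construct assembly handles orientation, truncation and tiling", {
  db <- gm_element_db()
  one <- build_construct(list(list(element = "T-nos")), db = db)
  expect_identical(one$full_sequence, db[["T-nos"]]$sequence)

  neg <- build_construct(list(list(element = "T-nos", orientation = "-")),
                         db = db)
  expect_identical(neg$full_sequence, revcomp(db[["T-nos"]]$sequence))

  g2 <- construct_g2(db)
  lens <- g2$parts$end - g2$parts$start
  kept <- g2$parts$elt_end - g2$parts$elt_start
  expect_identical(lens, kept)
  expect_identical(g2$parts$start, c(0L, cumsum(lens)[-length(lens)]))
  expect_identical(g2$parts$end[nrow(g2$parts)],
                   nchar(g2$full_sequence))

  expect_error(build_construct(list()), "at least one part")
  expect_error(
    build_construct(list(list(element = "T-nos", interval = c(0, 9999))),
                    db = db),
    "outside element bounds")
})

test_that("event assembly conserves length and places junctions", {
  db <- gm_element_db()
  host <- make_host_genome(5, 5000, 0.4)
  con <- construct_g1(db)

  ev <- create_event(host, con, 2500)
  expect_identical(nchar(ev$event_sequence),
                   nchar(host) + nchar(con$full_sequence))

  ev2 <- create_event(host, con, 2500, site_deletion_len = 10)
  expect_identical(nchar(ev2$event_sequence),
                   nchar(host) + nchar(con$full_sequence) - 10L)

  ev3 <- create_event(host, con, 2500, left_filler = 700L, seed = 9)
  tj <- ev3$truth_junctions
  expect_identical(tj$left$construct_start_on_event -
                     tj$left$host_end_on_event, 700L)
  # reassembly invariant
  expect_identical(
    ev3$event_sequence,
    paste0(substr(host, 1, 2500), ev3$left_filler,
           con$full_sequence, ev3$right_filler,
           substr(host, 2501, nchar(host))))

  expect_error(create_event(host, con, 6000), "out of range")
})

test_that("error-free on-target reads are exact event substrings with true starts", {
  sc <- g1_scenario(3, n_reads = 60, on_target_frac = 0.5)
  rs <- simulate_alf_reads(sc$event, sc$anchor, "up", n_reads = 60,
                           on_target_frac = 0.5,
                           error_rates = c(0, 0, 0), seed = 11)
  ev <- sc$event$event_sequence
  on <- rs$reads[rs$reads$truth_origin == "on_target", ]
  expect_gt(nrow(on), 5)
  for (i in seq_len(nrow(on))) {
    s <- on$sequence[i]
    fwd <- regexpr(s, ev, fixed = TRUE)
    rev <- regexpr(revcomp(s), ev, fixed = TRUE)
    hit <- max(fwd, rev)
    expect_gt(hit, 0)
    # leftmost exact-match coordinate equals the recorded truth start
    expect_identical(as.integer(hit) - 1L, on$truth_start[i])
  }
})

test_that("on-target read count is binomial around the requested fraction", {
  rs <- simulate_alf_reads(g1_scenario(1, n_reads = 10)$event,
                           substr(gm_element_db()[["P-35S"]]$sequence, 101, 120),
                           "up", n_reads = 1000, on_target_frac = 0.3,
                           seed = 21)
  n_on <- sum(rs$reads$truth_origin == "on_target")
  sd3 <- 3 * sqrt(1000 * 0.3 * 0.7)
  expect_lt(abs(n_on - 300), sd3)
})

test_that("simulation is byte-identical for a fixed seed", {
  sc <- g1_scenario(2, n_reads = 50)
  r1 <- simulate_alf_reads(sc$event, sc$anchor, "up", n_reads = 50, seed = 7)
  r2 <- simulate_alf_reads(sc$event, sc$anchor, "up", n_reads = 50, seed = 7)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(r1, f1); write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  r3 <- simulate_alf_reads(sc$event, sc$anchor, "up", n_reads = 50, seed = 8)
  expect_false(identical(r1$reads$sequence, r3$reads$sequence))
})

test_that("a missing anchor primer is rejected naming the primer", {
  sc <- g1_scenario(2, n_reads = 10)
  expect_error(
    simulate_alf_reads(sc$event, "ACACACACACACACACACAC", "down",
                       n_reads = 10, seed = 1),
    "ACACACACACACACACACAC")
})

test_that("realized error fraction tracks the configured rate", {
  sc <- g1_scenario(4, n_reads = 10)
  rates <- c(0.03, 0.02, 0.03) # 8% total
  rs <- simulate_alf_reads(sc$event, sc$anchor, "up", n_reads = 600,
                           on_target_frac = 1, error_rates = rates,
                           length_dist = c(meanlog = 6.0, sdlog = 0.3),
                           seed = 13)
  ev <- sc$event$event_sequence
  errs <- vapply(seq_len(rs$counts), function(i) {
    r <- rs$reads[i, ]
    # reconstruct the clean source molecule from the truth fields
    L0 <- r$truth_start
    src <- substr(ev, L0 + 1, nchar(ev)) # up-reads end at the anchor end
    src <- substr(src, 1, nchar(r$sequence) + 200)
    d1 <- utils::adist(r$sequence, substr(src, 1, nchar(r$sequence) + 50),
                       partial = TRUE)[1, 1]
    d2 <- utils::adist(revcomp(r$sequence),
                       substr(src, 1, nchar(r$sequence) + 50),
                       partial = TRUE)[1, 1]
    min(d1, d2) / nchar(r$sequence)
  }, 0)
  mean_rate <- mean(errs)
  expect_gt(mean_rate, 0.08 * 0.8)
  expect_lt(mean_rate, 0.08 * 1.2)
})

test_that("reverse complement is an involution on generated sequences", {
  db <- gm_element_db()
  for (e in db) expect_identical(revcomp(revcomp(e$sequence)), e$sequence)
  h <- make_host_genome(3, 2000 + 8000, 0.4)
  expect_identical(revcomp(revcomp(h)), h)
})
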