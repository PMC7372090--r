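test_that("qc filter enforces bounds with conserved counts", {
  set.seed(201)
  ok <- replicate(87, rand_seq(sample(300:3000, 1)))
  bad_short <- replicate(6, rand_seq(199))
  bad_long <- replicate(4, rand_seq(8501))
  bad_q <- replicate(3, rand_seq(500))
  rs <- toy_read_set(c(ok, bad_short, bad_long))
  low <- toy_read_set(bad_q, quality = 5L)
  rs$reads <- rbind(rs$reads, low$reads)
  rs <- read_set(rs$reads)

  out <- qc_filter(rs, min_len = 200, max_len = 8000, min_mean_quality = 7)
  expect_identical(out$report$input, 100L)
  expect_identical(out$report$removed, 13L)
  expect_identical(out$report$input, out$report$kept + out$report$removed)

  boundary <- toy_read_set(c(rand_seq(200), rand_seq(199)))
  out2 <- qc_filter(boundary)
  expect_identical(out2$report$removed, 1L)
})

test_that("primer selection keeps enriched reads and re-orients them", {
  sc <- g1_scenario(5, n_reads = 200, on_target_frac = 0.5)
  clean <- simulate_alf_reads(sc$event, sc$anchor, "up", n_reads = 150,
                              on_target_frac = 1,
                              error_rates = c(0, 0, 0), seed = 31)
  out <- primer_select(clean, sc$anchor, "up")
  expect_identical(out$report$kept, 150L)
  # all kept reads begin with the effective primer (revcomp for "up")
  ep <- revcomp(sc$anchor)
  expect_true(all(substr(out$reads$reads$sequence, 1, nchar(ep)) == ep))

  # host-only reads share no primer site
  host_only <- simulate_alf_reads(sc$event, sc$anchor, "up", n_reads = 150,
                                  on_target_frac = 0,
                                  error_rates = c(0, 0, 0), seed = 32)
  host_only <- read_set(
    host_only$reads[host_only$reads$truth_origin == "host_random", ])
  out2 <- primer_select(host_only, sc$anchor, "up")
  expect_identical(out2$report$kept, 0L)

  # at nanopore-like error the kept fraction is high but imperfect
  noisy <- simulate_alf_reads(sc$event, sc$anchor, "up", n_reads = 300,
                              on_target_frac = 1, seed = 33)
  out3 <- primer_select(noisy, sc$anchor, "up", max_mismatches = 2)
  frac <- out3$report$kept / out3$report$input
  expect_gt(frac, 0.6)
  expect_lt(frac, 1)
})

test_that("known-event subtraction removes explained reads and spares novel ones", {
  db <- gm_element_db()
  known <- g2_scenario(6, n_reads = 120, on_target_frac = 1)
  rs <- known$reads
  out <- subtract_known_event(rs, known$event$event_sequence)
  expect_gte(out$report$removed / out$report$input, 0.95)

  # novel-event reads sharing only the construct survive when their
  # genome-side share exceeds 1 - threshold
  set.seed(202)
  con <- construct_g2(db)$full_sequence
  novel_host <- make_host_genome(777, 20000, 0.37)
  junction_reads <- vapply(1:30, function(i) {
    paste0(substr(con, nchar(con) - 399, nchar(con)),
           substr(novel_host, 5000, 5000 + 800))
  }, "")
  rs2 <- toy_read_set(junction_reads)
  out2 <- subtract_known_event(rs2, known$event$event_sequence)
  expect_identical(out2$report$removed, 0L)

  out3 <- subtract_known_event(rs, character(0))
  expect_identical(out3$report$kept, out3$report$input)
})

test_that("element subtraction removes element-contained reads only", {
  db <- gm_element_db()
  p35s <- db[["P-35S"]]$sequence
  inside <- toy_read_set(substr(p35s, 51, 300))
  out <- subtract_element_covered(inside, db)
  expect_identical(out$report$removed, 1L)

  set.seed(203)
  host <- make_host_genome(888, 20000, 0.37)
  spanning <- toy_read_set(
    paste0(substr(p35s, 101, 300), substr(host, 1001, 1300))) # 40% element
  out2 <- subtract_element_covered(spanning, db)
  expect_identical(out2$report$removed, 0L)

  # element-only reads at ~10% error are still removed
  sc <- g1_scenario(7, n_reads = 10)
  elem_rs <- simulate_alf_reads(sc$event, sc$anchor, "up", n_reads = 160,
                                on_target_frac = 0,
                                error_rates = c(0.04, 0.03, 0.03),
                                length_dist = c(meanlog = 6.0, sdlog = 0.3),
                                seed = 34)
  elem_rs <- read_set(
    elem_rs$reads[elem_rs$reads$truth_origin == "element_only", ])
  out3 <- subtract_element_covered(elem_rs, db, min_identity = 0.75,
                                   coverage_threshold = 0.95)
  expect_gte(out3$report$removed / out3$report$input, 0.9)
})

test_that("clustering groups reads by locus with the >5 retention rule", {
  set.seed(204)
  template <- rand_seq(2500)
  ident <- toy_read_set(rep(substr(template, 101, 1600), 10))
  cl <- cluster_reads(ident)
  expect_length(cl, 1)
  expect_identical(nrow(cl[[1]]$members), 10L)

  five <- toy_read_set(rep(substr(template, 101, 1600), 5))
  expect_length(cluster_reads(five), 0)
  expect_length(cluster_reads(five, min_cluster_size = 5), 1)

  # two loci at ~8% error: two retained clusters with pure membership
  mutate <- function(s) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(runif(length(ch)) < 0.08)
    ch[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
    paste(ch, collapse = "")
  }
  hostA <- rand_seq(2200); hostB <- rand_seq(2200)
  reads <- c(vapply(1:20, function(i) mutate(substr(hostA, 51, 1850)), ""),
             vapply(1:20, function(i) mutate(substr(hostB, 201, 2000)), ""))
  rs <- toy_read_set(reads)
  rs$reads$truth_origin <- rep(c("locusA", "locusB"), each = 20)
  rs <- read_set(rs$reads)
  cl2 <- cluster_reads(rs)
  expect_length(cl2, 2)
  for (x in cl2) {
    origins <- rs$reads$truth_origin[match(x$members$read_id,
                                           rs$reads$read_id)]
    expect_gte(max(table(origins)) / length(origins), 0.95)
  }
})

test_that("consensus reproduces the template and is deterministic on ties", {
  set.seed(205)
  template <- rand_seq(2000)
  ident <- toy_read_set(rep(template, 8))
  cl <- cluster_reads(ident)
  cs <- build_consensus(cl[[1]], ident)
  expect_identical(cs$sequence, template)
  expect_true(all(cs$depth <= 8))

  # 21 reads at 8% total error recover >= 99% identity where depth >= 10
  mutate <- function(s, sub = 0.03, ins = 0.02, del = 0.03) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    m <- runif(n) < sub
    ch[m] <- sample(c("A", "C", "G", "T"), sum(m), replace = TRUE)
    keep <- runif(n) >= del
    insm <- runif(n) < ins
    extra <- rep("", n)
    extra[insm] <- sample(c("A", "C", "G", "T"), sum(insm), replace = TRUE)
    ch[!keep] <- ""
    paste(paste0(ch, extra), collapse = "")
  }
  noisy <- toy_read_set(vapply(1:21, function(i) mutate(template), ""))
  cl2 <- cluster_reads(noisy)
  expect_length(cl2, 1)
  cs2 <- build_consensus(cl2[[1]], noisy)
  al <- local_align(cs2$sequence, template)
  expect_gte(al$identity, 0.99)

  # deterministic tie handling: identical runs give identical output
  cs2b <- build_consensus(cl2[[1]], noisy)
  expect_identical(cs2$sequence, cs2b$sequence)
})

test_that("annotation labels host, elements, vector spacers and unknowns", {
  db <- gm_element_db()
  host <- make_host_genome(999, 20000, 0.37)
  cons_host <- substr(host, 3001, 5000)
  ann <- annotate_consensus(cons_host, db, NULL, host)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$category, "host")

  # element + unknown spacer + host layout
  spacer <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                  collapse = "")
  cons2 <- paste0(db[["T-nos"]]$sequence, spacer, substr(host, 8001, 9000))
  ann2 <- annotate_consensus(cons2, db, NULL, host)
  expect_identical(ann2$category,
                   c("element", "unknown", "host"))
  expect_identical(ann2$label[1], "T-nos")
})

test_that("junction calling distinguishes direct and filler-spaced transitions", {
  g1 <- g1_scenario(8)
  rep1 <- run_pipeline(g1$reads, g1$config)
  expect_length(rep1$junctions, 1)
  j1 <- rep1$junctions[[1]]
  expect_identical(j1$confidence, "high")
  expect_lte(abs(j1$breakpoint_host - g1$event$insertion_pos), 5)

  g2 <- g2_scenario(9)
  rep2 <- run_pipeline(g2$reads, g2$config)
  expect_length(rep2$junctions, 1)
  j2 <- rep2$junctions[[1]]
  expect_identical(j2$confidence, "low")
  expect_lte(abs(j2$spacer_len - 700), 70)
  expect_lte(abs(j2$breakpoint_host -
                   g2$event$truth_junctions$right$host_coord), 5)

  # element-only consensus yields no call
  db <- gm_element_db()
  ann <- annotate_consensus(db[["dfr"]]$sequence, db, NULL,
                            make_host_genome(1234, 20000, 0.37))
  expect_null(call_junction(ann))
})

test_that("the cascade conserves counts and handles empty input", {
  g1 <- g1_scenario(10, n_reads = 300)
  rep <- run_pipeline(g1$reads, g1$config)
  fr <- rep$filter_reports
  expect_true(all(fr$input == fr$kept + fr$removed))
  expect_identical(fr$kept[-nrow(fr)], fr$input[-1])
  expect_true(all(diff(fr$kept) <= 0))

  empty <- read_set(g1$reads$reads[0, ])
  rep0 <- run_pipeline(empty, g1$config)
  expect_length(rep0$junctions, 0)
  expect_true(all(rep0$filter_reports$input == 0))

  paths <- write_pipeline_report(rep, tempfile("repdir"))
  expect_true(all(file.exists(paths)))
})

test_that("pipeline configuration rejects unknown keys and bad values", {
  host <- make_host_genome(11, 2000 + 8000, 0.4)
  expect_error(
    pipeline_config("ACGTACGTACGTACGTACGT", "down", host, frobnicate = 1),
    "unknown pipeline configuration keys")
  expect_error(pipeline_config("ACGT", "down", host), "anchor_primer")
  expect_error(
    pipeline_config("ACGTACGTACGTACGTACGT", "sideways", host),
    "direction")
  expect_error(
    pipeline_config("ACGTACGTACGTACGTACGT", "down", host,
                    ke_coverage = 1.5),
    "ke_coverage")
})
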