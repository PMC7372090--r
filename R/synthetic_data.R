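# Synthetic hosts, constructs, insertion events and ALF-enriched reads.
# Ground-truth fields carry the information the pipeline must recover;
# pipeline operations never consult them.

.ELEMENT_CATEGORIES <- c("promoter", "terminator", "coding", "marker",
                         "vector-backbone", "unknown-filler")

# Evaluate code under a temporary RNG state so that every source of
# randomness flows from one explicit seed per call.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

.random_seq <- function(length, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic host genome segment
#'
#' A uniform pseudo-random nucleotide string with a target GC content,
#' standing in for the region of the host plant genome around an insertion
#' site. Reproducible for a fixed seed.
#'
#' @param seed integer seed; all randomness in the call flows from it
#' @param length segment length in nt (>= 1000)
#' @param gc target GC fraction in (0, 1); petunia-like genomes are around
#'   0.37
#' @return a nucleotide string
#' @export
make_host_genome <- function(seed, length = 50000L, gc = 0.37) {
  if (!is.numeric(length) || length(length) != 1 || length < 1000)
    stop("`length` must be a single number >= 1000 (got ",
         deparse(substitute(length)), " = ", length, ")")
  stopifnot(gc > 0, gc < 1)
  .with_seed(seed, .random_seq(as.integer(length), gc))
}

#' Define a GM element
#'
#' @param name short identifier, e.g. `"P-35S"` or `"T-nos"`
#' @param sequence nucleotide string over A/C/G/T, non-empty
#' @param category one of promoter, terminator, coding, marker,
#'   vector-backbone, unknown-filler
#' @return an `element_def`
#' @export
element_def <- function(name, sequence, category) {
  stopifnot(is.character(name), nchar(name) > 0,
            is.character(sequence), nchar(sequence) > 0)
  if (grepl("[^ACGT]", sequence))
    stop("element `", name, "`: sequence contains characters outside ACGT")
  category <- match.arg(category, .ELEMENT_CATEGORIES)
  structure(list(name = name, sequence = sequence, category = category),
            class = "element_def")
}

# name, length, category, generation seed for each stand-in element.
# Real element sequences are not public in full; these are fixed
# pseudo-random stand-ins of realistic length, generated once from the
# recorded seeds so that all tests are self-contained.
.ELEMENT_SPECS <- list(
  list("P-35S",  352L, "promoter",        101L),
  list("P-nos",  308L, "promoter",        102L),
  list("T-nos",  253L, "terminator",      103L),
  list("T-ocs",  223L, "terminator",      104L),
  list("T-35S",  204L, "terminator",      105L),
  list("nptII",  795L, "marker",          106L),
  list("dfr",   1140L, "coding",          107L),
  list("F35H",  1520L, "coding",          108L),
  list("bla",    861L, "marker",          109L),
  list("vector", 2000L, "vector-backbone", 110L)
)

#' Bundled database of GM element stand-ins
#'
#' Fixed pseudo-random stand-in sequences for the common screening-target
#' elements (35S and nos promoters/terminators, ocs terminator, nptII and
#' bla markers, the dfr and F3'5'H colour genes, a generic vector
#' backbone), at realistic lengths. Deterministic: the same database is
#' produced on every call.
#'
#' @return named list of [element_def()] objects
#' @export
gm_element_db <- function() {
  out <- lapply(.ELEMENT_SPECS, function(sp) {
    element_def(sp[[1]], .with_seed(sp[[4]], .random_seq(sp[[2]], 0.45)),
                sp[[3]])
  })
  names(out) <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(names(out))) stop("duplicate element names")
  out
}

#' Extract named sequences from an element database
#'
#' @param db a named list of [element_def()] objects
#' @return named character vector of sequences
#' @export
element_sequences <- function(db) {
  vapply(db, function(e) e$sequence, "")
}

#' Assemble a construct from oriented element parts
#'
#' Concatenates kept intervals of elements in order, reverse-complementing
#' parts with orientation `"-"`. Intervals are 0-based half-open on the
#' element; `NULL` keeps the full element. A kept interval shorter than
#' the element models a truncated element.
#'
#' @param parts list of parts, each a list with `element` (an
#'   [element_def()] or an element name to look up in `db`), `orientation`
#'   (`"+"` or `"-"`, default `"+"`), and optional `interval`
#' @param db optional named element database for name lookup
#' @return a `construct_map`: `full_sequence` plus a `parts` data.frame
#'   with per-part coordinates (`start`, `end`, 0-based half-open) tiling
#'   the full sequence without gaps or overlaps
#' @export
build_construct <- function(parts, db = NULL) {
  if (length(parts) == 0) stop("construct needs at least one part")
  rows <- list()
  seqs <- character(length(parts))
  pos <- 0L
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    el <- p$element
    if (is.character(el)) {
      if (is.null(db) || is.null(db[[el]]))
        stop("element `", el, "` not found in database")
      el <- db[[el]]
    }
    ori <- if (is.null(p$orientation)) "+" else p$orientation
    stopifnot(ori %in% c("+", "-"))
    iv <- if (is.null(p$interval)) c(0L, nchar(el$sequence)) else p$interval
    if (iv[1] < 0 || iv[2] > nchar(el$sequence) || iv[1] >= iv[2])
      stop("part ", i, " (", el$name, "): kept interval [", iv[1], ",",
           iv[2], ") outside element bounds")
    kept <- substr(el$sequence, iv[1] + 1L, iv[2])
    if (ori == "-") kept <- revcomp(kept)
    seqs[i] <- kept
    rows[[i]] <- data.frame(
      name = el$name, category = el$category, orientation = ori,
      elt_start = as.integer(iv[1]), elt_end = as.integer(iv[2]),
      start = pos, end = pos + nchar(kept), stringsAsFactors = FALSE)
    pos <- pos + nchar(kept)
  }
  structure(list(parts = do.call(rbind, rows),
                 full_sequence = paste(seqs, collapse = "")),
            class = "construct_map")
}

#' @export
print.construct_map <- function(x, ...) {
  cat("<construct_map>", nrow(x$parts), "parts,",
      nchar(x$full_sequence), "nt\n")
  print(x$parts[, c("name", "orientation", "start", "end")], row.names = FALSE)
  invisible(x)
}

#' G1-like construct layout
#'
#' A dfr-carrying cassette with a partial bla marker at its 5' end:
#' truncated bla, P-35S, dfr, T-ocs, P-nos, nptII, T-35S, all forward.
#'
#' @param db element database, default [gm_element_db()]
#' @return a `construct_map`
#' @export
construct_g1 <- function(db = gm_element_db()) {
  build_construct(list(
    list(element = "bla", interval = c(361L, 861L)), # truncated marker
    list(element = "P-35S"),
    list(element = "dfr"),
    list(element = "T-ocs"),
    list(element = "P-nos"),
    list(element = "nptII"),
    list(element = "T-35S")
  ), db = db)
}

#' G2-like construct layout
#'
#' Two coding sequences in opposite directions (nptII and F3'5'H) with the
#' promoters in the middle, a T-nos terminator at either end, and a vector
#' stretch between the promoters:
#' T-nos-, nptII-, P-nos-, vector+, P-35S+, F35H+, T-nos+.
#'
#' @param db element database, default [gm_element_db()]
#' @return a `construct_map`
#' @export
construct_g2 <- function(db = gm_element_db()) {
  build_construct(list(
    list(element = "T-nos", orientation = "-"),
    list(element = "nptII", orientation = "-"),
    list(element = "P-nos", orientation = "-"),
    list(element = "vector"),
    list(element = "P-35S"),
    list(element = "F35H"),
    list(element = "T-nos")
  ), db = db)
}

#' Create a synthetic insertion event
#'
#' Inserts a construct into a host genome at a given position, optionally
#' deleting host bases at the insertion site and adding filler sequence
#' (rearranged/unknown DNA) on either side of the construct, as observed
#' between construct and genome in real events. The assembled event
#' sequence satisfies, exactly:
#' `host[0:insertion_pos] + left_filler + construct + right_filler +
#' host[insertion_pos + site_deletion_len:]`.
#'
#' @param host host genome nucleotide string
#' @param construct a `construct_map` from [build_construct()]
#' @param insertion_pos 0-based host coordinate of the insertion
#' @param site_deletion_len host bases deleted at the site
#' @param left_filler,right_filler either an integer length (random filler
#'   generated from `seed`) or an explicit nucleotide string; 0/"" for none
#' @param seed seed for random filler generation
#' @return a `synthetic_event` with `event_sequence` and `truth_junctions`
#'   (0-based breakpoints on the event sequence and matched host
#'   coordinates)
#' @export
create_event <- function(host, construct, insertion_pos,
                         site_deletion_len = 0L,
                         left_filler = 0L, right_filler = 0L, seed = 1L) {
  stopifnot(inherits(construct, "construct_map"))
  n <- nchar(host)
  if (insertion_pos < 0 || insertion_pos > n - site_deletion_len)
    stop("insertion_pos ", insertion_pos, " out of range for host of ",
         n, " nt with deletion ", site_deletion_len)
  fill <- .with_seed(seed, list(
    left = if (is.character(left_filler)) left_filler
           else .random_seq(as.integer(left_filler), 0.42),
    right = if (is.character(right_filler)) right_filler
            else .random_seq(as.integer(right_filler), 0.42)))
  lf <- fill$left; rf <- fill$right
  cs <- nchar(construct$full_sequence)
  event_sequence <- paste0(
    substr(host, 1, insertion_pos), lf, construct$full_sequence, rf,
    substr(host, insertion_pos + site_deletion_len + 1L, n))
  construct_start <- insertion_pos + nchar(lf)
  construct_end <- construct_start + cs
  truth_junctions <- list(
    left = list(host_end_on_event = as.integer(insertion_pos),
                construct_start_on_event = as.integer(construct_start),
                host_coord = as.integer(insertion_pos)),
    right = list(construct_end_on_event = as.integer(construct_end),
                 host_start_on_event = as.integer(construct_end + nchar(rf)),
                 host_coord = as.integer(insertion_pos + site_deletion_len)))
  structure(list(host_genome = host,
                 insertion_pos = as.integer(insertion_pos),
                 site_deletion_len = as.integer(site_deletion_len),
                 left_filler = lf, right_filler = rf,
                 construct = construct,
                 event_sequence = event_sequence,
                 truth_junctions = truth_junctions),
            class = "synthetic_event")
}

#' @export
print.synthetic_event <- function(x, ...) {
  cat(sprintf(
    "<synthetic_event> host %d nt + construct %d nt (fillers %d/%d, deletion %d) -> event %d nt\n",
    nchar(x$host_genome), nchar(x$construct$full_sequence),
    nchar(x$left_filler), nchar(x$right_filler), x$site_deletion_len,
    nchar(x$event_sequence)))
  invisible(x)
}

#' Construct a read set
#'
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`
#'   (Phred+33 string), `truth_origin`, `truth_start`
#' @param provenance free-text label
#' @return a `read_set`; its `counts` field always equals `nrow(reads)`
#' @export
read_set <- function(reads, provenance = "") {
  needed <- c("read_id", "sequence", "quality", "truth_origin", "truth_start")
  stopifnot(is.data.frame(reads), all(needed %in% names(reads)))
  if (nrow(reads) > 0 &&
      any(nchar(reads$quality) != nchar(reads$sequence)))
    stop("quality string length must equal sequence length for every read")
  structure(list(reads = reads, provenance = provenance,
                 counts = nrow(reads)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set>", x$counts, "reads")
  if (nzchar(x$provenance)) cat(" (", x$provenance, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Mean Phred quality per read
#'
#' @param rs a `read_set`
#' @return numeric vector of per-read mean base qualities
#' @export
mean_read_quality <- function(rs) {
  vapply(rs$reads$quality,
         function(q) mean(utf8ToInt(q)) - 33, 0, USE.NAMES = FALSE)
}

# Truncated log-normal read lengths via inverse-CDF sampling.
.sample_lengths <- function(n, meanlog, sdlog, lo = 200L, hi = 8000L) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  u <- stats::runif(n, plo, phi)
  as.integer(round(stats::qlnorm(u, meanlog, sdlog)))
}

# Apply substitution/insertion/deletion errors to one sequence.
.mutate_seq <- function(s, sub, ins, del) {
  if (sub + ins + del == 0) return(s)
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(b)
  m <- stats::runif(n) < sub
  if (any(m)) {
    alts <- matrix(c("C", "G", "T", "A", "G", "T",
                     "A", "C", "T", "A", "C", "G"), nrow = 3)
    col <- match(b[m], c("A", "C", "G", "T"))
    pick <- sample.int(3, sum(m), replace = TRUE)
    b[m] <- alts[cbind(pick, col)]
  }
  keep <- stats::runif(n) >= del
  insm <- stats::runif(n) < ins
  insbase <- rep("", n)
  if (any(insm))
    insbase[insm] <- sample(c("A", "C", "G", "T"), sum(insm), replace = TRUE)
  b[!keep] <- ""
  paste(paste0(b, insbase), collapse = "")
}

#' Simulate ALF-enriched long reads from an insertion event
#'
#' Emulates a targeted-enrichment nanopore run: on-target reads start at
#' an anchor (enrichment) primer site on the event sequence and extend in
#' the enrichment direction across the construct-genome junction;
#' off-target reads are drawn from random host positions, from single GM
#' elements, and (optionally) from a second, already-characterized
#' background event. Read lengths are log-normal truncated to
#' \[200, 8000\] nt; errors are per-base substitutions, insertions and
#' deletions; each finished molecule is emitted on a random strand.
#' The hidden origin of each read is recorded in `truth_origin` /
#' `truth_start` for evaluation only.
#'
#' @param event a `synthetic_event`
#' @param anchor_primer nucleotide string; must occur verbatim in the
#'   event sequence
#' @param direction `"down"` (reads run rightward from the primer on the
#'   plus strand) or `"up"` (reads run leftward; molecules are the minus
#'   strand, beginning with the reverse complement of the primer)
#' @param n_reads total reads to simulate
#' @param on_target_frac expected fraction of enrichment-derived reads;
#'   the realized count is binomial
#' @param background_event optional `synthetic_event` supplying
#'   known-event background reads
#' @param element_db element database for element-only off-target reads
#' @param length_dist `c(meanlog, sdlog)` of the log-normal read length
#' @param error_rates `c(substitution, insertion, deletion)` per-base
#'   rates, each in \[0, 0.15\]; the default totals ~8%, nanopore-like
#' @param seed integer seed; fixed seed gives byte-identical output
#' @param base_quality constant per-base Phred quality placeholder
#' @return a `read_set`
#' @export
simulate_alf_reads <- function(event, anchor_primer,
                               direction = c("down", "up"),
                               n_reads = 1000L, on_target_frac = 0.3,
                               background_event = NULL,
                               element_db = gm_element_db(),
                               length_dist = c(meanlog = 7.0, sdlog = 0.45),
                               error_rates = c(0.03, 0.02, 0.03),
                               seed = 1L, base_quality = 12L) {
  direction <- match.arg(direction)
  stopifnot(inherits(event, "synthetic_event"),
            all(error_rates >= 0), all(error_rates <= 0.15),
            on_target_frac >= 0, on_target_frac <= 1, n_reads >= 0)
  anchor <- regexpr(anchor_primer, event$event_sequence, fixed = TRUE)
  if (anchor < 0)
    stop("anchor primer `", anchor_primer,
         "` not found in the event sequence")
  a_start <- as.integer(anchor) - 1L # 0-based
  a_end <- a_start + nchar(anchor_primer)
  ev_seq <- event$event_sequence

  cats <- c("host_random", "element_only", "known_event_background")
  w <- if (is.null(background_event)) c(2 / 3, 1 / 3, 0) else c(0.5, 0.25, 0.25)

  .with_seed(seed, {
    origin <- ifelse(stats::runif(n_reads) < on_target_frac, "on_target",
                     sample(cats, n_reads, replace = TRUE, prob = w))
    lens <- .sample_lengths(n_reads, length_dist[1], length_dist[2])
    seqs <- character(n_reads)
    tstart <- integer(n_reads)
    el_seqs <- element_sequences(element_db)
    for (i in seq_len(n_reads)) {
      L <- lens[i]
      if (origin[i] == "on_target") {
        if (direction == "down") {
          s <- a_start
          e <- min(nchar(ev_seq), s + L)
          mol <- substr(ev_seq, s + 1L, e)
        } else {
          e <- a_end
          s <- max(0L, e - L)
          mol <- revcomp(substr(ev_seq, s + 1L, e))
        }
        tstart[i] <- s
      } else {
        src <- switch(origin[i],
          host_random = event$host_genome,
          element_only = el_seqs[[sample.int(length(el_seqs), 1)]],
          known_event_background = background_event$event_sequence)
        s <- sample.int(max(1L, nchar(src) - min(L, nchar(src)) + 1L), 1) - 1L
        mol <- substr(src, s + 1L, min(nchar(src), s + L))
        tstart[i] <- s
      }
      mol <- .mutate_seq(mol, error_rates[1], error_rates[2], error_rates[3])
      if (stats::runif(1) < 0.5) mol <- revcomp(mol)
      seqs[i] <- mol
    }
    qual <- vapply(nchar(seqs),
                   function(n) strrep(intToUtf8(33L + as.integer(base_quality)), n),
                   "")
    read_set(data.frame(
      read_id = sprintf("read_%05d", seq_len(n_reads)),
      sequence = seqs, quality = qual,
      truth_origin = origin, truth_start = tstart,
      stringsAsFactors = FALSE),
      provenance = sprintf("simulated ALF run (%s, seed %d)", direction, seed))
  })
}
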