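#' Alignment scoring scheme
#'
#' Affine-gap scoring used by all local-alignment operations in the
#' package. A gap of length L scores `gap_open + L * gap_extend`
#' (the opening penalty is charged once per gap, on top of the per-base
#' extension). Defaults are tuned for noisy long reads at roughly 10%
#' error.
#'
#' @param match per-base match score (> 0)
#' @param mismatch per-base mismatch score (< 0)
#' @param gap_open gap opening penalty (<= 0)
#' @param gap_extend per-base gap extension penalty (<= 0)
#' @return a named list of class `align_scoring`
#' @export
align_scoring <- function(match = 2L, mismatch = -3L,
                          gap_open = -5L, gap_extend = -2L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_scoring")
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of nucleotide strings
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  .revcomp_cpp(x)
}

.empty_alignment <- function(strand = "+") {
  structure(list(score = 0L, identity = NA_real_,
                 query_interval = c(0L, 0L), ref_interval = c(0L, 0L),
                 strand = strand, cigar = "", n_match = 0L, n_cols = 0L),
            class = "alignment_result")
}

.as_alignment <- function(raw, strand = "+") {
  identity <- if (raw$n_cols > 0) raw$n_match / raw$n_cols else NA_real_
  structure(list(score = raw$score, identity = identity,
                 query_interval = c(raw$q_start, raw$q_end),
                 ref_interval = c(raw$r_start, raw$r_end),
                 strand = strand, cigar = raw$cigar,
                 n_match = raw$n_match, n_cols = raw$n_cols),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> score=%d identity=%.3f query=[%d,%d) ref=[%d,%d) strand=%s\n",
    x$score, ifelse(is.na(x$identity), 0, x$identity),
    x$query_interval[1], x$query_interval[2],
    x$ref_interval[1], x$ref_interval[2], x$strand))
  invisible(x)
}

# Group exact k-mer hits into diagonal clusters; each cluster becomes one
# banded-DP candidate.  diag = ref_pos - query_pos.  Clusters supported
# by fewer than min_hits seeds are noise on long inputs and are skipped
# (small inputs fall back to full DP instead).
.diag_clusters <- function(hits, band_join = 75L, max_clusters = 8L,
                           min_hits = 2L) {
  if (nrow(hits) == 0) return(list())
  diag <- hits[, 2] - hits[, 1]
  o <- order(diag)
  diag <- diag[o]
  grp <- cumsum(c(1L, as.integer(diff(diag) > band_join)))
  cl <- split(seq_along(diag), grp)
  cl <- cl[vapply(cl, length, 1L) >= min_hits]
  cl <- cl[order(vapply(cl, length, 1L), decreasing = TRUE)]
  if (length(cl) > max_clusters) cl <- cl[seq_len(max_clusters)]
  lapply(cl, function(idx) range(diag[idx]))
}

# All candidate local alignments of query against one strand of ref,
# via k-mer seeding and banded DP; falls back to full DP for small inputs
# with no usable seeds.
.candidates_one_strand <- function(query, ref, scoring, strand,
                                   k = 11L, band_margin = 60L,
                                   full_dp_cells = 2.5e5) {
  m <- nchar(query); n <- nchar(ref)
  if (m == 0 || n == 0) return(list())
  hits <- .kmer_hits_cpp(query, ref, as.integer(min(k, m, n)))
  out <- list()
  for (dr in .diag_clusters(hits)) {
    raw <- .sw_align_cpp(query, ref, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend,
                         as.integer(dr[1] - band_margin),
                         as.integer(dr[2] + band_margin))
    if (raw$score > 0) out[[length(out) + 1L]] <- .as_alignment(raw, strand)
  }
  if (length(out) == 0 && as.double(m) * n <= full_dp_cells) {
    raw <- .sw_align_cpp(query, ref, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend, -m, n)
    if (raw$score > 0) out[[length(out) + 1L]] <- .as_alignment(raw, strand)
  }
  out
}

# Candidates on both strands.  Minus-strand alignments are computed by
# aligning the reverse-complemented query against the reference (cheaper
# than reverse-complementing every reference) and reporting intervals on
# the query as given, with reference coordinates already on the plus
# strand.
.candidate_matches <- function(query, reference, scoring,
                               min_identity = 0, min_length = 1L) {
  cands <- c(.candidates_one_strand(query, reference, scoring, "+"),
             .candidates_one_strand(revcomp(query), reference, scoring, "-"))
  m <- nchar(query)
  cands <- lapply(cands, function(al) {
    if (al$strand == "-") { # map query interval back to the given query
      al$query_interval <- c(m - al$query_interval[2],
                             m - al$query_interval[1])
    }
    al
  })
  Filter(function(al) {
    !is.na(al$identity) && al$identity >= min_identity &&
      (al$query_interval[2] - al$query_interval[1]) >= min_length
  }, cands)
}

#' Local alignment of two nucleotide strings
#'
#' Maximal-scoring affine-gap local alignment. Small problems are solved
#' by full dynamic programming; larger ones use exact k-mer seeding with
#' banded dynamic programming around the seeded diagonals. Intervals are
#' 0-based, half-open. Empty input yields a score-0 result rather than an
#' error.
#'
#' @param a query nucleotide string
#' @param b reference nucleotide string
#' @param scoring an [align_scoring()] scheme
#' @param full_dp_cells matrix-size cap (cells) below which full DP is used
#' @return an `alignment_result`: score, identity (matches / alignment
#'   columns), `query_interval`, `ref_interval`, strand, and a CIGAR-like
#'   edit path using `=`, `X`, `I` (unaligned query base), `D` (unaligned
#'   reference base)
#' @export
local_align <- function(a, b, scoring = align_scoring(),
                        full_dp_cells = 1e6) {
  stopifnot(is.character(a), length(a) == 1, is.character(b), length(b) == 1)
  m <- nchar(a); n <- nchar(b)
  if (m == 0 || n == 0) return(.empty_alignment())
  if (as.double(m) * n <= full_dp_cells) {
    raw <- .sw_align_cpp(a, b, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend, -m, n)
    if (raw$score == 0) return(.empty_alignment())
    return(.as_alignment(raw, "+"))
  }
  cands <- .candidates_one_strand(a, b, scoring, "+",
                                  full_dp_cells = full_dp_cells)
  if (length(cands) == 0) return(.empty_alignment())
  scores <- vapply(cands, function(x) x$score, 1L)
  cands[[which.max(scores)]]
}

#' Find all local matches of a query against a reference
#'
#' Searches both strands, then greedily selects candidate alignments in
#' decreasing score order, keeping only those that do not overlap an
#' already-selected match on the query. Every returned match satisfies the
#' identity and length thresholds.
#'
#' @param query,reference nucleotide strings
#' @param min_identity minimum alignment identity in (0, 1]
#' @param min_length minimum matched length on the query (nt)
#' @param scoring an [align_scoring()] scheme
#' @return list of `alignment_result`, ordered by query start
#' @export
find_all_local_matches <- function(query, reference,
                                   min_identity = 0.75, min_length = 50L,
                                   scoring = align_scoring()) {
  stopifnot(min_identity > 0, min_identity <= 1)
  if (nchar(query) == 0 || nchar(reference) == 0) return(list())
  cands <- .candidate_matches(query, reference, scoring,
                              min_identity, min_length)
  if (length(cands) == 0) return(list())
  sc <- vapply(cands, function(x) x$score, 1L)
  qs <- vapply(cands, function(x) x$query_interval[1], 1L)
  rs <- vapply(cands, function(x) x$ref_interval[1], 1L)
  ord <- order(-sc, qs, rs)
  kept <- list()
  covered <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    qi <- cands[[i]]$query_interval
    if (nrow(covered) == 0 ||
        all(qi[2] <= covered[, 1] | qi[1] >= covered[, 2])) {
      kept[[length(kept) + 1L]] <- cands[[i]]
      covered <- rbind(covered, qi)
    }
  }
  kept[order(vapply(kept, function(x) x$query_interval[1], 1L))]
}

#' Fraction of a read covered by matches to a reference set
#'
#' The union of query intervals of all threshold-passing local matches
#' (both strands, all references) divided by the read length. Used by the
#' read-subtraction stages to decide whether a read is explained by known
#' sequence.
#'
#' @param read nucleotide string (non-empty)
#' @param references character vector (or named list) of reference
#'   nucleotide strings; empty set gives coverage 0
#' @param min_identity,min_length match thresholds, as in
#'   [find_all_local_matches()]
#' @param scoring an [align_scoring()] scheme
#' @return a fraction in \[0, 1\]
#' @export
coverage_fraction <- function(read, references,
                              min_identity = 0.75, min_length = 50L,
                              scoring = align_scoring()) {
  stopifnot(is.character(read), length(read) == 1, nchar(read) > 0)
  references <- unlist(references, use.names = FALSE)
  if (length(references) == 0) return(0)
  ivs <- list()
  for (ref in references) {
    for (al in .candidate_matches(read, ref, scoring,
                                  min_identity, min_length)) {
      ivs[[length(ivs) + 1L]] <- al$query_interval
    }
  }
  if (length(ivs) == 0) return(0)
  starts <- vapply(ivs, `[`, 1L, 1) + 1L # to 1-based inclusive
  ends <- vapply(ivs, `[`, 1L, 2)
  merged <- IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
  sum(IRanges::width(merged)) / nchar(read)
}

#' Substitution-only pattern matching on both strands
#'
#' Hamming-style sliding match of a short pattern (e.g. an enrichment
#' primer) against a text, optionally restricted to a window. Indels are
#' deliberately not modelled: at primer lengths (~17-18 nt) indel-tolerant
#' matching produces spurious hits.
#'
#' @param pattern nucleotide string, `length(pattern) <= length(text)`
#' @param text nucleotide string
#' @param max_mismatches maximum substitutions, `< nchar(pattern)`
#' @param search_window optional 0-based half-open `c(start, end)` interval
#'   on `text` to which matches are restricted
#' @return data.frame with 0-based `position` (on the given text, start of
#'   the matched window), `mismatches`, and `strand`, sorted by position
#' @export
match_with_mismatches <- function(pattern, text, max_mismatches = 0L,
                                  search_window = NULL) {
  stopifnot(nchar(pattern) <= nchar(text), max_mismatches < nchar(pattern))
  offset <- 0L
  if (!is.null(search_window)) {
    stopifnot(length(search_window) == 2, search_window[1] >= 0,
              search_window[2] <= nchar(text),
              search_window[1] < search_window[2])
    offset <- as.integer(search_window[1])
    text <- substr(text, search_window[1] + 1L, search_window[2])
    if (nchar(pattern) > nchar(text)) {
      return(data.frame(position = integer(0), mismatches = integer(0),
                        strand = character(0)))
    }
  }
  fwd <- .hamming_scan_cpp(pattern, text, as.integer(max_mismatches))
  rev <- .hamming_scan_cpp(revcomp(pattern), text, as.integer(max_mismatches))
  out <- data.frame(
    position = c(fwd[, 1], rev[, 1]) + offset,
    mismatches = c(fwd[, 2], rev[, 2]),
    strand = c(rep("+", nrow(fwd)), rep("-", nrow(rev))),
    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}
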