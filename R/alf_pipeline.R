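# Read-selection cascade, clustering, consensus and junction calling for
# ALF-enriched long reads.  Stage order mirrors the wet-lab analysis:
# QC -> primer selection -> known-event subtraction -> element-coverage
# subtraction -> clustering -> consensus -> annotation -> junction call.

.filter_report <- function(stage, input, kept, params = "") {
  data.frame(stage = stage, input = as.integer(input),
             kept = as.integer(kept),
             removed = as.integer(input - kept),
             params = params, stringsAsFactors = FALSE)
}

.subset_read_set <- function(rs, keep, provenance = rs$provenance) {
  read_set(rs$reads[keep, , drop = FALSE], provenance = provenance)
}

#' Quality-control filter
#'
#' Keeps reads whose length lies in `[min_len, max_len]` and whose mean
#' base quality is at least `min_mean_quality`.
#'
#' @param rs a `read_set`
#' @param min_len,max_len length bounds in nt
#' @param min_mean_quality minimum mean Phred quality
#' @return list with the filtered `read_set` and a one-row `report`
#'   (input = kept + removed always holds)
#' @export
qc_filter <- function(rs, min_len = 200L, max_len = 8000L,
                      min_mean_quality = 7) {
  stopifnot(min_len <= max_len)
  len <- nchar(rs$reads$sequence)
  mq <- mean_read_quality(rs)
  keep <- len >= min_len & len <= max_len & mq >= min_mean_quality
  list(reads = .subset_read_set(rs, keep),
       report = .filter_report(
         "qc", rs$counts, sum(keep),
         sprintf("min_len=%d,max_len=%d,min_mean_quality=%g",
                 min_len, max_len, min_mean_quality)))
}

#' Primer selection
#'
#' Keeps reads that carry the enrichment primer (either strand) within
#' the window where enrichment places it, and re-orients minus-strand
#' hits so that every kept read runs primer-to-unknown. For `"down"`
#' enrichment the primer itself starts the molecule; for `"up"`
#' enrichment the molecule begins with the reverse complement of the
#' primer.
#'
#' Matching tolerates `max_mismatches` edits (substitutions or indels):
#' nanopore-scale indel rates would otherwise reject a large share of
#' genuinely enriched reads.
#'
#' @param rs a `read_set`
#' @param anchor_primer enrichment primer sequence (>= 15 nt)
#' @param direction `"down"` or `"up"` enrichment
#' @param max_mismatches allowed edits in the primer match
#' @param window_len window at the read start (or end, for flipped reads)
#'   searched for the primer
#' @return list with the filtered, re-oriented `read_set` and a `report`
#' @export
primer_select <- function(rs, anchor_primer, direction = c("down", "up"),
                          max_mismatches = 2L, window_len = 150L) {
  direction <- match.arg(direction)
  stopifnot(nchar(anchor_primer) >= 15)
  ep <- if (direction == "down") anchor_primer else revcomp(anchor_primer)
  ep_rc <- revcomp(ep)
  plen <- nchar(ep)
  hit <- function(pattern, window) {
    .edit_presence_cpp(pattern, window, as.integer(max_mismatches))
  }
  n <- rs$counts
  keep <- logical(n)
  flip <- logical(n)
  for (i in seq_len(n)) {
    s <- rs$reads$sequence[i]
    len <- nchar(s)
    if (len < plen) next
    head_w <- substr(s, 1, min(window_len, len))
    if (nchar(head_w) >= plen && hit(ep, head_w)) {
      keep[i] <- TRUE
      next
    }
    tail_w <- substr(s, max(1L, len - window_len + 1L), len)
    if (nchar(tail_w) >= plen && hit(ep_rc, tail_w)) {
      keep[i] <- TRUE
      flip[i] <- TRUE
    }
  }
  reads <- rs$reads
  if (any(flip)) {
    reads$sequence[flip] <- revcomp(reads$sequence[flip])
    reads$quality[flip] <- vapply(reads$quality[flip], function(q)
      paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = ""), "")
  }
  list(reads = read_set(reads[keep, , drop = FALSE],
                        provenance = rs$provenance),
       report = .filter_report(
         "primer_select", n, sum(keep),
         sprintf("direction=%s,max_mismatches=%d,window_len=%d",
                 direction, max_mismatches, window_len)))
}

.subtract_by_coverage <- function(rs, refs, min_identity, coverage_threshold,
                                  stage, min_length = 50L) {
  refs <- unlist(refs, use.names = FALSE)
  if (length(refs) == 0 || rs$counts == 0) {
    return(list(reads = rs,
                report = .filter_report(stage, rs$counts, rs$counts,
                                        "no references")))
  }
  cov <- vapply(rs$reads$sequence, function(s)
    coverage_fraction(s, refs, min_identity = min_identity,
                      min_length = min_length), 0, USE.NAMES = FALSE)
  keep <- cov < coverage_threshold
  list(reads = .subset_read_set(rs, keep),
       report = .filter_report(
         stage, rs$counts, sum(keep),
         sprintf("min_identity=%g,coverage_threshold=%g",
                 min_identity, coverage_threshold)))
}

#' Subtract reads matching known event sequences
#'
#' Removes reads whose coverage by known construct-and-flanking (CaF)
#' references reaches `coverage_threshold`: such reads carry no new
#' information about the unknown event. With an empty reference list
#' nothing is removed.
#'
#' @param rs a `read_set`
#' @param known_event_refs character vector of known event (construct +
#'   flank) sequences
#' @param min_identity match identity threshold
#' @param coverage_threshold fraction of the read that must be covered
#'   for removal; looser than element subtraction because a CaF match
#'   indicates whole-read provenance
#' @return list of filtered `read_set` and `report`
#' @export
subtract_known_event <- function(rs, known_event_refs,
                                 min_identity = 0.75,
                                 coverage_threshold = 0.8) {
  .subtract_by_coverage(rs, known_event_refs, min_identity,
                        coverage_threshold, "known_event_subtraction")
}

#' Subtract reads fully covered by known GM elements
#'
#' Removes reads explained end-to-end by single known GM element
#' sequences (coverage at least `coverage_threshold`, default 0.95 as the
#' operational reading of "fully covered"). Junction-spanning reads keep
#' their genome-side portion uncovered and survive.
#'
#' @param rs a `read_set`
#' @param element_db element database ([gm_element_db()] layout)
#' @param min_identity match identity threshold
#' @param coverage_threshold coverage at or above which a read is removed
#' @return list of filtered `read_set` and `report`
#' @export
subtract_element_covered <- function(rs, element_db,
                                     min_identity = 0.75,
                                     coverage_threshold = 0.95) {
  .subtract_by_coverage(rs, element_sequences(element_db), min_identity,
                        coverage_threshold, "element_subtraction")
}

#' Greedy seed-based read clustering
#'
#' The longest unassigned read seeds a cluster; every other unassigned
#' read joins it if it aligns to the seed (either strand) at
#' `>= min_identity` over `>= min_overlap` nt. Each read belongs to at
#' most one cluster. By default only clusters with more than 5 members
#' are retained.
#'
#' @param rs a `read_set`
#' @param min_identity alignment identity to the seed required to join
#' @param min_overlap matched length (nt) on the member required to join
#' @param min_cluster_size smallest retained cluster (default 6, i.e.
#'   "more than 5 reads per cluster")
#' @param scoring an [align_scoring()] scheme
#' @return list of `cluster` objects: `members` data.frame (read_id,
#'   strand, identity, offset of the member on the seed), `seed_id`,
#'   `mean_identity`
#' @export
cluster_reads <- function(rs, min_identity = 0.75, min_overlap = 150L,
                          min_cluster_size = 6L,
                          scoring = align_scoring()) {
  stopifnot(min_cluster_size >= 1)
  n <- rs$counts
  if (n == 0) return(list())
  lens <- nchar(rs$reads$sequence)
  ord <- order(-lens)
  assigned <- logical(n)
  clusters <- list()
  for (si in ord) {
    if (assigned[si]) next
    seed_seq <- rs$reads$sequence[si]
    assigned[si] <- TRUE
    mem <- data.frame(read_id = rs$reads$read_id[si], strand = "+",
                      identity = 1, offset = 0L, stringsAsFactors = FALSE)
    qualifies <- function(al) {
      al$n_cols > 0 && !is.na(al$identity) && al$identity >= min_identity &&
        (al$query_interval[2] - al$query_interval[1]) >= min_overlap
    }
    for (mi in seq_len(n)) {
      if (assigned[mi]) next
      q <- rs$reads$sequence[mi]
      al <- local_align(q, seed_seq, scoring = scoring)
      strand <- "+"
      if (!qualifies(al)) { # only then try the other strand
        al2 <- local_align(revcomp(q), seed_seq, scoring = scoring)
        if (qualifies(al2)) { al <- al2; strand <- "-" }
      }
      if (qualifies(al)) {
        assigned[mi] <- TRUE
        mem <- rbind(mem, data.frame(
          read_id = rs$reads$read_id[mi], strand = strand,
          identity = al$identity,
          offset = al$ref_interval[1] - al$query_interval[1],
          stringsAsFactors = FALSE))
      }
    }
    clusters[[length(clusters) + 1L]] <- structure(
      list(members = mem, seed_id = rs$reads$read_id[si],
           mean_identity = mean(mem$identity)),
      class = "alf_cluster")
  }
  Filter(function(cl) nrow(cl$members) >= min_cluster_size, clusters)
}

#' @export
print.alf_cluster <- function(x, ...) {
  cat(sprintf("<alf_cluster> %d members, seed %s, mean identity %.3f\n",
              nrow(x$members), x$seed_id, x$mean_identity))
  invisible(x)
}

#' Build a cluster consensus by seed-anchored pileup
#'
#' Every member is aligned to the cluster seed; aligned columns vote by
#' summed base quality. Seed columns where a gap is the member majority
#' are dropped (they are seed insertion errors); positions where a
#' majority of members insert a base gain a consensus column (they are
#' seed deletion errors). Ties are broken by larger summed quality, then
#' by the fixed base precedence A < C < G < T, so the output is
#' deterministic.
#'
#' @param cluster an `alf_cluster`
#' @param rs the `read_set` holding the member reads
#' @param scoring an [align_scoring()] scheme
#' @return a `consensus_seq`: `sequence`, per-position `depth` (never
#'   exceeding the cluster size), `cluster_id`
#' @export
build_consensus <- function(cluster, rs, scoring = align_scoring()) {
  stopifnot(inherits(cluster, "alf_cluster"), nrow(cluster$members) >= 1)
  idx <- match(cluster$members$read_id, rs$reads$read_id)
  if (anyNA(idx)) stop("cluster members missing from read set")
  seed_seq <- rs$reads$sequence[match(cluster$seed_id, rs$reads$read_id)]
  n <- nchar(seed_seq)
  bases <- c("A", "C", "G", "T")

  base_cnt <- matrix(0L, nrow = 4, ncol = n)
  base_qual <- matrix(0, nrow = 4, ncol = n)
  gap_cnt <- integer(n)
  cover <- integer(n)
  ins <- list() # key: seed pos (0-based, insertion before it) -> entries

  for (k in seq_along(idx)) {
    i <- idx[k]
    strand <- cluster$members$strand[k]
    s <- rs$reads$sequence[i]
    q <- rs$reads$quality[i]
    if (strand == "-") {
      s <- revcomp(s)
      q <- paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = "")
    }
    al <- local_align(s, seed_seq, scoring = scoring)
    if (al$n_cols == 0) next
    sb <- strsplit(s, "", fixed = TRUE)[[1]]
    qv <- utf8ToInt(q) - 33L
    ops <- regmatches(al$cigar, gregexpr("[0-9]+[=XID]", al$cigar))[[1]]
    qpos <- al$query_interval[1] # 0-based
    rpos <- al$ref_interval[1]
    cover[(al$ref_interval[1] + 1L):al$ref_interval[2]] <-
      cover[(al$ref_interval[1] + 1L):al$ref_interval[2]] + 1L
    for (op in ops) {
      L <- as.integer(sub("[=XID]$", "", op))
      type <- substr(op, nchar(op), nchar(op))
      if (type == "=" || type == "X") {
        cols <- (rpos + 1L):(rpos + L)
        bc <- match(sb[(qpos + 1L):(qpos + L)], bases)
        ok <- !is.na(bc)
        if (any(ok)) {
          # cols are distinct within a run, so matrix indexing is safe
          vote_at <- cbind(bc[ok], cols[ok])
          base_cnt[vote_at] <- base_cnt[vote_at] + 1L
          base_qual[vote_at] <- base_qual[vote_at] +
            qv[((qpos + 1L):(qpos + L))[ok]]
        }
        qpos <- qpos + L; rpos <- rpos + L
      } else if (type == "D") {
        cols <- (rpos + 1L):(rpos + L)
        gap_cnt[cols] <- gap_cnt[cols] + 1L
        rpos <- rpos + L
      } else { # I: member bases absent from the seed, before seed pos rpos
        key <- as.character(rpos)
        cur <- ins[[key]]
        if (is.null(cur)) cur <- list()
        for (t in seq_len(L)) {
          b <- sb[qpos + t]
          if (length(cur) < t) cur[[t]] <- c(A = 0, C = 0, G = 0, T = 0,
                                             members = 0)
          if (b %in% bases) cur[[t]][b] <- cur[[t]][b] + qv[qpos + t]
          cur[[t]]["members"] <- cur[[t]]["members"] + 1
        }
        ins[[key]] <- cur
        qpos <- qpos + L
      }
    }
  }

  out <- character(0)
  depth <- integer(0)
  emit_insertions <- function(pos0) {
    cur <- ins[[as.character(pos0)]]
    if (is.null(cur)) return()
    dj <- if (pos0 >= 1 && pos0 < n) min(cover[pos0], cover[pos0 + 1L])
          else cover[max(1L, min(n, pos0 + 1L))]
    for (t in seq_along(cur)) {
      if (cur[[t]]["members"] > dj / 2) {
        v <- cur[[t]][bases]
        b <- bases[which(v == max(v))[1]] # max then A<C<G<T precedence
        out[length(out) + 1L] <<- b
        depth[length(depth) + 1L] <<- as.integer(cur[[t]]["members"])
      }
    }
  }
  for (p in seq_len(n)) {
    emit_insertions(p - 1L)
    d <- cover[p]
    if (d == 0) next
    if (gap_cnt[p] > d / 2) next # gap is the majority: drop column
    cnt <- base_cnt[, p]
    if (sum(cnt) == 0) next
    qual <- base_qual[, p]
    cand <- which(cnt == max(cnt))
    if (length(cand) > 1) {
      cand <- cand[qual[cand] == max(qual[cand])]
      cand <- cand[1] # base precedence A < C < G < T
    }
    out[length(out) + 1L] <- bases[cand]
    depth[length(depth) + 1L] <- d
  }
  emit_insertions(n)

  structure(list(sequence = paste(out, collapse = ""),
                 depth = depth, cluster_id = cluster$seed_id),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("<consensus_seq> %d nt, mean depth %.1f (cluster %s)\n",
              nchar(x$sequence), mean(x$depth), x$cluster_id))
  invisible(x)
}

#' Annotate a consensus against the reference world
#'
#' Finds the best-matching labeled intervals of a consensus against the
#' GM element database, optional vector references, and the host genome,
#' and reports the remaining gaps as `"unknown"` intervals (rearranged or
#' novel sequence). Matches are chosen greedily by score and do not
#' overlap on the consensus.
#'
#' @param consensus a `consensus_seq` or a nucleotide string
#' @param element_db element database
#' @param known_vector_refs optional named character vector of vector /
#'   plasmid backbone sequences
#' @param host_genome host genome string
#' @param min_identity,min_length match thresholds
#' @param min_gap smallest unmatched stretch reported as `"unknown"`
#' @param trim_tol candidates overlapping an already-selected interval by
#'   at most this many nt are trimmed to the free region instead of being
#'   discarded (alignment boundaries of adjacent features jitter by a few
#'   nt at long-read error rates)
#' @param scoring an [align_scoring()] scheme
#' @return data.frame of ordered intervals: `label`, `category` (element /
#'   vector / host / unknown), `start`, `end` (0-based half-open on the
#'   consensus), `identity`, `strand`, `ref_start`, `ref_end`
#' @export
annotate_consensus <- function(consensus, element_db,
                               known_vector_refs = NULL, host_genome,
                               min_identity = 0.75, min_length = 50L,
                               min_gap = 30L, trim_tol = 100L,
                               scoring = align_scoring()) {
  cseq <- if (inherits(consensus, "consensus_seq")) consensus$sequence
          else consensus
  refs <- list()
  for (nm in names(element_db)) {
    cat_ <- if (element_db[[nm]]$category == "vector-backbone") "vector"
            else "element"
    refs[[length(refs) + 1L]] <- list(name = nm, category = cat_,
                                      seq = element_db[[nm]]$sequence)
  }
  if (!is.null(known_vector_refs)) {
    vn <- names(known_vector_refs)
    if (is.null(vn)) vn <- sprintf("vector_%d", seq_along(known_vector_refs))
    for (i in seq_along(known_vector_refs))
      refs[[length(refs) + 1L]] <- list(name = vn[i], category = "vector",
                                        seq = known_vector_refs[[i]])
  }
  refs[[length(refs) + 1L]] <- list(name = "host", category = "host",
                                    seq = host_genome)

  cands <- list()
  for (r in refs) {
    for (al in .candidate_matches(cseq, r$seq, scoring,
                                  min_identity, min_length)) {
      cands[[length(cands) + 1L]] <- list(al = al, name = r$name,
                                          category = r$category)
    }
  }
  rows <- list()
  if (length(cands) > 0) {
    sc <- vapply(cands, function(x) x$al$score, 1L)
    qs <- vapply(cands, function(x) x$al$query_interval[1], 1L)
    covered <- matrix(numeric(0), ncol = 2)
    for (i in order(-sc, qs)) {
      al <- cands[[i]]$al
      qi <- al$query_interval
      ri <- al$ref_interval
      if (nrow(covered) > 0) {
        # trim the candidate to the uncovered region when the overlap is
        # small boundary jitter; drop it on substantial overlap
        trim_start <- 0L; trim_end <- 0L
        for (r in seq_len(nrow(covered))) {
          lo <- covered[r, 1]; hi <- covered[r, 2]
          if (qi[2] <= lo || qi[1] >= hi) next
          if (qi[1] >= lo && qi[2] <= hi) { trim_start <- Inf; break }
          if (qi[1] < lo && qi[2] > hi) { trim_start <- Inf; break }
          if (qi[1] >= lo) trim_start <- trim_start + (hi - qi[1])
          else trim_end <- trim_end + (qi[2] - lo)
        }
        if (trim_start + trim_end > trim_tol) next
        if (trim_start > 0) {
          qi[1] <- qi[1] + trim_start
          if (al$strand == "+") ri[1] <- ri[1] + trim_start
          else ri[2] <- ri[2] - trim_start
        }
        if (trim_end > 0) {
          qi[2] <- qi[2] - trim_end
          if (al$strand == "+") ri[2] <- ri[2] - trim_end
          else ri[1] <- ri[1] + trim_end
        }
        if (qi[2] - qi[1] < min_length) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        label = cands[[i]]$name, category = cands[[i]]$category,
        start = qi[1], end = qi[2], identity = al$identity,
        strand = al$strand, ref_start = ri[1],
        ref_end = ri[2], stringsAsFactors = FALSE)
      covered <- rbind(covered, qi)
    }
  }
  ann <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(label = character(0), category = character(0),
                         start = integer(0), end = integer(0),
                         identity = numeric(0), strand = character(0),
                         ref_start = integer(0), ref_end = integer(0),
                         stringsAsFactors = FALSE)
  ann <- ann[order(ann$start), , drop = FALSE]

  # fill gaps >= min_gap with "unknown"
  bounds <- c(0L, nchar(cseq))
  gaps <- list()
  prev_end <- bounds[1]
  for (i in seq_len(nrow(ann))) {
    if (ann$start[i] - prev_end >= min_gap)
      gaps[[length(gaps) + 1L]] <- c(prev_end, ann$start[i])
    prev_end <- max(prev_end, ann$end[i])
  }
  if (bounds[2] - prev_end >= min_gap)
    gaps[[length(gaps) + 1L]] <- c(prev_end, bounds[2])
  for (g in gaps) {
    ann <- rbind(ann, data.frame(
      label = "unknown", category = "unknown", start = g[1], end = g[2],
      identity = NA_real_, strand = "+", ref_start = NA_integer_,
      ref_end = NA_integer_, stringsAsFactors = FALSE))
  }
  ann <- ann[order(ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Call a construct-genome junction on an annotated consensus
#'
#' A junction is called when a construct-side interval (element or
#' vector) and a host-side interval, each at least `min_anchor_len` nt at
#' `>= min_anchor_identity`, are adjacent on the consensus, allowing an
#' intervening `"unknown"` spacer of at most `max_spacer` nt (fillers and
#' rearrangements sit between construct and genome in some events).
#' Unmatched stretches shorter than the annotation gap floor count as no
#' spacer. Confidence is `"high"` for a direct transition and `"low"`
#' across a spacer.
#'
#' @param annotation data.frame from [annotate_consensus()]
#' @param min_anchor_len minimum anchor length (>= 30 nt)
#' @param min_anchor_identity minimum anchor identity
#' @param max_spacer largest allowed unknown spacer (nt) between
#'   construct side and genome side
#' @param jitter_tol gaps shorter than this (alignment-boundary jitter)
#'   count as a direct transition
#' @param consensus_id optional id copied into the call
#' @return a `junction_call` (construct-side row, genome-side row,
#'   breakpoint on the consensus, breakpoint on the host, spacer length,
#'   confidence), or `NULL` when no qualifying pair exists
#' @export
call_junction <- function(annotation, min_anchor_len = 100L,
                          min_anchor_identity = 0.8, max_spacer = 2000L,
                          jitter_tol = 50L, consensus_id = NA_character_) {
  stopifnot(min_anchor_len >= 30)
  ann <- annotation
  if (nrow(ann) == 0) return(NULL)
  len <- ann$end - ann$start
  qual <- !is.na(ann$identity) & ann$identity >= min_anchor_identity &
    len >= min_anchor_len
  is_construct <- ann$category %in% c("element", "vector") & qual
  is_host <- ann$category == "host" & qual
  if (!any(is_construct) || !any(is_host)) return(NULL)

  best <- NULL
  ci <- which(is_construct); hi <- which(is_host)
  for (a in ci) {
    for (b in hi) {
      lo <- min(a, b); hiI <- max(a, b)
      between <- setdiff(seq(lo, hiI), c(a, b))
      if (length(between) > 0 && any(ann$category[between] != "unknown"))
        next
      first <- if (ann$start[a] <= ann$start[b]) a else b
      second <- if (first == a) b else a
      spacer <- max(0L, ann$start[second] - ann$end[first])
      if (spacer < jitter_tol) spacer <- 0L
      if (spacer > max_spacer) next
      if (is.null(best) || spacer < best$spacer)
        best <- list(a = a, b = b, first = first, second = second,
                     spacer = spacer)
    }
  }
  if (is.null(best)) return(NULL)
  a <- best$a; b <- best$b
  construct_first <- (best$first == a)
  host_row <- ann[b, ]
  bp_cons <- if (construct_first) host_row$start else host_row$end
  bp_host <- .host_coord_at(host_row, bp_cons)
  structure(list(
    consensus_id = consensus_id,
    construct_side = ann[a, ],
    genome_side = host_row,
    breakpoint_consensus = as.integer(bp_cons),
    breakpoint_host = as.integer(bp_host),
    spacer_len = as.integer(best$spacer),
    confidence = if (best$spacer == 0) "high" else "low"),
    class = "junction_call")
}

# Host coordinate corresponding to a consensus position, extrapolating
# the host anchor alignment linearly (valid near the anchor; the window
# is short and the consensus is polished).
.host_coord_at <- function(host_row, cpos) {
  off <- cpos - host_row$start
  if (host_row$strand == "+") host_row$ref_start + off
  else host_row$ref_end - off
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf(
    "<junction_call> %s|%s host breakpoint %d (consensus %d), spacer %d nt, confidence %s\n",
    x$construct_side$label, x$genome_side$label, x$breakpoint_host,
    x$breakpoint_consensus, x$spacer_len, x$confidence))
  invisible(x)
}

#' Default pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()]. Unknown names in `...` are rejected.
#'
#' @param anchor_primer enrichment primer sequence
#' @param direction `"down"` or `"up"`
#' @param host_genome host genome string
#' @param element_db element database
#' @param known_event_refs character vector of known event (CaF)
#'   sequences; empty for none
#' @param vector_refs optional named vector/plasmid references
#' @param ... overrides for the documented defaults: `qc_min_len`,
#'   `qc_max_len`, `qc_min_mean_quality`, `primer_max_mismatches`,
#'   `primer_window_len`, `ke_min_identity`, `ke_coverage`,
#'   `el_min_identity`, `el_coverage`, `cluster_min_identity`,
#'   `cluster_min_overlap`, `min_cluster_size`, `annotate_min_identity`,
#'   `annotate_min_length`, `junction_min_anchor_len`,
#'   `junction_min_anchor_identity`, `junction_max_spacer`
#' @return a named list of class `pipeline_config`
#' @export
pipeline_config <- function(anchor_primer, direction, host_genome,
                            element_db = gm_element_db(),
                            known_event_refs = character(0),
                            vector_refs = NULL, ...) {
  cfg <- list(
    anchor_primer = anchor_primer, direction = direction,
    host_genome = host_genome, element_db = element_db,
    known_event_refs = known_event_refs, vector_refs = vector_refs,
    qc_min_len = 200L, qc_max_len = 8000L, qc_min_mean_quality = 7,
    primer_max_mismatches = 2L, primer_window_len = 150L,
    ke_min_identity = 0.75, ke_coverage = 0.8,
    el_min_identity = 0.75, el_coverage = 0.95,
    cluster_min_identity = 0.75, cluster_min_overlap = 150L,
    min_cluster_size = 6L,
    annotate_min_identity = 0.75, annotate_min_length = 50L,
    junction_min_anchor_len = 100L, junction_min_anchor_identity = 0.8,
    junction_max_spacer = 2000L)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0)
    stop("unknown pipeline configuration keys: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  problems <- character(0)
  if (is.null(cfg$anchor_primer) || !is.character(cfg$anchor_primer) ||
      nchar(cfg$anchor_primer) < 15)
    problems <- c(problems, "anchor_primer must be a string of >= 15 nt")
  if (!cfg$direction %in% c("down", "up"))
    problems <- c(problems, "direction must be 'down' or 'up'")
  if (is.null(cfg$host_genome) || !nzchar(cfg$host_genome))
    problems <- c(problems, "host_genome must be a non-empty string")
  if (cfg$qc_min_len > cfg$qc_max_len)
    problems <- c(problems, "qc_min_len must not exceed qc_max_len")
  for (p in c("ke_min_identity", "ke_coverage", "el_min_identity",
              "el_coverage", "cluster_min_identity",
              "annotate_min_identity", "junction_min_anchor_identity")) {
    if (cfg[[p]] <= 0 || cfg[[p]] > 1)
      problems <- c(problems, paste0(p, " must be in (0, 1]"))
  }
  if (length(problems) > 0)
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(cfg, class = "pipeline_config")
}

#' Run the full read-selection and junction-calling pipeline
#'
#' Executes, in order: quality control, primer selection, known-event
#' subtraction, element-coverage subtraction, clustering, consensus
#' building, annotation, and junction calling. Every stage logs conserved
#' read counts. An empty input produces an empty report without error.
#'
#' @param rs a `read_set`
#' @param config a [pipeline_config()]
#' @return a `pipeline_report`: `filter_reports` (stage count table),
#'   `clusters`, `consensuses`, `annotations`, `junctions`
#' @export
run_pipeline <- function(rs, config) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be built with pipeline_config()")
  reports <- list()

  st <- qc_filter(rs, config$qc_min_len, config$qc_max_len,
                  config$qc_min_mean_quality)
  reports$qc <- st$report
  st <- primer_select(st$reads, config$anchor_primer, config$direction,
                      config$primer_max_mismatches, config$primer_window_len)
  reports$primer <- st$report
  st <- subtract_known_event(st$reads, config$known_event_refs,
                             config$ke_min_identity, config$ke_coverage)
  reports$known_event <- st$report
  st <- subtract_element_covered(st$reads, config$element_db,
                                 config$el_min_identity, config$el_coverage)
  reports$element <- st$report
  reads <- st$reads

  clusters <- cluster_reads(reads, config$cluster_min_identity,
                            config$cluster_min_overlap,
                            config$min_cluster_size)
  consensuses <- lapply(clusters, build_consensus, rs = reads)
  annotations <- lapply(consensuses, function(cs)
    annotate_consensus(cs, config$element_db, config$vector_refs,
                       config$host_genome,
                       min_identity = config$annotate_min_identity,
                       min_length = config$annotate_min_length))
  junctions <- list()
  for (i in seq_along(annotations)) {
    jc <- call_junction(annotations[[i]],
                        config$junction_min_anchor_len,
                        config$junction_min_anchor_identity,
                        config$junction_max_spacer,
                        consensus_id = consensuses[[i]]$cluster_id)
    if (!is.null(jc)) junctions[[length(junctions) + 1L]] <- jc
  }
  structure(list(filter_reports = do.call(rbind, unname(reports)),
                 clusters = clusters, consensuses = consensuses,
                 annotations = annotations, junctions = junctions,
                 config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$filter_reports[, c("stage", "input", "kept", "removed")],
        row.names = FALSE)
  cat(length(x$clusters), "retained cluster(s),",
      length(x$junctions), "junction call(s)\n")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits a stage-count TSV (one row per cascade stage), consensus FASTA,
#' and a JSON junction report. Coordinates in the JSON report are 1-based
#' inclusive, as stated in its header field.
#'
#' @param report a `pipeline_report`
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stage_path <- file.path(dir, "stage_counts.tsv")
  utils::write.table(report$filter_reports, stage_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fasta_path <- file.path(dir, "consensus.fasta")
  if (length(report$consensuses) > 0) {
    seqs <- vapply(report$consensuses, `[[`, "", "sequence")
    names(seqs) <- vapply(report$consensuses, `[[`, "", "cluster_id")
    write_fasta(seqs, fasta_path)
  } else write_fasta(character(0), fasta_path)
  json_path <- file.path(dir, "junctions.json")
  jx <- lapply(report$junctions, function(j) list(
    consensus_id = j$consensus_id,
    construct_label = j$construct_side$label,
    genome_label = j$genome_side$label,
    breakpoint_consensus_1based = j$breakpoint_consensus + 1L,
    breakpoint_host_1based = j$breakpoint_host + 1L,
    spacer_len = j$spacer_len,
    confidence = j$confidence))
  jsonlite::write_json(
    list(coordinate_system = "1-based inclusive", junctions = jx),
    json_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(stage_path, fasta_path, json_path))
}
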