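# In-silico verification of event-specific real-time PCR assays:
# primer-site finding, amplicon prediction, probe containment, and
# cross-event specificity matrices.

#' Define a primer/probe set
#'
#' @param name assay name
#' @param forward,reverse primer sequences (>= 15 nt)
#' @param probe hydrolysis probe sequence (non-empty)
#' @param declared_length declared amplicon length in bp (metadata)
#' @return a `primer_set`
#' @export
primer_set <- function(name, forward, reverse, probe,
                       declared_length = NA_integer_) {
  stopifnot(nchar(forward) >= 15, nchar(reverse) >= 15, nchar(probe) > 0)
  structure(list(name = name, forward = toupper(forward),
                 reverse = toupper(reverse), probe = toupper(probe),
                 declared_length = as.integer(declared_length)),
            class = "primer_set")
}

#' @export
print.primer_set <- function(x, ...) {
  cat(sprintf("<primer_set> %s: F %d nt, R %d nt, P %d nt, amplicon %s bp\n",
              x$name, nchar(x$forward), nchar(x$reverse), nchar(x$probe),
              ifelse(is.na(x$declared_length), "?", x$declared_length)))
  invisible(x)
}

#' Load primer sets from a TSV file
#'
#' Expects columns `name`, `forward`, `reverse`, `probe`,
#' `declared_length`.
#'
#' @param path TSV path
#' @return named list of [primer_set()] objects
#' @export
load_primer_sets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "forward", "reverse", "probe", "declared_length")
  if (!all(needed %in% names(tab)))
    stop("primer TSV must have columns: ", paste(needed, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i)
    primer_set(tab$name[i], tab$forward[i], tab$reverse[i], tab$probe[i],
               tab$declared_length[i]))
  names(out) <- tab$name
  out
}

#' Bundled event-specific petunia assays
#'
#' The published G1 and G2 event-specific primer/probe sets (fluorophore
#' and quencher labels stripped), loaded from the packaged TSV.
#'
#' @return named list of two [primer_set()] objects (`PxhG1`, `PxhG2`)
#' @export
petunia_assays <- function() {
  load_primer_sets(system.file("extdata", "event_assays.tsv",
                               package = "alfpipe", mustWork = TRUE))
}

#' Find primer binding sites on a template
#'
#' Substitution-only matching on both strands. A site is rejected when
#' any mismatch falls within the 3'-terminal `require_3prime_exact` bases
#' of the primer, where polymerase extension is most mismatch-sensitive.
#'
#' @param template template nucleotide string
#' @param primer primer sequence (>= 15 nt)
#' @param max_mismatches substitution budget over the whole primer
#' @param require_3prime_exact number of 3'-terminal primer bases that
#'   must match exactly
#' @return data.frame of `position` (0-based start of the site on the
#'   template plus strand), `strand`, `mismatches`
#' @export
find_primer_sites <- function(template, primer, max_mismatches = 2L,
                              require_3prime_exact = 3L) {
  stopifnot(nchar(primer) >= 15)
  primer <- toupper(primer)
  p <- nchar(primer)
  e <- as.integer(require_3prime_exact)
  empty <- data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (p > nchar(template)) return(empty)
  rows <- list()
  # plus strand: primer 3' end is the right end of the site
  fwd <- .hamming_scan_cpp(primer, template, as.integer(max_mismatches))
  if (nrow(fwd) > 0 && e > 0) {
    tail_p <- substr(primer, p - e + 1L, p)
    ok <- vapply(fwd[, 1], function(s)
      substr(template, s + p - e + 1L, s + p) == tail_p, TRUE)
    fwd <- fwd[ok, , drop = FALSE]
  }
  if (nrow(fwd) > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      position = fwd[, 1], strand = "+", mismatches = fwd[, 2],
      stringsAsFactors = FALSE)
  # minus strand: the site is revcomp(primer) on the plus text; the
  # primer's 3' end maps to the site's left end
  prc <- revcomp(primer)
  rev <- .hamming_scan_cpp(prc, template, as.integer(max_mismatches))
  if (nrow(rev) > 0 && e > 0) {
    head_p <- substr(prc, 1L, e)
    ok <- vapply(rev[, 1], function(s)
      substr(template, s + 1L, s + e) == head_p, TRUE)
    rev <- rev[ok, , drop = FALSE]
  }
  if (nrow(rev) > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      position = rev[, 1], strand = "-", mismatches = rev[, 2],
      stringsAsFactors = FALSE)
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Predict amplicons of a primer set on a template
#'
#' One prediction per convergent forward/reverse site pair (forward on
#' one strand, reverse on the other, 3' ends facing each other) with
#' amplicon length at most `max_amplicon_len`. `probe_bound` is true when
#' the probe matches inside the amplicon on either strand within its
#' mismatch budget.
#'
#' @param template template nucleotide string
#' @param ps a [primer_set()]
#' @param max_amplicon_len longest reported amplicon (nt)
#' @param max_mismatches primer substitution budget
#' @param probe_max_mismatches probe substitution budget
#' @param require_3prime_exact 3'-exactness window for primers
#' @param template_id optional template label
#' @return data.frame of predictions: `template_id`, `start`, `end`
#'   (0-based half-open), `length`, `sequence`, `strand` (strand carrying
#'   the forward primer), `fwd_mismatches`, `rev_mismatches`,
#'   `probe_bound`
#' @export
predict_amplicons <- function(template, ps, max_amplicon_len = 3000L,
                              max_mismatches = 2L,
                              probe_max_mismatches = 2L,
                              require_3prime_exact = 3L,
                              template_id = NA_character_) {
  stopifnot(inherits(ps, "primer_set"))
  empty <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      sequence = character(0), strand = character(0),
                      fwd_mismatches = integer(0),
                      rev_mismatches = integer(0),
                      probe_bound = logical(0), stringsAsFactors = FALSE)
  f_sites <- find_primer_sites(template, ps$forward, max_mismatches,
                               require_3prime_exact)
  r_sites <- find_primer_sites(template, ps$reverse, max_mismatches,
                               require_3prime_exact)
  if (nrow(f_sites) == 0 || nrow(r_sites) == 0) return(empty)
  lf <- nchar(ps$forward); lr <- nchar(ps$reverse)
  rows <- list()
  add_pair <- function(left_pos, left_len, right_pos, right_len,
                       strand, fmm, rmm) {
    start <- left_pos
    end <- right_pos + right_len
    len <- end - start
    if (len < max(lf, lr) || len > max_amplicon_len) return()
    seq <- substr(template, start + 1L, end)
    probe_hits <- if (nchar(ps$probe) <= nchar(seq))
      match_with_mismatches(ps$probe, seq, probe_max_mismatches)
      else data.frame()
    rows[[length(rows) + 1L]] <<- data.frame(
      template_id = template_id, start = start, end = end, length = len,
      sequence = seq, strand = strand, fwd_mismatches = fmm,
      rev_mismatches = rmm, probe_bound = nrow(probe_hits) > 0,
      stringsAsFactors = FALSE)
  }
  # forward on "+", reverse on "-": amplicon plus strand starts with F
  for (i in which(f_sites$strand == "+")) {
    for (j in which(r_sites$strand == "-")) {
      if (r_sites$position[j] >= f_sites$position[i])
        add_pair(f_sites$position[i], lf, r_sites$position[j], lr, "+",
                 f_sites$mismatches[i], r_sites$mismatches[j])
    }
  }
  # reverse on "+", forward on "-": the forward primer sits on the minus
  # strand; the plus-strand amplicon starts with R
  for (j in which(r_sites$strand == "+")) {
    for (i in which(f_sites$strand == "-")) {
      if (f_sites$position[i] >= r_sites$position[j])
        add_pair(r_sites$position[j], lr, f_sites$position[i], lf, "-",
                 f_sites$mismatches[i], r_sites$mismatches[j])
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Cross-event assay specificity matrix
#'
#' Runs every assay against every template; a pair is `detected` when at
#' least one predicted amplicon carries the probe.
#'
#' @param assays list of [primer_set()] objects
#' @param templates named character vector (or named list) of template
#'   sequences
#' @param ... passed to [predict_amplicons()]
#' @return logical matrix, assays in rows, templates in columns
#' @export
specificity_matrix <- function(assays, templates, ...) {
  templates <- unlist(templates)
  anames <- vapply(assays, `[[`, "", "name")
  m <- matrix(FALSE, nrow = length(assays), ncol = length(templates),
              dimnames = list(anames, names(templates)))
  for (i in seq_along(assays)) {
    for (j in seq_along(templates)) {
      amp <- predict_amplicons(templates[[j]], assays[[i]],
                               template_id = names(templates)[j], ...)
      m[i, j] <- any(amp$probe_bound)
    }
  }
  m
}

#' Write a specificity matrix as TSV
#'
#' @param m matrix from [specificity_matrix()]
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_specificity_matrix <- function(m, path) {
  tab <- data.frame(assay = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
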