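# Decision support: map a tri-state screening-PCR panel (positive /
# negative / not-tested per target) to a GM-group assignment with an
# explicit rule trace.  The rules themselves live in a bundled JSON file
# so they can be amended without code changes.

.DSS_STATES <- c("positive", "negative", "not_tested")

#' Load the decision rules
#'
#' @param path rules JSON; defaults to the bundled file
#' @return parsed rule list (`targets`, `gm_targets`, `rules`,
#'   `references`)
#' @export
dss_rules <- function(path = system.file("extdata", "dss_rules.json",
                                         package = "alfpipe",
                                         mustWork = TRUE)) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Construct a screening panel result
#'
#' @param sample sample name
#' @param results named character vector or list of per-target states
#'   (`"positive"`, `"negative"`, `"not_tested"`); target names must be
#'   known to the rule set; unlisted targets default to `"not_tested"`
#' @param cq optional named numeric vector of Cq values in (0, 45\] for
#'   positive targets
#' @param flower_color optional free-text metadata
#' @param laboratory optional metadata
#' @param rules rule set from [dss_rules()]
#' @return a `panel_result`
#' @export
panel_result <- function(sample, results, cq = NULL, flower_color = NA,
                         laboratory = NA, rules = dss_rules()) {
  targets <- unlist(rules$targets)
  results <- unlist(results)
  unknown <- setdiff(names(results), targets)
  if (length(unknown) > 0)
    stop("unknown panel target(s): ", paste(unknown, collapse = ", "))
  bad <- results[!results %in% .DSS_STATES]
  if (length(bad) > 0)
    stop("invalid result state(s): ", paste(unique(bad), collapse = ", "))
  status <- stats::setNames(rep("not_tested", length(targets)), targets)
  status[names(results)] <- results
  cqv <- stats::setNames(rep(NA_real_, length(targets)), targets)
  if (!is.null(cq)) {
    cq <- unlist(cq)
    unknown <- setdiff(names(cq), targets)
    if (length(unknown) > 0)
      stop("Cq given for unknown target(s): ",
           paste(unknown, collapse = ", "))
    if (any(!is.na(cq) & (cq <= 0 | cq > 45)))
      stop("Cq values must lie in (0, 45]")
    cqv[names(cq)] <- cq
  }
  structure(list(sample = sample, status = status, cq = cqv,
                 flower_color = flower_color, laboratory = laboratory),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  pos <- names(x$status)[x$status == "positive"]
  cat(sprintf("<panel_result> %s: positive for {%s}\n", x$sample,
              paste(pos, collapse = ", ")))
  invisible(x)
}

.check_condition <- function(cond, status, rules) {
  if (!is.null(cond$group)) {
    grp <- unlist(rules[[cond$group]])
    if (cond$is == "all_negative_ignoring_not_tested") {
      tested <- status[grp][status[grp] != "not_tested"]
      return(all(tested == "negative"))
    }
    stop("unknown group condition: ", cond$is)
  }
  s <- status[[cond$target]]
  switch(cond$is,
         positive = s == "positive",
         negative = s == "negative",
         not_positive = s != "positive",
         not_tested = s == "not_tested",
         stop("unknown condition type: ", cond$is))
}

#' Classify a screening panel
#'
#' Evaluates the decision rules in order and assigns the label of the
#' first rule whose conditions all hold; the trace of every evaluated
#' rule (fired or not) is returned as the rationale. The classifier is
#' total: the final fallback rule has no conditions, so exactly one
#' label is always produced. An `invalid` label is assigned exactly when
#' the endogenous control (actin) is negative.
#'
#' @param panel a [panel_result()]
#' @param rules rule set from [dss_rules()]
#' @return a `classification`: `label`, `rule_id`, `rationale`,
#'   `references` (citation keys), `trace` data.frame
#' @export
classify_panel <- function(panel, rules = dss_rules()) {
  stopifnot(inherits(panel, "panel_result"))
  trace <- list()
  fired <- NULL
  for (rule in rules$rules) {
    ok <- all(vapply(rule$when, .check_condition, TRUE,
                     status = panel$status, rules = rules))
    trace[[length(trace) + 1L]] <- data.frame(
      rule_id = rule$id, label = rule$label, fired = ok,
      stringsAsFactors = FALSE)
    if (ok) { fired <- rule; break }
  }
  structure(list(sample = panel$sample, label = fired$label,
                 rule_id = fired$id,
                 rationale = fired$rationale,
                 references = unlist(fired$references),
                 trace = do.call(rbind, trace)),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> %s -> %s (rule %s)\n", x$sample, x$label,
              x$rule_id))
  invisible(x)
}

#' Render a classification as a human-readable report
#'
#' Includes the fired rule's rationale and the literature keys attached
#' to the assigned construct origin; an invalid panel is reported as a
#' control failure with no origin claim.
#'
#' @param classification a `classification`
#' @param rules rule set from [dss_rules()] (for reference descriptions)
#' @return character scalar report
#' @export
explain <- function(classification, rules = dss_rules()) {
  stopifnot(inherits(classification, "classification"))
  lines <- c(sprintf("Sample: %s", classification$sample),
             sprintf("Assignment: %s", classification$label),
             sprintf("Rationale: %s", classification$rationale))
  refs <- classification$references
  if (length(refs) > 0) {
    descr <- vapply(refs, function(k) {
      d <- rules$references[[k]]
      if (is.null(d)) "" else d
    }, "")
    lines <- c(lines, "References:",
               sprintf("  [%s] %s", refs, descr))
  }
  paste(lines, collapse = "\n")
}

.parse_panel_cell <- function(x, line_no, target) {
  x <- trimws(x)
  if (x %in% c("-", "–", "−")) return(list(status = "negative", cq = NA_real_))
  if (x == "+") return(list(status = "positive", cq = NA_real_))
  if (x %in% c("n.d.", "nd", "NA", "")) return(list(status = "not_tested", cq = NA_real_))
  val <- suppressWarnings(as.numeric(x))
  if (is.na(val))
    stop("line ", line_no, ", target ", target,
         ": unrecognized result symbol `", x, "`")
  if (val <= 0 || val > 45)
    stop("line ", line_no, ", target ", target, ": Cq ", val,
         " outside (0, 45]")
  list(status = "positive", cq = val)
}

#' Load a screening panel table
#'
#' Reads a TSV in the screening-table dialect: metadata columns
#' `laboratory`, `sample`, `flower_color`, then one column per target
#' with `+` (positive), `-` (negative), `n.d.` (not tested, which is
#' never treated as negative) or a numeric Cq (positive with that Cq).
#'
#' @param path TSV path
#' @param rules rule set from [dss_rules()]
#' @return list of [panel_result()] objects
#' @export
load_panel_table <- function(path, rules = dss_rules()) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  meta <- intersect(c("laboratory", "sample", "flower_color"), names(tab))
  if (!"sample" %in% meta) stop("panel table needs a `sample` column")
  target_cols <- setdiff(names(tab), meta)
  unknown <- setdiff(target_cols, unlist(rules$targets))
  if (length(unknown) > 0)
    stop("unknown target column(s): ", paste(unknown, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    st <- character(0); cq <- numeric(0)
    for (tc in target_cols) {
      cell <- .parse_panel_cell(tab[[tc]][i], i + 1L, tc)
      st[tc] <- cell$status
      if (!is.na(cell$cq)) cq[tc] <- cell$cq
    }
    panel_result(tab$sample[i], st, cq = if (length(cq)) cq else NULL,
                 flower_color = if ("flower_color" %in% meta)
                   tab$flower_color[i] else NA,
                 laboratory = if ("laboratory" %in% meta)
                   tab$laboratory[i] else NA,
                 rules = rules)
  })
}

#' Bundled screening panel table
#'
#' The interlaboratory screening results for petunia market samples as a
#' machine-readable fixture.
#'
#' @return list of [panel_result()] objects
#' @export
petunia_panel_table <- function() {
  load_panel_table(system.file("extdata", "screening_panel.tsv",
                               package = "alfpipe", mustWork = TRUE))
}

#' Classify every panel in a table
#'
#' @param panels list of [panel_result()] objects
#' @param rules rule set from [dss_rules()]
#' @return data.frame: `sample`, `laboratory`, `flower_color`, `label`,
#'   `rule_id`
#' @export
classify_panel_table <- function(panels, rules = dss_rules()) {
  rows <- lapply(panels, function(p) {
    cl <- classify_panel(p, rules)
    data.frame(sample = p$sample,
               laboratory = as.character(p$laboratory),
               flower_color = as.character(p$flower_color),
               label = cl$label, rule_id = cl$rule_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
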