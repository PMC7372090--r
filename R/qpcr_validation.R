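# Real-time PCR validation arithmetic: genome copies from DNA mass,
# calibration-curve fitting, amplification efficiency, LOD, and a
# stochastic replicate simulator standing in for wet-lab runs.

#' Genome copies from DNA mass
#'
#' Converts a DNA mass per reaction into haploid genome copy number using
#' the 1C value (mass of one haploid genome copy):
#' `round(mass_ng * 1000 / c_value_pg)`.
#'
#' @param mass_ng DNA mass per reaction in ng (> 0)
#' @param c_value_pg 1C genome weight in pg (> 0); 1.43 pg for petunia
#' @return integer copy number (vectorized over `mass_ng`)
#' @export
copies_from_mass <- function(mass_ng, c_value_pg = 1.43) {
  if (any(mass_ng <= 0) || c_value_pg <= 0)
    stop("mass and 1C value must both be positive")
  as.integer(round(mass_ng * 1000 / c_value_pg))
}

#' Bundled petunia calibration dilution series
#'
#' The five-point DNA dilution series used for efficiency evaluation
#' (mass per reaction in ng) together with the copy numbers as printed
#' and the copies recomputed from the 1.43 pg 1C value. The printed and
#' recomputed series differ slightly for the upper points (the printed
#' values imply a 1C of about 1.42 pg); only the 20-copy point is
#' invariant to this. Both are kept; computations use the recomputed
#' column.
#'
#' @return data.frame with `mass_ng`, `copies_printed`,
#'   `copies_recomputed`
#' @export
petunia_calibration_series <- function() {
  mass <- c(150, 17.7, 2.08, 0.24, 0.029)
  data.frame(mass_ng = mass,
             copies_printed = c(105634L, 12428L, 1462L, 172L, 20L),
             copies_recomputed = copies_from_mass(mass, 1.43))
}

#' Amplification efficiency from a calibration slope
#'
#' `E = (10^(-1/slope) - 1) * 100` percent; a slope of -3.3219 (a 10-fold
#' dilution spanning log2(10) cycles) corresponds to 100% efficiency.
#'
#' @param slope slope of mean Cq versus log10(copies); must be negative
#' @return efficiency in percent
#' @export
efficiency_from_slope <- function(slope) {
  if (any(slope >= 0)) stop("calibration slope must be negative")
  (10^(-1 / slope) - 1) * 100
}

#' Fit a qPCR calibration curve
#'
#' Least-squares line of mean Cq versus log10(copies), with R^2 computed
#' on the replicate means (replicates are averaged per level first, as
#' when samples are run in duplicate); set `r2_on = "replicates"` to use
#' every replicate instead.
#'
#' @param points data.frame with columns `copies` (> 0) and `cq`;
#'   multiple rows per copy level are replicates
#' @param r2_on `"means"` (default) or `"replicates"`
#' @return a `calibration_curve`: `slope`, `intercept`, `r_squared`,
#'   `efficiency_percent`, and the per-level means
#' @export
fit_calibration <- function(points, r2_on = c("means", "replicates")) {
  r2_on <- match.arg(r2_on)
  stopifnot(is.data.frame(points), all(c("copies", "cq") %in% names(points)),
            all(points$copies > 0))
  points <- points[!is.na(points$cq), , drop = FALSE]
  levels_ <- sort(unique(points$copies), decreasing = TRUE)
  if (length(levels_) < 3)
    stop("calibration needs at least 3 distinct copy levels (got ",
         length(levels_), ")")
  means <- vapply(levels_, function(cp)
    mean(points$cq[points$copies == cp]), 0)
  fit <- stats::lm(means ~ log10(levels_))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2_of <- function(y, yhat) {
    sst <- sum((y - mean(y))^2)
    if (sst <= 0) return(1)
    max(0, min(1, 1 - sum((y - yhat)^2) / sst))
  }
  r2 <- if (r2_on == "means") r2_of(means, stats::fitted(fit)) else {
    full <- stats::lm(cq ~ log10(copies), data = points)
    r2_of(points$cq, stats::fitted(full))
  }
  structure(list(points = data.frame(copies = levels_, mean_cq = means),
                 slope = slope, intercept = intercept, r_squared = r2,
                 efficiency_percent = efficiency_from_slope(slope)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> slope %.4f, intercept %.2f, R2 %.4f, efficiency %.1f%%\n",
    x$slope, x$intercept, x$r_squared, x$efficiency_percent))
  invisible(x)
}

#' Simulate replicate qPCR reactions
#'
#' Per replicate, the delivered template count is Poisson with mean
#' `true_copies` (pipetting a dilute template is a Poisson draw); zero
#' templates give no detection. Otherwise
#' `Cq = cq_intercept - log(n) / log(1 + efficiency) + N(0, noise_sd)`,
#' censored to no-detection beyond `max_cycles` (runs use 45 cycles).
#'
#' @param true_copies mean template copies per reaction
#' @param amplification_efficiency per-cycle efficiency in (0.5, 1\];
#'   1 doubles the template every cycle
#' @param cq_intercept Cq of a single template copy
#' @param noise_sd Gaussian Cq noise (cycles)
#' @param n_replicates number of reactions
#' @param max_cycles cycle cutoff
#' @param seed integer seed; fixed seed gives an identical vector
#' @param poisson use Poisson template delivery (default); `FALSE` fixes
#'   the template count at `round(true_copies)` in every replicate, for
#'   noise-free calibration work
#' @return numeric vector of length `n_replicates`; `NA` = no detection
#' @export
simulate_qpcr_replicates <- function(true_copies,
                                     amplification_efficiency = 1.0,
                                     cq_intercept = 37.0,
                                     noise_sd = 0.15,
                                     n_replicates = 10L,
                                     max_cycles = 45L, seed = 1L,
                                     poisson = TRUE) {
  stopifnot(amplification_efficiency > 0.5,
            amplification_efficiency <= 1.2,
            true_copies >= 0, n_replicates >= 1)
  .with_seed(seed, {
    n <- if (poisson) stats::rpois(n_replicates, true_copies)
         else rep(round(true_copies), n_replicates)
    cq <- rep(NA_real_, n_replicates)
    pos <- n > 0
    if (any(pos)) {
      cq[pos] <- cq_intercept -
        log(n[pos]) / log(1 + amplification_efficiency) +
        stats::rnorm(sum(pos), 0, noise_sd)
      cq[pos][cq[pos] > max_cycles] <- NA_real_
    }
    cq
  })
}

#' Build a detection table
#'
#' @param copies copy levels, strictly decreasing
#' @param positives detected replicates per level
#' @param total total replicates per level (recycled)
#' @return a `detection_table` data.frame
#' @export
detection_table <- function(copies, positives, total = 10L) {
  total <- rep_len(total, length(copies))
  stopifnot(length(positives) == length(copies),
            all(positives >= 0), all(positives <= total),
            all(diff(copies) < 0))
  structure(data.frame(copies = copies, positives = as.integer(positives),
                       total = as.integer(total)),
            class = c("detection_table", "data.frame"))
}

#' Limit of detection from a replicate detection table
#'
#' The LOD is the lowest copy number detected positively in all
#' replicate reactions, provided every higher level is also all-positive.
#' If even the highest level fails, the LOD is not reached within the
#' tested range. A warning flag is raised when a lower level is
#' all-positive while an intermediate one is not (non-monotone table),
#' and when every level is all-positive (the true LOD may lie below the
#' tested range).
#'
#' @param table a [detection_table()] (or data.frame with `copies`,
#'   `positives`, `total`), copies strictly decreasing
#' @return list: `lod` (copies, or `NA` for "not reached"), `reached`,
#'   `warning` (character, `""` when none)
#' @export
lod_from_table <- function(table) {
  stopifnot(nrow(table) > 0, all(diff(table$copies) < 0))
  allpos <- table$positives == table$total
  warning_msg <- ""
  if (!allpos[1]) {
    return(list(lod = NA_real_, reached = FALSE,
                warning = "highest tested level not all-positive; LOD not reached"))
  }
  run_end <- which(!allpos)[1] # first failing level, NA if none
  if (is.na(run_end)) {
    lod <- table$copies[nrow(table)]
    warning_msg <- "all levels all-positive; LOD may be below tested range"
  } else {
    lod <- table$copies[run_end - 1L]
    if (any(allpos[run_end:nrow(table)]))
      warning_msg <- "non-monotone detection: a lower level is all-positive below a failing level"
  }
  list(lod = lod, reached = TRUE, warning = warning_msg)
}

#' Validate an assay against acceptance criteria
#'
#' Checks the calibration curve's amplification efficiency and R^2
#' against configurable acceptance windows and reports the LOD; the
#' overall verdict passes only if every criterion passes.
#'
#' @param curve a `calibration_curve`
#' @param det_table a [detection_table()], or `NULL` to skip the LOD
#' @param criteria list with `efficiency` (percent window, default
#'   `c(90, 110)`) and `r_squared_min` (default 0.98)
#' @return a `validation_report`: per-criterion booleans, LOD, overall
#'   verdict, and the criteria used
#' @export
validate_assay <- function(curve, det_table = NULL,
                           criteria = list(efficiency = c(90, 110),
                                           r_squared_min = 0.98)) {
  stopifnot(inherits(curve, "calibration_curve"))
  eff_ok <- curve$efficiency_percent >= criteria$efficiency[1] &&
    curve$efficiency_percent <= criteria$efficiency[2]
  r2_ok <- curve$r_squared >= criteria$r_squared_min
  checks <- list(
    efficiency = list(pass = eff_ok,
                      value = curve$efficiency_percent,
                      window = criteria$efficiency),
    r_squared = list(pass = r2_ok, value = curve$r_squared,
                     minimum = criteria$r_squared_min))
  lod <- if (!is.null(det_table)) lod_from_table(det_table) else NULL
  structure(list(curve = curve, checks = checks, lod = lod,
                 criteria = criteria,
                 pass = eff_ok && r2_ok),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  efficiency %.1f%% in [%g, %g]: %s\n",
              x$checks$efficiency$value, x$checks$efficiency$window[1],
              x$checks$efficiency$window[2],
              ifelse(x$checks$efficiency$pass, "pass", "fail")))
  cat(sprintf("  R2 %.4f >= %g: %s\n", x$checks$r_squared$value,
              x$checks$r_squared$minimum,
              ifelse(x$checks$r_squared$pass, "pass", "fail")))
  if (!is.null(x$lod))
    cat(sprintf("  LOD: %s copies%s\n",
                ifelse(x$lod$reached, format(x$lod$lod), "not reached"),
                ifelse(nzchar(x$lod$warning),
                       paste0(" (", x$lod$warning, ")"), "")))
  invisible(x)
}
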