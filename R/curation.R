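#' Concordance between two copy-number profiles
#'
#' Length-weighted fraction of the non-blacklisted genome on which two
#' callers assign the same integer state. Symmetric in its arguments.
#'
#' @param a,b [cn_profile]s on the same [bin_grid], states assigned.
#' @return Fraction in \[0, 1\].
#' @export
concordance <- function(a, b) {
  stopifnot(inherits(a, "cn_profile"), inherits(b, "cn_profile"))
  if (!same_grid(a$grid, b$grid)) stopf("profiles are on different bin grids")
  keep <- !is.na(a$states) & !is.na(b$states)
  w <- bin_widths(a$grid)[keep]
  sum(w * (a$states[keep] == b$states[keep])) / sum(w)
}

#' Minimum mean reads per bin for a copy-number state
#'
#' The curation rule of at least 10 reads per chromosome copy of each bin:
#' a bin called s-somy requires on average `10 * s` reads (2-somy: 20 reads,
#' 3-somy: 30 reads, ...).
#'
#' @param state Copy-number state (>= 0).
#' @param min_per_copy Reads required per chromosome copy (default 10).
#' @return Minimum mean reads per bin.
#' @export
per_bin_read_threshold <- function(state, min_per_copy = 10) {
  if (any(state < 0)) stopf("state must be >= 0")
  min_per_copy * state
}

#' Minimum total reads for a library of given ploidy
#'
#' Summing the per-bin minimum of [per_bin_read_threshold] over all bins:
#' `10 * ploidy * n_bins` reads. On a ~3,000-bin 1-Mb tiling this is 60,000
#' reads for a diploid G1 library (2n) and 240,000 for a polyploid G2/M
#' library (8n).
#'
#' @param ploidy Chromosome copies per bin (>= 1).
#' @param n_bins Number of bins (>= 1).
#' @param min_per_copy Reads required per chromosome copy (default 10).
#' @return Total read minimum.
#' @export
min_required_reads <- function(ploidy, n_bins, min_per_copy = 10) {
  assert_count(ploidy, "ploidy", min = 1L)
  assert_count(n_bins, "n_bins", min = 1L)
  min_per_copy * ploidy * n_bins
}

#' Read-depth curation filter
#'
#' A library passes when the mean over non-blacklisted bins of
#' `count / state` is at least `min_per_copy` reads per chromosome copy
#' (boundary inclusive: exactly 10 passes). Bins with state 0 are excluded
#' from the mean.
#'
#' @param library A `cell_library`.
#' @param profile A [cn_profile] on the library's grid with assigned states.
#' @param min_per_copy Reads required per chromosome copy (default 10).
#' @return List with `pass` (logical) and `mean_reads_per_copy` (observed).
#' @export
read_depth_filter <- function(library, profile, min_per_copy = 10) {
  stopifnot(length(library$counts) == nrow(profile$grid))
  keep <- !is.na(profile$states) & profile$states > 0
  if (!any(keep)) stopf("degenerate input: no bins with state > 0")
  obs <- mean(library$counts[keep] / profile$states[keep])
  list(pass = obs >= min_per_copy, mean_reads_per_copy = obs)
}

#' Non-rounded copy number of a called state
#'
#' Continuous re-estimate of a called state used for artifact QC:
#' `mean_state / (mean_expected / cn_expected)`. For a 5-somy call in a 4n
#' sample this is `Mean.5-somy / (Mean.4-somy / 4)`; a value of 4.6 reveals
#' that the "5-somy" bins actually sit 0.4 copies below a true 5-somy.
#'
#' @param mean_state Mean corrected count over bins called the state.
#' @param mean_expected Mean corrected count over bins at the expected state
#'   (> 0).
#' @param cn_expected The expected state (library ploidy, >= 1).
#' @return Real-valued copy number.
#' @export
non_rounded_copy_number <- function(mean_state, mean_expected, cn_expected) {
  if (any(mean_expected <= 0)) stopf("mean_expected must be > 0")
  if (any(cn_expected < 1)) stopf("cn_expected must be >= 1")
  mean_state / (mean_expected / cn_expected)
}

#' Per-state statistics of a profile
#'
#' For each called state: mean corrected count over its bins, number of
#' bins, and length-weighted genome fraction. Carries the expected state
#' (the profile's ground ploidy) and its mean for the wavy-pattern filter.
#'
#' @param profile A [cn_profile] with assigned states.
#' @param corrected Per-bin corrected counts the profile was called on.
#' @return A `state_statistics` object: list with `table` (data frame:
#'   `state`, `mean`, `n_bins`, `fraction`), `expected_state`,
#'   `mean_expected`.
#' @export
state_statistics <- function(profile, corrected) {
  stopifnot(inherits(profile, "cn_profile"),
            length(corrected) == nrow(profile$grid))
  keep <- !is.na(profile$states)
  st <- profile$states[keep]
  x <- corrected[keep]
  w <- bin_widths(profile$grid)[keep]
  states <- sort(unique(st))
  tab <- data.frame(
    state = states,
    mean = vapply(states, function(s) mean(x[st == s]), 0),
    n_bins = vapply(states, function(s) sum(st == s), 0L),
    fraction = vapply(states, function(s) sum(w[st == s]) / sum(w), 0)
  )
  expected <- profile$ploidy
  if (!expected %in% states)
    stopf("expected state %g not present in profile", expected)
  mean_expected <- tab$mean[tab$state == expected]
  if (mean_expected <= 0) stopf("expected state has non-positive mean")
  structure(list(table = tab, expected_state = expected,
                 mean_expected = mean_expected), class = "state_statistics")
}

#' Wavy-pattern artifact filter
#'
#' Smooth coverage waves produce spurious segments one copy above or below
#' the expected state whose mean counts sit too close to the expected
#' state's mean. For every state other than the expected one occupying more
#' than `genome_fraction_trigger` of the genome, the non-rounded copy number
#' is computed; the library fails when any evaluated state deviates from its
#' integer value by more than `max_deviation` copies (for 5-somy: a value
#' lower than 4.75 or higher than 5.25 at the default 0.25). Boundaries are
#' read literally: exactly 1% genome fraction does not trigger evaluation
#' and a deviation of exactly 0.25 passes.
#'
#' @param stats A [state_statistics] object.
#' @param genome_fraction_trigger Evaluation trigger (default 0.01).
#' @param max_deviation Maximum tolerated deviation in copies (default
#'   0.25).
#' @return List with `evaluations` (data frame: `state`, `fraction`,
#'   `non_rounded`, `pass`) and `pass` (overall; TRUE when nothing was
#'   evaluated).
#' @export
wavy_pattern_filter <- function(stats, genome_fraction_trigger = 0.01,
                                max_deviation = 0.25) {
  stopifnot(inherits(stats, "state_statistics"))
  tab <- stats$table
  ev <- tab[tab$state != stats$expected_state &
            tab$fraction > genome_fraction_trigger, ]
  if (nrow(ev) == 0) {
    return(list(evaluations = data.frame(state = numeric(0), fraction = numeric(0),
                                         non_rounded = numeric(0), pass = logical(0)),
                pass = TRUE))
  }
  nr <- non_rounded_copy_number(ev$mean, stats$mean_expected, stats$expected_state)
  pass <- abs(nr - ev$state) <= max_deviation
  list(evaluations = data.frame(state = ev$state, fraction = ev$fraction,
                                non_rounded = nr, pass = pass),
       pass = all(pass))
}

#' Curate one library
#'
#' Applies the full library-quality ledger: dual-caller concordance (minimum
#' 0.95 for 2n samples, 0.90 for 4n and 8n samples), the per-copy read-depth
#' minimum, and the wavy-pattern filter. The overall decision is keep iff
#' every applied filter passes; the filters are pure predicates, so the
#' decision does not depend on evaluation order.
#'
#' @param library A `cell_library`.
#' @param profile_a Primary [cn_profile] (changepoint caller; used for the
#'   read-depth and wavy evaluations).
#' @param profile_b Second caller's [cn_profile].
#' @param condition List with `class` (`"2n"`, `"4n"` or `"8n"`) selecting
#'   the concordance threshold, and optionally `wavy_armed` (default TRUE;
#'   set FALSE to restrict the wavy filter to specific sample sets, as a
#'   configuration rather than a code change).
#' @param corrected Optional per-bin corrected counts; recomputed with
#'   [gc_correct] when missing.
#' @param concordance_2n,concordance_poly Concordance thresholds.
#' @param min_per_copy Read-depth minimum per chromosome copy.
#' @param wavy_trigger,wavy_max_dev Wavy-filter parameters, see
#'   [wavy_pattern_filter].
#' @return A `curation_report`: list with `cell_id`, `concordance`,
#'   `concordance_threshold`, `read_depth` (pass + observed), `wavy`
#'   (evaluations + pass), `decision` (`"keep"` or `"discard"`) and
#'   `reasons` (failed filter names).
#' @export
curate_library <- function(library, profile_a, profile_b, condition,
                           corrected = NULL,
                           concordance_2n = 0.95, concordance_poly = 0.90,
                           min_per_copy = 10, wavy_trigger = 0.01,
                           wavy_max_dev = 0.25) {
  if (is.character(condition)) condition <- list(class = condition)
  if (!condition$class %in% c("2n", "4n", "8n"))
    stopf("condition class must be one of '2n', '4n', '8n'")
  wavy_armed <- !identical(condition$wavy_armed, FALSE)
  conc_thr <- if (condition$class == "2n") concordance_2n else concordance_poly
  conc <- concordance(profile_a, profile_b)
  rd <- read_depth_filter(library, profile_a, min_per_copy = min_per_copy)
  if (is.null(corrected)) corrected <- gc_correct(library$counts, profile_a$grid)
  wavy <- if (wavy_armed) {
    wavy_pattern_filter(state_statistics(profile_a, corrected),
                        genome_fraction_trigger = wavy_trigger,
                        max_deviation = wavy_max_dev)
  } else {
    list(evaluations = NULL, pass = TRUE)
  }
  passes <- c(concordance = conc >= conc_thr, read_depth = rd$pass,
              wavy_pattern = wavy$pass)
  structure(list(
    cell_id = library$cell_id,
    condition_class = condition$class,
    concordance = conc,
    concordance_threshold = conc_thr,
    read_depth = rd,
    wavy = wavy,
    decision = if (all(passes)) "keep" else "discard",
    reasons = names(passes)[!passes]
  ), class = "curation_report")
}

#' Summarize curation reports for a cohort
#'
#' @param reports List of `curation_report` objects.
#' @return Data frame, one row per cell: concordance, mean reads per copy
#'   per bin, worst non-rounded deviation (NA when nothing was evaluated)
#'   and decision.
#' @export
cohort_summary <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    dev <- if (!is.null(r$wavy$evaluations) && nrow(r$wavy$evaluations) > 0) {
      max(abs(r$wavy$evaluations$non_rounded - r$wavy$evaluations$state))
    } else NA_real_
    data.frame(cell_id = r$cell_id, condition = r$condition_class,
               concordance = r$concordance,
               mean_reads_per_copy = r$read_depth$mean_reads_per_copy,
               worst_wavy_deviation = dev, decision = r$decision,
               reasons = paste(r$reasons, collapse = ";"))
  }))
}

#' Write a curation report as JSON
#'
#' @param report A `curation_report`.
#' @param path JSON path.
#' @export
write_curation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
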