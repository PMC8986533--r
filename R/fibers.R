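#' Simulate a set of combed DNA fibers
#'
#' Each fiber carries one bidirectionally measured fork labelled by two
#' sequential 30-min analog pulses (CldU first, then IdU) and one or more
#' replication origins. Per-pulse fork speeds are drawn from a normal
#' distribution truncated at zero; with probability `stall_probability` the
#' second-pulse speed is multiplied by a stall factor drawn uniformly in
#' \[0, 0.5\] applied to the fork's own first-pulse speed — a stalled fork
#' travels at most half as far in the second pulse as it did in the first,
#' so every stalled fork has CldU/IdU ratio > 2. Origins on
#' multi-origin fibers are spaced exponentially with mean `iod_mean`. Track
#' lengths are stored in micrometres via the combing stretch factor.
#'
#' @param n_fibers Number of fibers (0 gives an empty set).
#' @param speed_mean,speed_sd Fork speed distribution, kb/min
#'   (`speed_mean` > 0).
#' @param pulse_minutes Duration of each labelling pulse, minutes (> 0).
#' @param stall_probability Probability the second pulse is stalled, in
#'   \[0, 1\].
#' @param iod_mean Mean inter-origin spacing, kb.
#' @param stretch Combing stretch factor, kb per micrometre (> 0).
#' @param seed Integer random seed.
#' @param origin_count_probs Probabilities of a fiber carrying 1, 2 or 3
#'   origins.
#' @return A `fiber_set`: list with `tracks` (data frame: `fiber_id`,
#'   `fork_id`, `cldu_um`, `idu_um`, `stalled`), `origins` (data frame:
#'   `fiber_id`, `position_kb`, sorted within fiber), `pulse_minutes`,
#'   `stretch`.
#' @export
simulate_fibers <- function(n_fibers, speed_mean = 1.5, speed_sd = 0.3,
                            pulse_minutes = 30, stall_probability = 0,
                            iod_mean = 200, stretch = 2, seed = 1L,
                            origin_count_probs = c(0.4, 0.4, 0.2)) {
  n_fibers <- assert_count(n_fibers, "n_fibers", min = 0L)
  assert_scalar_number(speed_mean, "speed_mean", min = 0, strict = TRUE)
  assert_scalar_number(speed_sd, "speed_sd", min = 0)
  assert_scalar_number(pulse_minutes, "pulse_minutes", min = 0, strict = TRUE)
  assert_scalar_number(stall_probability, "stall_probability", min = 0)
  if (stall_probability > 1) stopf("stall_probability must be <= 1")
  assert_scalar_number(stretch, "stretch", min = 0, strict = TRUE)
  assert_scalar_number(iod_mean, "iod_mean", min = 0, strict = TRUE)
  if (n_fibers == 0) {
    return(structure(list(
      tracks = data.frame(fiber_id = character(0), fork_id = character(0),
                          cldu_um = numeric(0), idu_um = numeric(0),
                          stalled = logical(0)),
      origins = data.frame(fiber_id = character(0), position_kb = numeric(0)),
      pulse_minutes = pulse_minutes, stretch = stretch), class = "fiber_set"))
  }
  rtnorm_pos <- function(n, m, s) {
    if (s == 0) return(rep(m, n))
    x <- stats::rnorm(n, m, s)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), m, s)
    x
  }
  sim <- with_seed(seed, {
    v1 <- rtnorm_pos(n_fibers, speed_mean, speed_sd)
    v2 <- rtnorm_pos(n_fibers, speed_mean, speed_sd)
    stalled <- stats::runif(n_fibers) < stall_probability
    v2[stalled] <- v1[stalled] * stats::runif(sum(stalled), 0, 0.5)
    n_origins <- sample.int(3L, n_fibers, replace = TRUE, prob = origin_count_probs)
    org <- lapply(seq_len(n_fibers), function(i) {
      pos <- stats::runif(1, 0, 100)
      if (n_origins[i] > 1)
        pos <- cumsum(c(pos, stats::rexp(n_origins[i] - 1, 1 / iod_mean)))
      pos
    })
    list(v1 = v1, v2 = v2, stalled = stalled, org = org)
  })
  fiber_id <- sprintf("fiber_%04d", seq_len(n_fibers))
  tracks <- data.frame(
    fiber_id = fiber_id,
    fork_id = sprintf("fork_%04d", seq_len(n_fibers)),
    cldu_um = sim$v1 * pulse_minutes / stretch,
    idu_um = sim$v2 * pulse_minutes / stretch,
    stalled = sim$stalled
  )
  origins <- data.frame(
    fiber_id = rep(fiber_id, lengths(sim$org)),
    position_kb = unlist(sim$org)
  )
  structure(list(tracks = tracks, origins = origins,
                 pulse_minutes = pulse_minutes, stretch = stretch),
            class = "fiber_set")
}

#' Replication fork speed
#'
#' Fork speed is the combined length of the CldU and IdU tracks converted to
#' kb via the stretch factor, divided by the total labelling time (two
#' pulses): `stretch * (cldu_um + idu_um) / (2 * pulse_minutes)`.
#'
#' @param cldu_um,idu_um Track lengths in micrometres.
#' @param pulse_minutes Single-pulse duration, minutes.
#' @param stretch Stretch factor, kb per micrometre.
#' @return Speed in kb/min.
#' @export
fork_speed <- function(cldu_um, idu_um, pulse_minutes = 30, stretch = 2) {
  stretch * (cldu_um + idu_um) / (2 * pulse_minutes)
}

#' Fork asymmetry ratio
#'
#' Length of the first-pulse (CldU) track divided by the second-pulse (IdU)
#' track — the order is fixed by pulse order, not by magnitude. A
#' `max/min` variant is available via `robust = TRUE` for robustness
#' analyses.
#'
#' @param cldu_um,idu_um Track lengths in micrometres (> 0).
#' @param robust If TRUE return `max/min` instead of CldU/IdU.
#' @return Dimensionless ratio.
#' @export
asymmetry_ratio <- function(cldu_um, idu_um, robust = FALSE) {
  if (robust) pmax(cldu_um, idu_um) / pmin(cldu_um, idu_um)
  else cldu_um / idu_um
}

#' Per-fork metrics of a fiber set
#'
#' Forks with a missing or zero-length segment are excluded with a logged
#' reason rather than silently dropped.
#'
#' @param fibers A `fiber_set`.
#' @return List with `metrics` (data frame: `fork_id`, `speed_kb_min`,
#'   `ratio`, `cldu_kb`, `idu_kb`) and `excluded` (data frame: `fork_id`,
#'   `reason`). The stretch factor used is recorded as an attribute.
#' @export
fork_metrics <- function(fibers) {
  stopifnot(inherits(fibers, "fiber_set"))
  tr <- fibers$tracks
  bad <- is.na(tr$cldu_um) | is.na(tr$idu_um) | tr$cldu_um <= 0 | tr$idu_um <= 0
  reason <- ifelse(is.na(tr$cldu_um) | tr$cldu_um <= 0,
                   "missing or zero-length CldU segment",
                   "missing or zero-length IdU segment")
  ok <- tr[!bad, , drop = FALSE]
  metrics <- data.frame(
    fork_id = ok$fork_id,
    speed_kb_min = fork_speed(ok$cldu_um, ok$idu_um, fibers$pulse_minutes,
                              fibers$stretch),
    ratio = asymmetry_ratio(ok$cldu_um, ok$idu_um),
    cldu_kb = ok$cldu_um * fibers$stretch,
    idu_kb = ok$idu_um * fibers$stretch
  )
  out <- list(metrics = metrics,
              excluded = data.frame(fork_id = tr$fork_id[bad],
                                    reason = reason[bad]))
  attr(out, "stretch") <- fibers$stretch
  out
}

#' Inter-origin distances
#'
#' Distances between consecutive origins on the same fiber; fibers with
#' fewer than two origins contribute nothing.
#'
#' @param fibers A `fiber_set`.
#' @return Numeric vector of distances in kb.
#' @export
inter_origin_distances <- function(fibers) {
  stopifnot(inherits(fibers, "fiber_set"))
  unlist(lapply(split(fibers$origins$position_kb, fibers$origins$fiber_id),
                function(p) if (length(p) >= 2) diff(sort(p)) else numeric(0)),
         use.names = FALSE)
}

#' Summarize fork metrics
#'
#' @param metrics Data frame from [fork_metrics] (`$metrics`), n >= 1.
#' @return List with `n`, `median_speed`, `mean_speed`, `median_ratio`
#'   (medians use the midpoint convention for even n).
#' @export
summarize_forks <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics)) metrics <- metrics$metrics
  if (nrow(metrics) == 0) stopf("no forks to summarize")
  list(n = nrow(metrics),
       median_speed = stats::median(metrics$speed_kb_min),
       mean_speed = mean(metrics$speed_kb_min),
       median_ratio = stats::median(metrics$ratio))
}

#' Write / read a fiber set as CSV
#'
#' Two CSV files: per-fork tracks and per-fiber origin positions.
#' Acquisition parameters travel in a header comment of the tracks file.
#' Doubles keep 17 significant digits so the round trip is exact.
#'
#' @param fibers A `fiber_set`.
#' @param tracks_path,origins_path CSV paths.
#' @return `tracks_path` (writer) or the `fiber_set` (reader).
#' @export
write_fibers <- function(fibers, tracks_path, origins_path) {
  con <- file(tracks_path, "w")
  writeLines(sprintf("# pulse_minutes=%.17g stretch=%.17g",
                     fibers$pulse_minutes, fibers$stretch), con)
  close(con)
  tr <- fibers$tracks
  for (j in seq_along(tr)) if (is.double(tr[[j]])) tr[[j]] <- sprintf("%.17g", tr[[j]])
  suppressWarnings(utils::write.table(tr, tracks_path, sep = ",", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  write_table_full(fibers$origins, origins_path, sep = ",")
  invisible(tracks_path)
}

#' @rdname write_fibers
#' @export
read_fibers <- function(tracks_path, origins_path) {
  hdr <- readLines(tracks_path, n = 1)
  m <- regmatches(hdr, regexec("pulse_minutes=([^ ]+) stretch=([^ ]+)", hdr))[[1]]
  if (length(m) != 3) stopf("tracks file lacks the acquisition header")
  tracks <- utils::read.csv(tracks_path, comment.char = "#",
                            stringsAsFactors = FALSE)
  origins <- utils::read.csv(origins_path, stringsAsFactors = FALSE)
  structure(list(tracks = tracks, origins = origins,
                 pulse_minutes = as.numeric(m[2]), stretch = as.numeric(m[3])),
            class = "fiber_set")
}
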