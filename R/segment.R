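#' Copy-number profile
#'
#' Container for one cell's segmentation: per-bin integer states (NA on
#' blacklisted bins, NA until [assign_integer_states] is applied), a segment
#' table, the calling algorithm tag and, once assigned, the ground ploidy.
#'
#' @param grid The [bin_grid] the profile lives on.
#' @param states Per-bin states (NA where undefined).
#' @param segments Data frame with columns `chrom`, `start`, `end`, `bins`
#'   (global indices of the member bins, list column), `n_bins`, `mean`
#'   (mean corrected signal) and `state`.
#' @param algorithm `"changepoint"` or `"hmm"`.
#' @param ploidy Expected (ground) ploidy of the library, NA until assigned.
#' @return A `cn_profile` object.
#' @export
cn_profile <- function(grid, states, segments, algorithm, ploidy = NA_real_) {
  structure(list(grid = grid, states = states, segments = segments,
                 algorithm = algorithm, ploidy = ploidy),
            class = "cn_profile")
}

robust_sigma <- function(x) {
  s <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(s) || s <= 0) s <- max(stats::sd(x), 1e-8)
  s
}

# Best interior segment of x[l..r]: boundaries (i, j) maximizing the SSE
# reduction of carving out bins (i+1)..j, normalized per changepoint added
# (1 when the carved segment touches an end of the window, else 2) — the
# circular-binary-segmentation style scan that can see a short interior
# event a single split cannot pay for. Returns c(i, j, score, k);
# deterministic (first maximum on ties). O(n^2) per scan.
best_segment <- function(cs, css, l, r) {
  n <- r - l + 1L
  if (n < 2L) return(NULL)
  s0 <- if (l > 1L) cs[l - 1L] else 0
  tot <- cs[r] - s0
  iv <- (l - 1L):(r - 1L)          # segment is (i+1)..j
  jv <- l:r
  csi <- c(s0, cs[l:(r - 1L)])     # cs at positions iv
  csj <- cs[jv]
  sin_ <- outer(csi, csj, function(a, b) b - a)
  nin <- outer(iv, jv, function(a, b) b - a)
  valid <- nin >= 1L & nin < n
  nin[!valid] <- 1L
  sout <- tot - sin_
  nout <- n - nin
  red <- sin_^2 / nin + sout^2 / nout - tot^2 / n
  k_cp <- outer(iv, jv, function(a, b) (a >= l) + (b < r))
  score <- red / pmax(k_cp, 1L)
  score[!valid] <- -Inf
  best <- arrayInd(which.max(score), dim(score))
  i <- iv[best[1]]; j <- jv[best[2]]
  c(i, j, score[best], k_cp[best])
}

#' Segment a per-bin signal by penalized binary changepoint search
#'
#' Recursive changepoint search per chromosome in the circular-binary-
#' segmentation style: at each step the interior segment maximizing the
#' squared-error reduction per added changepoint is carved out when that
#' normalized reduction exceeds `penalty * sigma^2 * log(N)` (N = number of
#' non-blacklisted bins genome-wide; sigma estimated robustly from
#' successive differences), then the pieces are re-scanned. Searching for a
#' whole segment rather than a single split lets a short interior event be
#' found in one step. Deterministic for fixed input; each scan is O(n^2) in
#' the chromosome's bin count. States are left unassigned; see
#' [assign_integer_states].
#'
#' @param signal Per-bin corrected counts or reference ratios.
#' @param grid A [bin_grid]; every chromosome needs >= 2 non-blacklisted
#'   bins.
#' @param penalty Model-complexity weight (> 0). Larger values give fewer
#'   segments; doubling the penalty never increases the segment count.
#' @return A [cn_profile] with `algorithm = "changepoint"`.
#' @export
segment_changepoint <- function(signal, grid, penalty = 1.5) {
  stopifnot(inherits(grid, "bin_grid"), length(signal) == nrow(grid))
  assert_scalar_number(penalty, "penalty", min = 0, strict = TRUE)
  nb_all <- which(!grid$blacklisted)
  sigma2 <- robust_sigma(signal[nb_all])^2
  thresh <- penalty * sigma2 * log(length(nb_all))
  seg_rows <- list()
  for (ch in unique(grid$chrom)) {
    idx <- nb_all[grid$chrom[nb_all] == ch]
    n <- length(idx)
    if (n < 2L) stopf("chromosome %s has < 2 non-blacklisted bins", ch)
    x <- signal[idx]
    cs <- cumsum(x)
    css <- cumsum(x^2)
    bounds <- list(c(1L, n))
    done <- list()
    while (length(bounds) > 0) {
      b <- bounds[[length(bounds)]]
      bounds[[length(bounds)]] <- NULL
      sp <- best_segment(cs, css, b[1], b[2])
      if (!is.null(sp) && sp[3] > thresh) {
        i <- as.integer(sp[1]); j <- as.integer(sp[2])
        pieces <- list(c(i + 1L, j))
        if (i >= b[1]) pieces <- c(pieces, list(c(b[1], i)))
        if (j < b[2]) pieces <- c(pieces, list(c(j + 1L, b[2])))
        bounds <- c(bounds, pieces)
      } else {
        done <- c(done, list(b))
      }
    }
    done <- done[order(vapply(done, `[`, 1L, 1L))]
    for (b in done) {
      bins <- idx[b[1]:b[2]]
      seg_rows <- c(seg_rows, list(data.frame(
        chrom = ch, start = grid$start[bins[1]], end = grid$end[bins[length(bins)]],
        n_bins = length(bins), mean = mean(signal[bins]), state = NA_real_
      ) |> (\(d) {d$bins <- I(list(bins)); d})()))
    }
  }
  segments <- do.call(rbind, seg_rows)
  cn_profile(grid, rep(NA_real_, nrow(grid)), segments, "changepoint")
}

# Ploidy hint -> per-copy scale for HMM emission means: median signal of
# non-blacklisted bins divided by the modal state.
estimate_per_copy <- function(signal_nb, ploidy) {
  stats::median(signal_nb) / ploidy
}

#' Segment a per-bin signal with a sticky Gaussian HMM
#'
#' Hidden states are candidate copy numbers 0..`max_state` with emission
#' means proportional to the state (seeded at state times a robust per-copy
#' estimate, median signal / modal state) and a shared noise scale estimated
#' from the data. Transitions are sticky (`stay_prob` of remaining in the
#' same state, giving an expected sojourn of `1/(1 - stay_prob)` bins,
#' matching the tens-of-megabase scale of real aneuploid segments at 1-Mb
#' bins). The most probable state path is computed by the Viterbi algorithm
#' per chromosome with a single deterministic initialization (no random
#' restarts, no EM), so identical inputs always give identical profiles.
#' Consecutive same-state bins are merged into segments; final integer
#' states are still assigned by [assign_integer_states] so that both callers
#' share one ploidy-anchoring rule.
#'
#' @param signal Per-bin corrected counts or reference ratios.
#' @param grid A [bin_grid].
#' @param max_state Copy-number cap (must be >= baseline ploidy + 2).
#' @param ploidy Modal-state hint used to seed the per-copy depth estimate;
#'   defaults to `round(max_state / 2)`.
#' @param stay_prob Self-transition probability in (0, 1).
#' @return A [cn_profile] with `algorithm = "hmm"`.
#' @export
segment_hmm <- function(signal, grid, max_state, ploidy = NULL,
                        stay_prob = 0.95) {
  stopifnot(inherits(grid, "bin_grid"), length(signal) == nrow(grid))
  max_state <- assert_count(max_state, "max_state", min = 1L)
  if (is.null(ploidy)) ploidy <- max(1L, round(max_state / 2))
  nb_all <- which(!grid$blacklisted)
  d <- estimate_per_copy(signal[nb_all], ploidy)
  if (!is.finite(d) || d <= 0) stopf("cannot estimate per-copy depth from signal")
  states <- 0:max_state
  mu <- states * d
  mu[1] <- 0.02 * d  # state 0 emits near zero, not exactly zero
  sigma <- max(robust_sigma(signal[nb_all]), d / 4)
  log_stay <- log(stay_prob)
  log_switch <- log((1 - stay_prob) / max_state)
  path <- rep(NA_integer_, nrow(grid))
  for (ch in unique(grid$chrom)) {
    idx <- nb_all[grid$chrom[nb_all] == ch]
    n <- length(idx)
    if (n < 1L) next
    ll <- outer(signal[idx], mu, function(x, m) stats::dnorm(x, m, sigma, log = TRUE))
    K <- length(states)
    delta <- ll[1, ]
    back <- matrix(0L, n, K)
    if (n > 1) for (t in 2:n) {
      cand <- matrix(delta, K, K) + log_switch        # cand[j, k]: from j to k
      diag(cand) <- delta + log_stay
      back[t, ] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(back[t, ], seq_len(K))] + ll[t, ]
    }
    st <- integer(n)
    st[n] <- which.max(delta)
    if (n > 1) for (t in (n - 1):1) st[t] <- back[t + 1, st[t + 1]]
    path[idx] <- states[st]
  }
  seg_rows <- list()
  for (ch in unique(grid$chrom)) {
    idx <- nb_all[grid$chrom[nb_all] == ch]
    if (length(idx) == 0) next
    runs <- rle(path[idx])
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in seq_along(runs$lengths)) {
      bins <- idx[starts[k]:ends[k]]
      seg_rows <- c(seg_rows, list(data.frame(
        chrom = ch, start = grid$start[bins[1]], end = grid$end[bins[length(bins)]],
        n_bins = length(bins), mean = mean(signal[bins]), state = NA_real_
      ) |> (\(d) {d$bins <- I(list(bins)); d})()))
    }
  }
  segments <- do.call(rbind, seg_rows)
  cn_profile(grid, rep(NA_real_, nrow(grid)), segments, "hmm")
}

#' Assign integer copy-number states under a ground-ploidy constraint
#'
#' Each segment's state is `round(mean / s)` (round half away from zero) for
#' a global per-copy scale `s`, subject to the constraint that the ground
#' ploidy — the count-weighted mean assigned state, a continuous quantity —
#' lies within `ploidy_bounds` (e.g. \[3.5, 4.5\] for 4n samples,
#' \[7.5, 8.5\] for 8n samples, both inclusive). The profile's `ploidy`
#' field records the count-weighted modal state (ties to the lower state),
#' the integer expected state downstream curation measures deviations
#' against.
#'
#' When `per_copy_depth` is supplied (as the calling pipeline does, using
#' the robust median-anchored estimate), the scale is pinned to it: the
#' ground state's level is a property of the library's sequencing depth,
#' not a free parameter. Re-optimizing the scale against the segment means
#' would let a smooth coverage wave masquerade as a clean mosaic of
#' adjacent states — precisely the artifact the wavy-pattern filter must
#' see at its true scale. Without `per_copy_depth` the scale is found by
#' grid search minimizing the weighted squared rounding error over feasible
#' scales (smallest scale on ties); the pinned scale also falls back to
#' this search if it violates the ploidy bounds.
#'
#' @param profile A [cn_profile] with unassigned states.
#' @param per_copy_depth Known reads-per-copy scale (optional).
#' @param ploidy_bounds Numeric `c(min, max)` with `min < max`.
#' @return The profile with integer `states`, segment states, `ploidy`
#'   (modal state) and a `per_copy` attribute (the selected scale). Errors
#'   with "ploidy constraint unsatisfiable" when no scale meets the bounds.
#' @export
assign_integer_states <- function(profile, per_copy_depth = NULL, ploidy_bounds) {
  stopifnot(inherits(profile, "cn_profile"))
  if (length(ploidy_bounds) != 2 || ploidy_bounds[1] >= ploidy_bounds[2])
    stopf("ploidy_bounds must be c(min, max) with min < max")
  seg <- profile$segments
  m <- seg$mean
  w <- seg$n_bins
  W <- stats::weighted.mean(m, w)
  if (!is.finite(W) || W <= 0) stopf("segment means must be positive")
  eval_scale <- function(s) {
    st <- round_half_away(m / s)
    st[st < 0] <- 0
    ground <- stats::weighted.mean(st, w)
    if (ground < ploidy_bounds[1] || ground > ploidy_bounds[2]) return(NULL)
    tab <- tapply(w, st, sum)
    modal <- as.numeric(names(tab))[order(-tab, as.numeric(names(tab)))][1]
    list(s = s, obj = sum(w * (m / s - st)^2), st = st, ground = modal)
  }
  best <- if (!is.null(per_copy_depth)) eval_scale(per_copy_depth) else NULL
  if (is.null(best)) {
    lo_s <- W / (ploidy_bounds[2] + 2.5)
    hi_s <- W / max(ploidy_bounds[1] - 1.5, 0.25)
    for (s in exp(seq(log(lo_s), log(hi_s), length.out = 6001))) {
      cand <- eval_scale(s)
      if (!is.null(cand) && (is.null(best) || cand$obj < best$obj - 1e-12)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) stopf("ploidy constraint unsatisfiable for bounds [%g, %g]",
                           ploidy_bounds[1], ploidy_bounds[2])
  profile$segments$state <- best$st
  states <- profile$states
  for (k in seq_len(nrow(seg))) states[seg$bins[[k]]] <- best$st[k]
  profile$states <- states
  profile$ploidy <- best$ground
  attr(profile, "per_copy") <- best$s
  profile
}

#' Full per-cell copy-number calling pipeline
#'
#' GC correction, optional reference normalization, both callers
#' (changepoint and HMM), and ploidy-constrained integer state assignment.
#'
#' @param library A `cell_library`.
#' @param grid A [bin_grid].
#' @param reference Optional per-bin mean counts of matched G1 libraries.
#' @param ploidy Expected ploidy class of the library (2, 4, 8, ...).
#' @param ploidy_bounds Ground-ploidy constraint; defaults to
#'   `ploidy +/- 0.5`.
#' @param max_state Copy-number cap for the HMM; defaults to `ploidy + 2`.
#' @param penalty Changepoint penalty, see [segment_changepoint].
#' @return List with elements `changepoint` and `hmm` (both [cn_profile]s
#'   with assigned states), `corrected` and `signal`.
#' @export
call_copy_number <- function(library, grid, reference = NULL, ploidy,
                             ploidy_bounds = c(ploidy - 0.5, ploidy + 0.5),
                             max_state = ploidy + 2, penalty = 1.5) {
  corrected <- gc_correct(library$counts, grid)
  signal <- if (is.null(reference)) corrected
            else normalize_to_reference(corrected, reference, grid)
  # per-copy scale anchored at the modal (ground) state's level
  per_copy <- stats::median(signal[!grid$blacklisted]) / ploidy
  cp <- segment_changepoint(signal, grid, penalty = penalty)
  cp <- assign_integer_states(cp, per_copy_depth = per_copy,
                              ploidy_bounds = ploidy_bounds)
  hm <- segment_hmm(signal, grid, max_state = max_state, ploidy = ploidy)
  hm <- assign_integer_states(hm, per_copy_depth = per_copy,
                              ploidy_bounds = ploidy_bounds)
  list(changepoint = cp, hmm = hm, corrected = corrected, signal = signal)
}

#' Write a copy-number profile as BED and its segments as JSON
#'
#' @param profile A [cn_profile] with assigned states.
#' @param bed_path Output BED path (chrom, start, end, state per bin).
#' @param json_path Optional output path for the segment list as JSON.
#' @return `bed_path`, invisibly.
#' @export
write_profile_bed <- function(profile, bed_path, json_path = NULL) {
  g <- profile$grid
  keep <- !is.na(profile$states)
  df <- data.frame(chrom = g$chrom[keep], start = g$start[keep],
                   end = g$end[keep], state = profile$states[keep])
  utils::write.table(df, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(json_path)) {
    seg <- profile$segments[, c("chrom", "start", "end", "n_bins", "mean", "state")]
    jsonlite::write_json(seg, json_path, digits = NA)
  }
  invisible(bed_path)
}
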