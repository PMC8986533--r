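#' GC-correct binned read counts
#'
#' Fits a quadratic of count versus bin GC over non-blacklisted bins, divides
#' each count by the fitted relative bias, and rescales so the genome-wide
#' mean count is preserved. The fit is robustified by iterative trimming of
#' large residuals, so copy-number aberrations sharing a GC band do not leak
#' into the bias curve.
#'
#' @param counts Per-bin read counts aligned to `grid`.
#' @param grid A [bin_grid] (needs >= 20 non-blacklisted bins).
#' @return Numeric vector of corrected counts (>= 0), same length as
#'   `counts`; the mean over non-blacklisted bins equals the input mean.
#' @export
gc_correct <- function(counts, grid) {
  stopifnot(inherits(grid, "bin_grid"), length(counts) == nrow(grid))
  nb <- !grid$blacklisted
  if (sum(nb) < 20) stopf("gc_correct needs >= 20 non-blacklisted bins")
  if (all(counts[nb] == 0)) stopf("degenerate input: all counts are zero")
  gc <- grid$gc
  dat <- data.frame(y = counts[nb], g = gc[nb], g2 = gc[nb]^2)
  use <- rep(TRUE, nrow(dat))
  for (it in 1:3) {
    fit <- stats::lm(y ~ g + g2, data = dat[use, ])
    resid <- dat$y - stats::predict(fit, newdata = dat)
    s <- stats::mad(resid)
    if (s == 0) break
    use_new <- abs(resid - stats::median(resid)) <= 2.5 * s
    if (all(use_new == use)) break
    use <- use_new
  }
  pred <- stats::predict(fit, newdata = data.frame(g = gc, g2 = gc^2))
  # guard against a pathological fit dipping to or below zero
  pred <- pmax(pred, 0.05 * mean(counts[nb]))
  fac <- pred / mean(pred[nb])
  corrected <- counts / fac
  unname(corrected * mean(counts[nb]) / mean(corrected[nb]))
}

#' Blacklist artifact-prone bins from control libraries
#'
#' Flags bins whose mean control coverage deviates from the genome-wide
#' median by more than `mad_factor` times the median absolute deviation
#' (extreme low or high coverage in control samples). Existing blacklist
#' flags are kept.
#'
#' @param control_libraries List of `cell_library` objects (>= 1).
#' @param grid A [bin_grid].
#' @param mad_factor Deviation multiplier; `Inf` blacklists nothing.
#' @return The grid with updated `blacklisted` flags.
#' @export
build_blacklist <- function(control_libraries, grid, mad_factor = 3) {
  stopifnot(inherits(grid, "bin_grid"))
  if (length(control_libraries) < 1) stopf("at least one control library is required")
  cov <- rowMeans(sapply(control_libraries, function(l) {
    stopifnot(length(l$counts) == nrow(grid))
    l$counts
  }))
  if (!is.finite(mad_factor)) return(grid)
  med <- stats::median(cov)
  m <- stats::mad(cov)
  grid$blacklisted <- grid$blacklisted | (abs(cov - med) > mad_factor * m)
  grid
}

#' Normalize corrected counts to a matched reference
#'
#' Divides each bin by the mean coverage of matched G1 reference libraries
#' (G1 diploid for G2/M diploid, G1 polyploid for G2/M polyploid) and
#' rescales so the genome-wide median ratio is 1.
#'
#' @param corrected Per-bin corrected counts.
#' @param reference Per-bin mean counts of the reference libraries; must be
#'   strictly positive on non-blacklisted bins.
#' @param grid A [bin_grid].
#' @return Per-bin ratio signal with median 1 over non-blacklisted bins.
#' @export
normalize_to_reference <- function(corrected, reference, grid) {
  stopifnot(inherits(grid, "bin_grid"),
            length(corrected) == nrow(grid), length(reference) == nrow(grid))
  nb <- !grid$blacklisted
  bad <- which(nb & reference <= 0)
  if (length(bad) > 0)
    stopf("reference is zero at non-blacklisted bin %s:%d", grid$chrom[bad[1]],
          grid$start[bad[1]])
  ratio <- corrected / reference
  ratio / stats::median(ratio[nb])
}
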