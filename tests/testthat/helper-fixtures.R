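# Shared fixtures, all built in code at test time.

toy_grid <- function(n_chrom = 3, bins = 100, width = 1e6) {
  make_toy_genome(n_chrom, bins, width)
}

# A profile with states fixed by hand (bypassing the callers), for score and
# concordance arithmetic.
manual_profile <- function(grid, states, ploidy) {
  seg <- data.frame(chrom = grid$chrom[1], start = grid$start[1],
                    end = grid$end[nrow(grid)], n_bins = nrow(grid),
                    mean = mean(states), state = NA_real_)
  seg$bins <- I(list(seq_len(nrow(grid))))
  p <- cn_profile(grid, states, seg, "manual", ploidy = ploidy)
  p
}

# Independent oracle for two-changepoint placement: exhaustive search over
# all (i < j) segmentations of x into three pieces, minimizing total SSE.
best_two_changepoints <- function(x) {
  n <- length(x)
  sse <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  best <- c(NA, NA); best_val <- Inf
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) {
    val <- sse(x[1:i]) + sse(x[(i + 1):j]) + sse(x[(j + 1):n])
    if (val < best_val) { best_val <- val; best <- c(i, j) }
  }
  best
}
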