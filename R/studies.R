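#' Random first-cycle tetraploid karyotypes
#'
#' Draws per-cell karyotype specs for G2/M tetraploid cells: baseline copy
#' number 8 (a 4n cell that completed S phase) with 1-3 non-overlapping
#' under- or over-replicated territories at copy number 7 or 9. Territory
#' lengths are 30-100 bins (30-100 Mb at 1-Mb bins), the segmental-to-arm
#' scale of the large contiguous territories seen in first-cycle tetraploid
#' karyotypes.
#'
#' @param n_cells Number of karyotypes to draw.
#' @param grid A [bin_grid].
#' @param baseline Baseline copy number (default 8).
#' @param seed Integer random seed.
#' @return List of [karyotype_spec] objects.
#' @export
random_tetraploid_karyotypes <- function(n_cells, grid, baseline = 8, seed = 1L) {
  chroms <- unique(grid$chrom)
  nb_per <- vapply(chroms, function(ch) sum(grid$chrom == ch), 0L)
  with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      k <- sample(1:3, 1)
      ab <- NULL
      tries <- 0
      while (is.null(ab) || nrow(ab) < k) {
        tries <- tries + 1
        if (tries > 200) break
        ch <- sample(chroms, 1)
        len <- sample(30:100, 1)
        start <- sample.int(nb_per[[ch]] - len, 1)
        cand <- data.frame(chrom = ch, start_bin = start,
                           end_bin = start + len - 1L,
                           cn = sample(c(baseline - 1, baseline + 1), 1))
        ok <- is.null(ab) || !any(ab$chrom == ch &
                                  ab$start_bin <= cand$end_bin &
                                  ab$end_bin >= cand$start_bin)
        if (ok) ab <- rbind(ab, cand)
      }
      karyotype_spec(baseline, ab, label = "4n G2/M")
    })
  })
}

#' Karyotype-recovery study on simulated G2/M tetraploid cells
#'
#' Simulates `n_cells` aberrant G2/M tetraploid cells (baseline copy number
#' 8, 1-3 random territories at 7 or 9 copies) and `n_cells` clean ones on a
#' ~3,000-bin 1-Mb tiling at the stated per-copy depth, runs both callers
#' with the 8n ground-ploidy constraint, curates every cell, and scores both
#' populations.
#'
#' @param n_cells Cells per arm.
#' @param depth_per_copy Reads per bin per copy.
#' @param n_chrom,bins_per_chrom Grid geometry.
#' @param seed Integer random seed.
#' @return List with per-caller bin recovery (over aberrant cells), clean-
#'   and aberrant-arm curation retention fractions, mean concordance, and
#'   the three karyotype scores per arm.
#' @export
study_karyotype_recovery <- function(n_cells = 30, depth_per_copy = 10,
                                     n_chrom = 3, bins_per_chrom = 1000,
                                     seed = 1L) {
  grid <- make_toy_genome(n_chrom, bins_per_chrom, 1e6)
  specs <- random_tetraploid_karyotypes(n_cells, grid, baseline = 8,
                                        seed = derive_seed(seed, 1))
  clean_spec <- karyotype_spec(8, label = "4n G2/M clean")
  run_arm <- function(spec_list, seed_off) {
    lapply(seq_along(spec_list), function(i) {
      cfg <- sim_config(depth_per_copy = depth_per_copy,
                        seed = derive_seed(seed, seed_off + i))
      lib <- simulate_cell_counts(grid, spec_list[[i]], cfg,
                                  cell_id = sprintf("cell_%03d", seed_off + i))
      calls <- call_copy_number(lib, grid, ploidy = 8,
                                ploidy_bounds = c(7.5, 8.5), max_state = 10)
      list(lib = lib, calls = calls,
           truth = truth_states(spec_list[[i]], grid))
    })
  }
  ab <- run_arm(specs, 100L)
  cl <- run_arm(rep(list(clean_spec), n_cells), 500L)
  recov <- function(cells, which_caller) {
    mean(unlist(lapply(cells, function(c)
      c$calls[[which_caller]]$states == c$truth)))
  }
  curate_arm <- function(cells) {
    vapply(cells, function(c) {
      curate_library(c$lib, c$calls$changepoint, c$calls$hmm, "8n",
                     corrected = c$calls$corrected)$decision == "keep"
    }, TRUE)
  }
  score_arm <- function(cells) {
    an <- vapply(cells, function(c)
      aneuploidy_score(c$calls$changepoint, ploidy = 8)$score, 0)
    fr <- vapply(cells, function(c)
      aneuploidy_score(c$calls$changepoint, ploidy = 8)$aneuploid_fraction, 0)
    het <- heterogeneity_score(lapply(cells, function(c) c$calls$changepoint))$mean
    list(aneuploidy = mean(an), aneuploid_fraction = mean(fr),
         heterogeneity = het)
  }
  list(
    recovery_changepoint = recov(ab, "changepoint"),
    recovery_hmm = recov(ab, "hmm"),
    concordance = mean(vapply(ab, function(c)
      concordance(c$calls$changepoint, c$calls$hmm), 0)),
    clean_retention = mean(curate_arm(cl)),
    aberrant_scores = score_arm(ab),
    clean_scores = score_arm(cl),
    n_cells = n_cells
  )
}

#' Operating characteristic of the wavy-pattern filter
#'
#' Simulates euploid 4n cells with a multiplicative coverage wave of the
#' given amplitudes and measures the fraction of cells the wavy-pattern
#' filter discards (evaluated on the changepoint caller's profile).
#'
#' @param amplitudes Wave amplitudes to test.
#' @param n_per_arm Cells per amplitude.
#' @param depth_per_copy Reads per bin per copy.
#' @param n_chrom,bins_per_chrom Grid geometry.
#' @param seed Integer random seed.
#' @return Data frame with `amplitude` and `discard_rate`.
#' @export
study_wavy_oc <- function(amplitudes = c(0, 0.2), n_per_arm = 50,
                          depth_per_copy = 10, n_chrom = 3,
                          bins_per_chrom = 1000, seed = 1L) {
  grid <- make_toy_genome(n_chrom, bins_per_chrom, 1e6)
  spec <- karyotype_spec(4, label = "4n")
  rates <- vapply(seq_along(amplitudes), function(ai) {
    discards <- vapply(seq_len(n_per_arm), function(i) {
      cfg <- sim_config(depth_per_copy = depth_per_copy,
                        wave_amplitude = amplitudes[ai],
                        seed = derive_seed(seed, ai * 1000L + i))
      lib <- simulate_cell_counts(grid, spec, cfg)
      calls <- call_copy_number(lib, grid, ploidy = 4)
      stats <- state_statistics(calls$changepoint, calls$corrected)
      !wavy_pattern_filter(stats)$pass
    }, TRUE)
    mean(discards)
  }, 0)
  data.frame(amplitude = amplitudes, discard_rate = rates)
}

#' Fiber estimator recovery study
#'
#' @param n_forks Forks for the speed arm.
#' @param seed Integer random seed.
#' @return List with mean/median speed versus the generating mean, median
#'   stall ratio under certain stalling, and IOD mean versus the generating
#'   mean.
#' @export
study_fiber_recovery <- function(n_forks = 300, seed = 1L) {
  fs <- simulate_fibers(n_forks, speed_mean = 1.5, speed_sd = 0.3,
                        seed = derive_seed(seed, 1))
  s <- summarize_forks(fork_metrics(fs))
  fst <- simulate_fibers(n_forks, stall_probability = 1,
                         seed = derive_seed(seed, 2))
  st <- summarize_forks(fork_metrics(fst))
  iod <- inter_origin_distances(simulate_fibers(500, iod_mean = 200,
                                                seed = derive_seed(seed, 3)))
  list(mean_speed = s$mean_speed, median_speed = s$median_speed,
       generating_speed = 1.5, stall_median_ratio = st$median_ratio,
       iod_mean = mean(iod), generating_iod = 200, n_iod = length(iod))
}

#' Planted-spot recall study
#'
#' Simulates single-nucleus images with planted Gaussian foci at the given
#' signal-to-noise ratio (spot amplitude / noise s.d.) across seeds, detects
#' foci inside the true nuclear mask, and matches detections to planted
#' centres within 2 px.
#'
#' @param n_seeds Number of seeded images.
#' @param snr Spot amplitude over noise standard deviation.
#' @param seed Integer random seed.
#' @return List with `recall`, `false_positives_per_nucleus` and
#'   `mean_position_error_px`.
#' @export
study_foci_recall <- function(n_seeds = 100, snr = 5, seed = 1L) {
  noise_sd <- 0.1
  res <- vapply(seq_len(n_seeds), function(i) {
    b <- simulate_focus_image(c(96, 96), 1, foci_per_nucleus = 12,
                              focus_sigma = 1.5,
                              focus_intensity = snr * noise_sd,
                              noise_sd = noise_sd,
                              seed = derive_seed(seed, i))
    fo <- detect_foci(b$damage, b$labels == 1)
    if (nrow(b$foci) == 0) return(c(0, 0, nrow(fo), 0))
    d <- vapply(seq_len(nrow(b$foci)), function(k) {
      if (nrow(fo) == 0) return(Inf)
      min(sqrt((fo$x - b$foci$x[k])^2 + (fo$y - b$foci$y[k])^2))
    }, 0)
    hits <- sum(d <= 2)
    c(hits, nrow(b$foci), max(nrow(fo) - hits, 0), sum(d[d <= 2]))
  }, numeric(4))
  list(recall = sum(res[1, ]) / sum(res[2, ]),
       false_positives_per_nucleus = mean(res[3, ]),
       mean_position_error_px = sum(res[4, ]) / sum(res[1, ]))
}

#' Uniformity of the Costes randomization p-value under independence
#'
#' Generates independent noise channels, computes the randomization p-value
#' per seed, and returns the p-values with a Kolmogorov-Smirnov comparison
#' against the uniform distribution.
#'
#' @param n_seeds Number of independent experiments.
#' @param n_rand Randomizations per experiment.
#' @param seed Integer random seed.
#' @return List with `p_values`, `ks_statistic`, `ks_p`.
#' @export
study_costes_uniformity <- function(n_seeds = 200, n_rand = 199, seed = 1L) {
  pv <- vapply(seq_len(n_seeds), function(i) {
    with_seed(derive_seed(seed, i), {
      a <- matrix(stats::runif(1600), 40, 40)
      b <- matrix(stats::runif(1600), 40, 40)
      costes_randomization_p(a, b, n = n_rand,
                             seed = derive_seed(seed, 10000L + i),
                             thresholds = c(0.5, 0.5))$p
    })
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  list(p_values = pv, ks_statistic = unname(ks$statistic), ks_p = ks$p.value)
}
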