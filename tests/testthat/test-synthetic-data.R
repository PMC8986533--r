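test_that("toy genome tiling has the forced geometry and bounded GC", {
  g <- make_toy_genome(3, 100, 1e6)
  expect_equal(nrow(g), 300)
  expect_true(all(g$end - g$start == 1e6))

  g1 <- make_toy_genome(1, 1, 5e5)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$start, g1$end), c(0, 5e5))

  g2 <- make_toy_genome(2, 50, 1e4)
  expect_equal(max(g2$end[g2$chrom == "chr1"]), 5e5)
  expect_equal(max(g2$end[g2$chrom == "chr2"]), 5e5)

  expect_true(all(g$gc >= 0.3 & g$gc <= 0.6))
  expect_false(any(g$blacklisted))
  expect_error(make_toy_genome(0, 10, 1e6), "n_chromosomes")
  expect_error(make_toy_genome(2, 10, -5), "bin_width")
})

test_that("karyotype specs reject overlapping or invalid aberrations", {
  expect_error(karyotype_spec(4, data.frame(chrom = "chr1", start_bin = 10,
                                            end_bin = 20, cn = 4.5)),
               "integers")
  expect_error(karyotype_spec(4, data.frame(chrom = c("chr1", "chr1"),
                                            start_bin = c(10, 15),
                                            end_bin = c(20, 30), cn = c(5, 3))),
               "overlap")
  g <- toy_grid(1, 50)
  ks <- karyotype_spec(2, data.frame(chrom = "chr1", start_bin = 40,
                                     end_bin = 60, cn = 3))
  expect_error(truth_states(ks, g), "outside the grid")
})

test_that("simulated counts match the negative-binomial moments", {
  g <- toy_grid(3, 1000)
  ks <- karyotype_spec(4, label = "4n")
  cfg <- sim_config(depth_per_copy = 10, nb_dispersion = 1.5, seed = 42)
  lib <- simulate_cell_counts(g, ks, cfg)
  mu <- 40
  n <- nrow(g)
  # total within 3 s.d. of the analytic mean (var = n * dispersion * mu)
  expect_lt(abs(lib$total - n * mu), 3 * sqrt(n * 1.5 * mu))
  # per-bin variance close to dispersion * mean
  expect_lt(abs(var(lib$counts) / (1.5 * mu) - 1), 0.15)

  # dispersion 1 gives Poisson-like counts: var ~= mean
  cfg_p <- sim_config(depth_per_copy = 10, nb_dispersion = 1, seed = 42)
  lib_p <- simulate_cell_counts(g, ks, cfg_p)
  expect_lt(abs(var(lib_p$counts) / mean(lib_p$counts) - 1), 0.15)

  # determinism: same seed + config is bitwise identical
  expect_identical(simulate_cell_counts(g, ks, cfg)$counts, lib$counts)

  # zero-copy bins emit zero reads
  ks0 <- karyotype_spec(2, data.frame(chrom = "chr1", start_bin = 1,
                                      end_bin = 10, cn = 0))
  lib0 <- simulate_cell_counts(toy_grid(1, 100), ks0, cfg)
  expect_true(all(lib0$counts[1:10] == 0))
})

test_that("population simulation returns the requested mixture with ground truth", {
  g <- toy_grid(1, 60)
  s2 <- karyotype_spec(2, label = "2n")
  s4 <- karyotype_spec(4, data.frame(chrom = "chr1", start_bin = 10,
                                     end_bin = 20, cn = 5), label = "4n")
  pop <- simulate_population(g, list(list(spec = s2, n = 5), list(spec = s4, n = 5)),
                             sim_config(seed = 1))
  expect_length(pop, 10)
  expect_equal(sum(vapply(pop, function(l) l$condition, "") == "2n"), 5)
  expect_equal(sum(vapply(pop, function(l) l$condition, "") == "4n"), 5)
  # ground truth of the aneuploid spec has exactly one non-baseline run
  cn <- pop[[6]]$truth$cn
  runs <- rle(cn)
  expect_equal(sum(runs$values != 4), 1)
  # per-cell seeds differ but the population is reproducible as a whole
  pop2 <- simulate_population(g, list(list(spec = s2, n = 5), list(spec = s4, n = 5)),
                              sim_config(seed = 1))
  expect_identical(lapply(pop, `[[`, "counts"), lapply(pop2, `[[`, "counts"))
  expect_false(identical(pop[[1]]$counts, pop[[2]]$counts))
  expect_error(simulate_population(g, list(), sim_config()), "at least one")
})

test_that("fiber simulation honours the deterministic limit and stall model", {
  fs <- simulate_fibers(20, speed_mean = 1, speed_sd = 0, pulse_minutes = 30,
                        stall_probability = 0, stretch = 2, seed = 1)
  expect_true(all(fs$tracks$cldu_um == 15))
  expect_true(all(fs$tracks$idu_um == 15))

  fs1 <- simulate_fibers(200, stall_probability = 1, seed = 2)
  fm <- fork_metrics(fs1)
  expect_true(all(fm$metrics$ratio > 1))

  expect_equal(nrow(simulate_fibers(0)$tracks), 0)
  expect_error(simulate_fibers(10, stretch = 0), "stretch")
})

test_that("focus image generator returns faithful ground truth", {
  # zero rate: pure-noise damage channel, empty foci list
  b0 <- simulate_focus_image(c(96, 96), 1, foci_per_nucleus = 0, seed = 1)
  expect_equal(nrow(b0$foci), 0)
  expect_lt(max(b0$damage), 0.6)  # no spot of amplitude ~1 present

  # full overlap: marker and damage spot centre sets identical
  b1 <- simulate_focus_image(c(96, 96), 1, foci_per_nucleus = 8,
                             overlap_fraction = 1, seed = 2)
  expect_true(all(b1$marker_foci$shared))
  expect_equal(b1$marker_foci[, c("x", "y")], b1$foci[, c("x", "y")],
               ignore_attr = TRUE)

  # Poisson rate recovered across seeds (oracle: Poisson mean 12)
  means <- vapply(1:40, function(s) {
    nrow(simulate_focus_image(c(200, 200), 4, foci_per_nucleus = 12,
                              seed = s)$foci) / 4
  }, 0)
  expect_lt(abs(mean(means) - 12), 3 * sqrt(12 / (40 * 4)))

  # impossible packing is an explicit error
  expect_error(simulate_focus_image(c(40, 40), 25, seed = 1), "cannot pack")
})
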