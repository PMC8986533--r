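test_that("concordance is the length-weighted agreement and is symmetric", {
  g <- toy_grid(1, 100)
  a <- manual_profile(g, rep(4, 100), 4)
  b <- manual_profile(g, rep(4, 100), 4)
  expect_equal(concordance(a, b), 1)

  b$states[1:6] <- 5
  expect_equal(concordance(a, b), 0.94)
  expect_lt(concordance(a, b), 0.95)  # fails the 2n threshold
  expect_gte(concordance(a, b), 0.90) # passes the polyploid threshold
  expect_equal(concordance(a, b), concordance(b, a))

  b$states[] <- 5
  expect_equal(concordance(a, b), 0)

  g2 <- toy_grid(1, 50)
  expect_error(concordance(a, manual_profile(g2, rep(4, 50), 4)),
               "different bin grids")
})

test_that("read-depth thresholds follow the 10-reads-per-copy rule", {
  expect_equal(per_bin_read_threshold(2), 20)
  expect_equal(per_bin_read_threshold(3), 30)
  expect_equal(per_bin_read_threshold(0), 0)
  expect_error(per_bin_read_threshold(-1), ">= 0")

  expect_equal(min_required_reads(2, 3000), 60000)
  expect_equal(min_required_reads(8, 3000), 240000)
  expect_equal(min_required_reads(1, 1), 10)
})

test_that("read-depth filter compares mean reads per copy, boundary inclusive", {
  g <- toy_grid(3, 1000)
  mk <- function(counts) structure(list(cell_id = "c", condition = "",
                                        counts = counts, total = sum(counts),
                                        truth = NULL), class = "cell_library")
  # uniform 4-somy, 100,000 reads over 3,000 bins: 33.3/bin < 40 -> discard
  p4 <- manual_profile(g, rep(4, 3000), 4)
  rd <- read_depth_filter(mk(rep(100000 / 3000, 3000)), p4)
  expect_false(rd$pass)
  expect_equal(rd$mean_reads_per_copy, 100000 / 3000 / 4)

  # uniform 2-somy at exactly 20 reads/bin passes (inclusive boundary)
  p2 <- manual_profile(g, rep(2, 3000), 2)
  expect_true(read_depth_filter(mk(rep(20, 3000)), p2)$pass)

  # uniform 8-somy at 79 reads/bin fails
  p8 <- manual_profile(g, rep(8, 3000), 8)
  expect_false(read_depth_filter(mk(rep(79, 3000)), p8)$pass)

  p0 <- manual_profile(g, rep(0, 3000), 2)
  expect_error(read_depth_filter(mk(rep(20, 3000)), p0), "degenerate")
})

test_that("non-rounded copy number follows the mean-ratio formula", {
  expect_equal(non_rounded_copy_number(125, 100, 4), 5.0)
  expect_equal(non_rounded_copy_number(115, 100, 4), 4.6)
  expect_equal(non_rounded_copy_number(100, 100, 4), 4.0)
  expect_error(non_rounded_copy_number(100, 0, 4), "mean_expected")
})

test_that("wavy-pattern filter triggers above 1% and discards beyond 0.25", {
  g <- toy_grid(1, 100)
  mk_stats <- function(frac5, mean5) {
    n5 <- round(frac5 * 100)
    states <- c(rep(5, n5), rep(4, 100 - n5))
    p <- manual_profile(g, states, 4)
    corrected <- ifelse(states == 5, mean5, 100)
    state_statistics(p, corrected)
  }
  # 5-somy at 2% of the genome, non-rounded 4.6: discard (4.6 < 4.75)
  w <- wavy_pattern_filter(mk_stats(0.02, 115))
  expect_false(w$pass)
  expect_equal(w$evaluations$non_rounded, 4.6)

  # non-rounded 5.0: keep
  expect_true(wavy_pattern_filter(mk_stats(0.02, 125))$pass)

  # below the >1% trigger: not evaluated, keep
  w3 <- wavy_pattern_filter(mk_stats(0.009, 115))
  expect_true(w3$pass)
  expect_equal(nrow(w3$evaluations), 0)

  # boundary conventions: exactly 0.25 deviation passes; exactly 1% genome
  # fraction does not trigger
  expect_true(wavy_pattern_filter(mk_stats(0.02, 118.75))$pass)  # nr = 4.75
  expect_equal(nrow(wavy_pattern_filter(mk_stats(0.01, 115))$evaluations), 0)
})

test_that("library curation combines the three filters into one decision", {
  g <- toy_grid(3, 200)
  ks <- karyotype_spec(4, label = "4n G2/M")
  # clean 4n library at depth 12/copy: keep, all filters pass
  lib <- simulate_cell_counts(g, ks, sim_config(depth_per_copy = 12, seed = 31))
  calls <- call_copy_number(lib, g, ploidy = 4)
  rep_keep <- curate_library(lib, calls$changepoint, calls$hmm, "4n",
                             corrected = calls$corrected)
  expect_equal(rep_keep$decision, "keep")
  expect_length(rep_keep$reasons, 0)
  expect_equal(rep_keep$concordance_threshold, 0.90)

  # the same cell with a strong coverage wave is discarded by the wavy filter
  libw <- simulate_cell_counts(g, ks, sim_config(depth_per_copy = 12,
                                                 wave_amplitude = 0.15,
                                                 seed = 31))
  callsw <- call_copy_number(libw, g, ploidy = 4)
  rep_w <- curate_library(libw, callsw$changepoint, callsw$hmm, "4n",
                          corrected = callsw$corrected)
  expect_equal(rep_w$decision, "discard")
  expect_true("wavy_pattern" %in% rep_w$reasons)

  # insufficient total reads: discarded with a read-depth reason
  libd <- simulate_cell_counts(g, ks, sim_config(depth_per_copy = 5, seed = 32))
  callsd <- call_copy_number(libd, g, ploidy = 4)
  expect_lt(libd$total, min_required_reads(4, nrow(g)))
  rep_d <- curate_library(libd, callsd$changepoint, callsd$hmm, "4n",
                          corrected = callsd$corrected)
  expect_equal(rep_d$decision, "discard")
  expect_true("read_depth" %in% rep_d$reasons)

  # disarming the wavy filter is configuration, not code
  rep_off <- curate_library(libw, callsw$changepoint, callsw$hmm,
                            list(class = "4n", wavy_armed = FALSE),
                            corrected = callsw$corrected)
  expect_false("wavy_pattern" %in% rep_off$reasons)

  # the decision is a pure function of the filters: recomputation agrees and
  # keep holds iff no reason is recorded
  rep2 <- curate_library(lib, calls$changepoint, calls$hmm, "4n",
                         corrected = calls$corrected)
  expect_identical(rep2$decision, rep_keep$decision)
  for (r in list(rep_keep, rep_w, rep_d)) {
    expect_identical(r$decision == "keep", length(r$reasons) == 0L)
  }

  summ <- cohort_summary(list(rep_keep, rep_w, rep_d))
  expect_equal(summ$decision, c("keep", "discard", "discard"))
})
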