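test_that("nuclear segmentation recovers simulated nuclei and splits touching ones", {
  b <- simulate_focus_image(c(220, 220), 9, foci_per_nucleus = 5, seed = 8)
  seg <- segment_nuclei(b$dapi)
  expect_equal(nrow(seg$nuclei), 9)
  truth_areas <- sort(b$nuclei$area_px)
  got_areas <- sort(seg$nuclei$area_px)
  expect_true(all(abs(got_areas - truth_areas) / truth_areas < 0.10))

  # blank image: empty list, not an error
  seg0 <- segment_nuclei(matrix(0, 50, 50))
  expect_equal(nrow(seg0$nuclei), 0)

  # two touching discs split by the watershed
  img <- matrix(0, 80, 120)
  rows <- matrix(seq_len(80), 80, 120)
  cols <- matrix(seq_len(120), 80, 120, byrow = TRUE)
  img[(rows - 40)^2 + (cols - 45)^2 <= 18^2] <- 1
  img[(rows - 40)^2 + (cols - 76)^2 <= 18^2] <- 1
  img <- img + matrix(rnorm(80 * 120, 0, 0.01), 80, 120)
  seg2 <- segment_nuclei(img)
  expect_equal(nrow(seg2$nuclei), 2)
})

test_that("focus detection finds planted spots and suppresses close pairs", {
  b <- simulate_focus_image(c(96, 96), 1, foci_per_nucleus = 12,
                            focus_intensity = 0.5, noise_sd = 0.1, seed = 3)
  fo <- detect_foci(b$damage, b$labels == 1)
  expect_equal(nrow(fo), nrow(b$foci))
  # every planted spot matched within 2 px
  d <- sapply(seq_len(nrow(b$foci)), function(i) {
    min(sqrt((fo$x - b$foci$x[i])^2 + (fo$y - b$foci$y[i])^2))
  })
  expect_true(all(d <= 2))

  # zero planted spots: no detections at default prominence
  b0 <- simulate_focus_image(c(96, 96), 1, foci_per_nucleus = 0,
                             noise_sd = 0.1, seed = 4)
  expect_equal(nrow(detect_foci(b0$damage, b0$labels == 1)), 0)

  # two spots closer than min_separation merge into one detection
  img <- matrix(0, 60, 60)
  for (cx in c(30, 32)) {
    d2 <- outer((seq_len(60) - 30)^2, (seq_len(60) - cx)^2, "+")
    img <- img + exp(-d2 / (2 * 1.5^2))
  }
  mask <- matrix(TRUE, 60, 60)
  expect_equal(nrow(detect_foci(img, mask, min_separation = 3,
                                prominence = 0.05)), 1)
})

test_that("damage index multiplies coverage by mean positive intensity", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:10] <- TRUE  # 100-px nucleus
  img <- matrix(0, 20, 20)
  img[1:4, 1:5] <- 50       # 20 positive px at 50 a.u.
  di <- damage_index(img, mask, threshold = 10)
  expect_equal(di$coverage, 20)
  expect_equal(di$mean_positive_intensity, 50)
  expect_equal(di$index, 1000)

  # no positive pixels
  di0 <- damage_index(matrix(0, 20, 20), mask, threshold = 10)
  expect_equal(di0$index, 0)
  expect_equal(di0$coverage, 0)

  # all pixels positive at constant intensity I: index = 100 * I
  di1 <- damage_index(matrix(7, 20, 20), mask, threshold = 1)
  expect_equal(di1$index, 700)
})

test_that("the damage index is scale-equivariant with coverage unchanged", {
  b <- simulate_focus_image(c(96, 96), 1, foci_per_nucleus = 10, seed = 5)
  mask <- b$labels == 1
  d1 <- damage_index(b$damage, mask)
  d3 <- damage_index(3 * b$damage, mask)
  expect_equal(d3$coverage, d1$coverage, tolerance = 1e-2)
  expect_equal(d3$index, 3 * d1$index, tolerance = 1e-2)
})

test_that("normalized counts and the >= k foci classification behave", {
  nc <- normalized_counts(10, 100, 500)
  expect_equal(nc$per_area, 0.1)
  expect_equal(nc$per_dna_intensity, 0.02)
  expect_equal(normalized_counts(10, 200, 500)$per_area, 0.05)
  expect_error(normalized_counts(10, 0, 500), "area")

  expect_equal(fraction_above_threshold(c(9, 10, 11), k = 10), 2 / 3)
  expect_equal(fraction_above_threshold(rep(0, 5)), 0)
  expect_equal(fraction_above_threshold(c(3, 4), k = 0), 1)
  expect_error(fraction_above_threshold(numeric(0)), "no nuclei")
})

test_that("Manders coefficients hit the identical and disjoint limits", {
  a <- matrix(0, 40, 40); a[10:15, 10:15] <- 2
  m_id <- manders(a, a)
  expect_equal(m_id$M1, 1)
  expect_equal(m_id$M2, 1)

  b <- matrix(0, 40, 40); b[25:30, 25:30] <- 3
  m_dj <- manders(a, b)
  expect_equal(m_dj$M1, 0)
  expect_equal(m_dj$M2, 0)

  expect_error(manders(a, matrix(0, 40, 40)), "zero total intensity")
  expect_error(manders(a, matrix(0, 10, 10)), "shape")
})

test_that("Manders M1 tracks the planted overlap share", {
  shares <- vapply(1:20, function(s) {
    b <- simulate_focus_image(c(120, 120), 1, foci_per_nucleus = 10,
                              focus_intensity = 1, noise_sd = 0.02,
                              overlap_fraction = 0.5, seed = s)
    mask <- b$labels == 1
    thr <- 0.15
    m <- manders(b$damage, b$marker, mask, thresholds = c(thr, thr))$M1
    # oracle: intensity share of damage sitting on marker-positive pixels,
    # computed from the known pixel values (definition), must match exactly
    exp_m <- sum(b$damage[mask & b$marker > thr]) / sum(b$damage[mask])
    expect_identical(m, exp_m)
    m
  }, 0)
  # with half the centres shared, roughly half the damage intensity
  # colocalizes; Monte-Carlo band
  expect_gt(mean(shares), 0.3)
  expect_lt(mean(shares), 0.8)
})

test_that("Costes randomization p-values behave at the limits", {
  # zero background: all of a's intensity sits on b-positive pixels, and no
  # permutation scattering the signal can reach perfect colocalization
  a <- matrix(0, 40, 40); a[5:10, 5:10] <- runif(36, 0.5, 1)
  p_id <- costes_randomization_p(a, a, n = 200, seed = 1)
  expect_equal(p_id$observed, 1)
  expect_equal(p_id$p, 1 / 201)

  const <- matrix(4, 40, 40)
  b <- matrix(runif(1600), 40, 40)
  p_c <- costes_randomization_p(const, b, n = 100, seed = 2, thresholds = c(0, 0.5))
  expect_equal(p_c$p, 1)
})
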