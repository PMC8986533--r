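#' Otsu threshold of a numeric vector
#'
#' Histogram-based Otsu threshold computed on values rescaled to \[0, 1\]
#' and mapped back, so the result is equivariant under positive affine
#' rescaling of the input.
#'
#' @param v Numeric vector (non-constant).
#' @param levels Histogram resolution.
#' @return Threshold on the original intensity scale.
#' @export
otsu_threshold <- function(v, levels = 256L) {
  r <- range(v)
  if (diff(r) == 0) stopf("cannot threshold a constant signal")
  x <- (v - r[1]) / diff(r)
  h <- tabulate(pmin(floor(x * levels) + 1L, levels), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(levels) - 0.5) / levels)
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  r[1] + (k / levels) * diff(r)
}

place_in_ellipse <- function(n, cx, cy, rx, ry, shrink, min_sep, existing = NULL,
                             max_tries = 2000L) {
  pts <- if (is.null(existing)) matrix(numeric(0), 0, 2) else existing
  placed <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(placed) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stopf("cannot place %d foci in nucleus at (%g, %g): packing impossible",
            n, cx, cy)
    u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
    if (u^2 + v^2 > 1) next
    x <- cx + u * rx * shrink; y <- cy + v * ry * shrink
    all_pts <- rbind(pts, placed)
    if (nrow(all_pts) > 0 &&
        any((all_pts[, 1] - x)^2 + (all_pts[, 2] - y)^2 < min_sep^2)) next
    placed <- rbind(placed, c(x, y))
  }
  placed
}

add_spots <- function(img, centers, sigma, intensity) {
  if (nrow(centers) == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * sigma)
  for (k in seq_len(nrow(centers))) {
    x <- centers[k, 1]; y <- centers[k, 2]
    ys <- max(1, floor(y - r)):min(h, ceiling(y + r))
    xs <- max(1, floor(x - r)):min(w, ceiling(x + r))
    d2 <- outer((ys - y)^2, (xs - x)^2, "+")
    img[ys, xs] <- img[ys, xs] + intensity * exp(-d2 / (2 * sigma^2))
  }
  img
}

#' Simulate a multi-channel nuclear focus image
#'
#' Generates a 2D field of elliptical nuclei (DNA-stain channel with smooth
#' interior intensity), a damage channel with Poisson-distributed isotropic
#' Gaussian foci inside each nucleus, and an optional marker channel that
#' shares exactly `round(overlap_fraction * n_foci)` spot centres with the
#' damage channel per nucleus. Planted centres keep a minimum pairwise
#' separation of `2 * focus_sigma + 2` pixels so that ground-truth spots are
#' individually resolvable. Ground truth (nucleus geometry, label mask, spot
#' centres) is returned alongside the pixels.
#'
#' @param shape `c(rows, cols)` of the field in pixels.
#' @param n_nuclei Number of nuclei; they are laid out on a grid and must
#'   fit without touching the field border (an impossible packing is an
#'   explicit error, not a silent truncation).
#' @param foci_per_nucleus Poisson rate of damage foci per nucleus.
#' @param focus_sigma Spot standard deviation, px.
#' @param focus_intensity Spot peak amplitude, arbitrary units.
#' @param noise_sd Additive Gaussian noise s.d. on the damage/marker
#'   channels (the DNA channel receives a fifth of it).
#' @param overlap_fraction NULL for no marker channel; otherwise the
#'   fraction of each nucleus's damage spot centres shared by the marker
#'   channel, in \[0, 1\].
#' @param seed Integer random seed.
#' @return An `image_bundle`: list with channels `dapi`, `damage`,
#'   optionally `marker` (matrices, non-negative), and ground truth:
#'   `labels` (nucleus label matrix), `nuclei` (data frame: `id`, `cx`,
#'   `cy`, `rx`, `ry`, `area_px`), `foci` and `marker_foci` (data frames:
#'   `nucleus`, `x`, `y`, `shared`).
#' @export
simulate_focus_image <- function(shape = c(128, 128), n_nuclei = 1,
                                 foci_per_nucleus = 12, focus_sigma = 1.5,
                                 focus_intensity = 1, noise_sd = 0.1,
                                 overlap_fraction = NULL, seed = 1L) {
  n_nuclei <- assert_count(n_nuclei, "n_nuclei", min = 1L)
  h <- shape[1]; w <- shape[2]
  if (!is.null(overlap_fraction)) {
    assert_scalar_number(overlap_fraction, "overlap_fraction", min = 0)
    if (overlap_fraction > 1) stopf("overlap_fraction must be in [0, 1]")
  }
  k <- ceiling(sqrt(n_nuclei))
  cell_h <- h / k; cell_w <- w / k
  rb <- 0.30 * min(cell_h, cell_w)
  min_sep <- 2 * focus_sigma + 2
  if (rb < max(6, 2 * min_sep))
    stopf("cannot pack %d nuclei with resolvable foci into a %dx%d field",
          n_nuclei, h, w)
  with_seed(seed, {
    dapi <- matrix(0, h, w)
    damage <- matrix(0, h, w)
    marker <- if (!is.null(overlap_fraction)) matrix(0, h, w) else NULL
    labels <- matrix(0L, h, w)
    nuclei <- NULL; foci <- NULL; mfoci <- NULL
    for (i in seq_len(n_nuclei)) {
      gr <- (i - 1) %/% k; gcol <- (i - 1) %% k
      cy <- (gr + 0.5) * cell_h + stats::runif(1, -0.06, 0.06) * cell_h
      cx <- (gcol + 0.5) * cell_w + stats::runif(1, -0.06, 0.06) * cell_w
      rx <- rb * stats::runif(1, 0.85, 1.15)
      ry <- rb * stats::runif(1, 0.85, 1.15)
      if (cx - rx < 2 || cx + rx > w - 1 || cy - ry < 2 || cy + ry > h - 1)
        stopf("nucleus %d does not fit in the field without touching borders", i)
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      e2 <- ((cols - cx) / rx)^2 + ((rows - cy) / ry)^2
      inside <- e2 <= 1
      dapi[inside] <- dapi[inside] + (1 - 0.4 * e2[inside])
      labels[inside] <- i
      nuclei <- rbind(nuclei, data.frame(id = i, cx = cx, cy = cy, rx = rx,
                                         ry = ry, area_px = sum(inside)))
      nf <- stats::rpois(1, foci_per_nucleus)
      ctr <- place_in_ellipse(nf, cx, cy, rx, ry, shrink = 0.75,
                              min_sep = min_sep)
      damage <- add_spots(damage, ctr, focus_sigma, focus_intensity)
      if (nf > 0)
        foci <- rbind(foci, data.frame(nucleus = i, x = ctr[, 1], y = ctr[, 2],
                                       shared = FALSE))
      if (!is.null(overlap_fraction)) {
        n_shared <- round(overlap_fraction * nf)
        shared_ctr <- if (n_shared > 0) ctr[seq_len(n_shared), , drop = FALSE]
                      else matrix(numeric(0), 0, 2)
        extra <- place_in_ellipse(nf - n_shared, cx, cy, rx, ry, shrink = 0.75,
                                  min_sep = min_sep, existing = shared_ctr)
        mc <- rbind(shared_ctr, extra)
        marker <- add_spots(marker, mc, focus_sigma, focus_intensity)
        if (nf > 0) {
          foci$shared[foci$nucleus == i] <- seq_len(nf) <= n_shared
          mfoci <- rbind(mfoci, data.frame(
            nucleus = i, x = mc[, 1], y = mc[, 2],
            shared = seq_len(nrow(mc)) <= n_shared))
        }
      }
    }
    dapi <- pmax(dapi + matrix(stats::rnorm(h * w, 0, noise_sd / 5), h, w), 0)
    damage <- pmax(damage + matrix(stats::rnorm(h * w, 0, noise_sd), h, w), 0)
    if (!is.null(marker))
      marker <- pmax(marker + matrix(stats::rnorm(h * w, 0, noise_sd), h, w), 0)
    if (is.null(foci))
      foci <- data.frame(nucleus = integer(0), x = numeric(0), y = numeric(0),
                         shared = logical(0))
    structure(list(dapi = dapi, damage = damage, marker = marker,
                   labels = labels, nuclei = nuclei, foci = foci,
                   marker_foci = mfoci), class = "image_bundle")
  })
}

#' Segment nuclei from a DNA-stain channel
#'
#' Global Otsu threshold, hole filling, connected components, watershed
#' split of touching nuclei on the distance map, and a minimum-area filter.
#'
#' @param dna 2D matrix (DNA-stain channel).
#' @param min_area Minimum object area in px.
#' @return List with `labels` (integer matrix, 0 = background) and `nuclei`
#'   (data frame: `id`, `area_px`, `dna_intensity` = integrated DNA-stain
#'   intensity). A blank image yields zero nuclei, not an error.
#' @export
segment_nuclei <- function(dna, min_area = 50) {
  if (diff(range(dna)) == 0)
    return(list(labels = matrix(0L, nrow(dna), ncol(dna)),
                nuclei = data.frame(id = integer(0), area_px = integer(0),
                                    dna_intensity = numeric(0))))
  thr <- otsu_threshold(as.vector(dna))
  bw <- EBImage::Image(dna > thr)
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dm, tolerance = 1)
  labm <- EBImage::imageData(lab)
  ids <- setdiff(sort(unique(as.vector(labm))), 0)
  keep <- ids[vapply(ids, function(i) sum(labm == i) >= min_area, TRUE)]
  out <- matrix(0L, nrow(dna), ncol(dna))
  rows <- NULL
  for (j in seq_along(keep)) {
    sel <- labm == keep[j]
    out[sel] <- j
    rows <- rbind(rows, data.frame(id = j, area_px = sum(sel),
                                   dna_intensity = sum(dna[sel])))
  }
  if (is.null(rows))
    rows <- data.frame(id = integer(0), area_px = integer(0),
                       dna_intensity = numeric(0))
  list(labels = out, nuclei = rows)
}

dog_response <- function(damage, focus_sigma) {
  g1 <- EBImage::imageData(EBImage::gblur(EBImage::Image(damage),
                                          sigma = focus_sigma))
  g2 <- EBImage::imageData(EBImage::gblur(EBImage::Image(damage),
                                          sigma = 2 * focus_sigma))
  g1 - g2
}

clipped_mad <- function(v) {
  for (it in 1:4) {
    noise <- stats::mad(v)
    if (noise == 0) break
    v <- v[abs(v - stats::median(v)) < 3 * noise]
  }
  noise
}

#' Detection prominence from a noise region
#'
#' Six times the iteratively clipped MAD of the band-pass response over the
#' given pixels. Evaluated on a spot-free region (e.g. the extranuclear
#' background of the field) this gives a noise floor unbiased by spot
#' density inside busy nuclei.
#'
#' @param damage 2D matrix (damage channel).
#' @param mask Logical matrix of the noise region.
#' @param focus_sigma Band-pass centre scale, px.
#' @return Prominence threshold in the band-pass domain.
#' @export
focus_prominence <- function(damage, mask, focus_sigma = 1.5) {
  resp <- dog_response(damage, focus_sigma)
  6 * max(clipped_mad(resp[mask]), 1e-12)
}

local_maxima <- function(resp, radius) {
  h <- nrow(resp); w <- ncol(resp)
  is_max <- matrix(TRUE, h, w)
  for (dy in -radius:radius) for (dx in -radius:radius) {
    if (dy == 0 && dx == 0) next
    shifted <- matrix(-Inf, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    shifted[ys, xs] <- resp[ys - dy, xs - dx]
    is_max <- is_max & (resp >= shifted)
  }
  is_max
}

#' Detect foci inside a nucleus mask
#'
#' Band-pass (difference-of-Gaussians) filtering inside the mask, local
#' maxima above a prominence threshold, and greedy non-maximum suppression
#' at `min_separation` (two true spots closer than that merge into one
#' detection). Deterministic: candidates are ranked by response with index
#' order breaking ties.
#'
#' @param damage 2D matrix (damage channel).
#' @param mask Logical matrix of the nucleus.
#' @param min_separation Suppression radius, px.
#' @param prominence Response threshold in the band-pass domain; default is
#'   6 times the median absolute deviation of the in-mask response, a
#'   noise-floor estimate robust to a minority of spot pixels.
#' @param focus_sigma Band-pass centre scale, px.
#' @return Data frame: `x`, `y` (pixel coordinates), `response`,
#'   `intensity` (raw damage value at the peak).
#' @export
detect_foci <- function(damage, mask, min_separation = 3, prominence = NULL,
                        focus_sigma = 1.5) {
  if (!any(mask)) stopf("mask is empty")
  resp <- dog_response(damage, focus_sigma)
  if (is.null(prominence)) {
    # noise floor from iteratively clipped MAD of the in-mask response, so
    # that spot pixels do not (much) inflate the threshold; for densely
    # spotted nuclei prefer a spot-free region via [focus_prominence]
    prominence <- 6 * max(clipped_mad(resp[mask]), 1e-12)
  }
  cand <- which(mask & resp > prominence & local_maxima(resp, min_separation))
  if (length(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0),
                      intensity = numeric(0)))
  ord <- cand[order(-resp[cand], cand)]
  ys <- (ord - 1) %% nrow(damage) + 1
  xs <- (ord - 1) %/% nrow(damage) + 1
  keep <- logical(length(ord))
  for (i in seq_along(ord)) {
    if (i == 1 || all((xs[keep] - xs[i])^2 + (ys[keep] - ys[i])^2 >=
                      min_separation^2)) keep[i] <- TRUE
  }
  data.frame(x = xs[keep], y = ys[keep], response = resp[ord][keep],
             intensity = damage[ord][keep])
}

#' Coverage-times-intensity damage index of one nucleus
#'
#' Positive pixels are the in-mask pixels above the threshold; coverage is
#' their percentage of the nuclear area, and the damage index is coverage
#' multiplied by the mean intensity of the positive pixels. With no
#' positive pixels, coverage, mean and index are all 0.
#'
#' @param damage 2D matrix (damage channel).
#' @param mask Logical matrix of the nucleus (non-empty).
#' @param threshold `"otsu"` (computed within the mask) or a fixed
#'   intensity value.
#' @return List with `coverage` (percent), `mean_positive_intensity` and
#'   `index`.
#' @export
damage_index <- function(damage, mask, threshold = "otsu") {
  if (!any(mask)) stopf("mask is empty")
  thr <- if (is.numeric(threshold)) threshold else otsu_threshold(damage[mask])
  pos <- mask & damage > thr
  np <- sum(pos); nm <- sum(mask)
  coverage <- 100 * np / nm
  mpi <- if (np > 0) mean(damage[pos]) else 0
  list(coverage = coverage, mean_positive_intensity = mpi,
       index = coverage * mpi)
}

#' Normalized focus counts
#'
#' Focus count per unit nuclear area and per unit integrated DNA-stain
#' intensity.
#'
#' @param count Focus count.
#' @param area Nuclear area (> 0), px or um^2.
#' @param dna_intensity Integrated DNA-stain intensity (> 0).
#' @return List with `per_area` and `per_dna_intensity`.
#' @export
normalized_counts <- function(count, area, dna_intensity) {
  assert_scalar_number(area, "area", min = 0, strict = TRUE)
  assert_scalar_number(dna_intensity, "dna_intensity", min = 0, strict = TRUE)
  list(per_area = count / area, per_dna_intensity = count / dna_intensity)
}

#' Fraction of nuclei with at least k foci
#'
#' @param counts Vector of per-nucleus focus counts (>= 1 nucleus).
#' @param k Classification threshold, boundary inclusive (default 10).
#' @return Fraction in \[0, 1\].
#' @export
fraction_above_threshold <- function(counts, k = 10) {
  if (length(counts) == 0) stopf("no nuclei")
  mean(counts >= k)
}

#' Per-nucleus quantification of a damage channel
#'
#' Runs [segment_nuclei], then per nucleus [detect_foci], [damage_index]
#' and [normalized_counts].
#'
#' @param dna,damage 2D matrices.
#' @param threshold,min_separation,prominence,focus_sigma Passed through.
#'   When `prominence` is NULL it is computed once from the extranuclear
#'   background of the field ([focus_prominence]), so the detection
#'   threshold does not depend on how densely spotted each nucleus is.
#' @param min_area Minimum nucleus area for segmentation.
#' @return Data frame, one row per nucleus: `id`, `area_px`,
#'   `dna_intensity`, `foci`, `coverage`, `mean_positive_intensity`,
#'   `index`, `foci_per_area`, `foci_per_dna_intensity`.
#' @export
quantify_nuclei <- function(dna, damage, threshold = "otsu",
                            min_separation = 3, prominence = NULL,
                            focus_sigma = 1.5, min_area = 50) {
  seg <- segment_nuclei(dna, min_area = min_area)
  if (is.null(prominence) && any(seg$labels == 0)) {
    prominence <- focus_prominence(damage, seg$labels == 0,
                                   focus_sigma = focus_sigma)
  }
  if (nrow(seg$nuclei) == 0) {
    return(data.frame(id = integer(0), area_px = integer(0),
                      dna_intensity = numeric(0), foci = integer(0),
                      coverage = numeric(0), mean_positive_intensity = numeric(0),
                      index = numeric(0), foci_per_area = numeric(0),
                      foci_per_dna_intensity = numeric(0)))
  }
  do.call(rbind, lapply(seq_len(nrow(seg$nuclei)), function(i) {
    mask <- seg$labels == seg$nuclei$id[i]
    fo <- detect_foci(damage, mask, min_separation = min_separation,
                      prominence = prominence, focus_sigma = focus_sigma)
    di <- damage_index(damage, mask, threshold = threshold)
    nc <- normalized_counts(nrow(fo), seg$nuclei$area_px[i],
                            seg$nuclei$dna_intensity[i])
    data.frame(id = seg$nuclei$id[i], area_px = seg$nuclei$area_px[i],
               dna_intensity = seg$nuclei$dna_intensity[i], foci = nrow(fo),
               coverage = di$coverage,
               mean_positive_intensity = di$mean_positive_intensity,
               index = di$index, foci_per_area = nc$per_area,
               foci_per_dna_intensity = nc$per_dna_intensity)
  }))
}

#' Manders colocalization coefficients
#'
#' `M1` is the fraction of channel-a intensity lying on pixels where
#' channel b exceeds its threshold; `M2` is the symmetric quantity. Both lie
#' in \[0, 1\] for non-negative images.
#'
#' @param channel_a,channel_b 2D matrices of the same shape.
#' @param mask Logical matrix restricting the analysis (non-empty).
#' @param thresholds `c(threshold_a, threshold_b)`; pixels strictly above
#'   count as signal. Default `c(0, 0)`.
#' @return List with `M1` and `M2`.
#' @export
manders <- function(channel_a, channel_b, mask = NULL, thresholds = c(0, 0)) {
  if (!all(dim(channel_a) == dim(channel_b))) stopf("channels differ in shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel_a), ncol(channel_a))
  if (!any(mask)) stopf("mask is empty")
  a <- channel_a[mask]; b <- channel_b[mask]
  if (sum(a) <= 0 || sum(b) <= 0) stopf("a channel has zero total intensity in the mask")
  list(M1 = sum(a[b > thresholds[2]]) / sum(a),
       M2 = sum(b[a > thresholds[1]]) / sum(b))
}

#' Costes randomization test for colocalization
#'
#' Permutes the pixel positions of channel a within the mask `n` times and
#' compares the randomized Manders M1 against the observed value. Ties
#' count against rejection and one is added to numerator and denominator,
#' so `p = (1 + #randomized >= observed) / (n + 1)` is conservative
#' (stochastically >= uniform under the null); its resolution is
#' `1 / (n + 1)`.
#'
#' @param channel_a,channel_b 2D matrices of the same shape.
#' @param mask Logical matrix (non-empty).
#' @param n Number of randomizations (default 1000).
#' @param seed Integer random seed.
#' @param thresholds As in [manders].
#' @return List with `p`, `observed` (M1), `n`.
#' @export
costes_randomization_p <- function(channel_a, channel_b, mask = NULL,
                                   n = 1000, seed = 1L, thresholds = c(0, 0)) {
  n <- assert_count(n, "n", min = 1L)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(channel_a), ncol(channel_a))
  obs <- manders(channel_a, channel_b, mask, thresholds)$M1
  av <- channel_a[mask]
  bsel <- channel_b[mask] > thresholds[2]
  tot <- sum(av)
  nb <- sum(bsel)
  rand <- with_seed(seed, {
    vapply(seq_len(n), function(i) sum(av[sample.int(length(av), nb)]) / tot, 0)
  })
  list(p = (1 + sum(rand >= obs - 1e-12)) / (n + 1), observed = obs, n = n)
}

#' Write / read an image bundle as multi-channel TIFF plus JSON sidecar
#'
#' Channels are stored as 16-bit TIFF frames; each channel is divided by its
#' recorded maximum (kept in the JSON sidecar together with channel names
#' and any ground truth), so intensities are quantized to 1/65535 of the
#' channel maximum. A read image re-written and re-read is bit-identical.
#'
#' @param bundle An `image_bundle` (ground truth, when present, travels in
#'   the sidecar).
#' @param tiff_path,meta_path Output paths.
#' @return `tiff_path` (writer) or the `image_bundle` (reader).
#' @export
write_image_bundle <- function(bundle, tiff_path, meta_path) {
  chans <- Filter(Negate(is.null), list(dapi = bundle$dapi,
                                        damage = bundle$damage,
                                        marker = bundle$marker))
  scales <- vapply(chans, function(m) max(m, 1e-12), 0)
  frames <- lapply(seq_along(chans), function(i) {
    round(chans[[i]] / scales[i] * 65535) / 65535
  })
  tiff::writeTIFF(frames, tiff_path, bits.per.sample = 16L, compression = "none")
  meta <- list(channels = names(chans), scales = as.list(scales),
               nuclei = bundle$nuclei, foci = bundle$foci,
               marker_foci = bundle$marker_foci)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(tiff_path)
}

#' @rdname write_image_bundle
#' @export
read_image_bundle <- function(tiff_path, meta_path) {
  frames <- tiff::readTIFF(tiff_path, all = TRUE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  out <- list(dapi = NULL, damage = NULL, marker = NULL, labels = NULL,
              nuclei = meta$nuclei, foci = meta$foci,
              marker_foci = meta$marker_foci)
  for (i in seq_along(meta$channels)) {
    out[[meta$channels[i]]] <- unname(frames[[i]]) * meta$scales[[i]]
  }
  structure(out, class = "image_bundle")
}
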