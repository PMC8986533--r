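#' Karyotype specification for the single-cell count simulator
#'
#' Describes the ground-truth copy-number landscape of one cell class: a
#' baseline ploidy plus a list of aberrant intervals. A 4n cell at G2/M has
#' completed S phase, so its baseline copy number is 8; under- and
#' over-replicated regions then appear as 7- or 9-copy intervals.
#'
#' @param baseline_ploidy Integer copies per bin for unaffected bins.
#' @param aberrations `NULL` or data frame with columns `chrom`, `start_bin`,
#'   `end_bin` (1-based inclusive bin indices within the chromosome) and `cn`
#'   (integer copy number >= 0). Intervals must not overlap.
#' @param label Free-text label attached to simulated cells.
#' @return A `karyotype_spec` object.
#' @export
karyotype_spec <- function(baseline_ploidy, aberrations = NULL, label = "") {
  baseline_ploidy <- assert_count(baseline_ploidy, "baseline_ploidy", min = 0L)
  if (!is.null(aberrations)) {
    aberrations <- as.data.frame(aberrations)
    need <- c("chrom", "start_bin", "end_bin", "cn")
    if (!all(need %in% names(aberrations)))
      stopf("aberrations needs columns: %s", paste(need, collapse = ", "))
    if (any(aberrations$cn != trunc(aberrations$cn)) || any(aberrations$cn < 0))
      stopf("aberration copy numbers must be integers >= 0")
    if (any(aberrations$end_bin < aberrations$start_bin) || any(aberrations$start_bin < 1))
      stopf("aberration intervals must satisfy 1 <= start_bin <= end_bin")
    for (ch in unique(aberrations$chrom)) {
      ab <- aberrations[aberrations$chrom == ch, ]
      ab <- ab[order(ab$start_bin), ]
      if (nrow(ab) > 1 && any(ab$start_bin[-1] <= ab$end_bin[-nrow(ab)]))
        stopf("aberration intervals overlap on %s", ch)
    }
  }
  structure(list(baseline_ploidy = baseline_ploidy, aberrations = aberrations,
                 label = label), class = "karyotype_spec")
}

#' Ground-truth per-bin copy numbers of a karyotype on a grid
#'
#' @param spec A [karyotype_spec].
#' @param grid A [bin_grid].
#' @return Integer vector of copy numbers, one per bin. Errors if an
#'   aberration references bins outside the grid.
#' @export
truth_states <- function(spec, grid) {
  stopifnot(inherits(spec, "karyotype_spec"))
  cn <- rep.int(spec$baseline_ploidy, nrow(grid))
  ab <- spec$aberrations
  if (!is.null(ab) && nrow(ab) > 0) {
    for (i in seq_len(nrow(ab))) {
      sel <- which(grid$chrom == ab$chrom[i])
      if (length(sel) == 0 || ab$end_bin[i] > length(sel))
        stopf("aberration %d (%s:%d-%d) lies outside the grid", i, ab$chrom[i],
              ab$start_bin[i], ab$end_bin[i])
      cn[sel[ab$start_bin[i]:ab$end_bin[i]]] <- ab$cn[i]
    }
  }
  cn
}

#' Simulation configuration for binned single-cell counts
#'
#' @param depth_per_copy Expected reads per bin per chromosome copy (> 0).
#' @param nb_dispersion Negative-binomial variance inflation (>= 1); at 1 the
#'   counts are Poisson. Default 1.3 models a good-quality single-cell
#'   library with mild overdispersion.
#' @param gc_coefficients Quadratic bias coefficients `c(a0, a1, a2)` mapping
#'   bin GC `g` to the multiplicative factor `a0 + a1*g + a2*g^2`. The default
#'   `c(1, 0, 0)` applies no GC bias.
#' @param wave_amplitude Amplitude `A` in \[0, 1) of a smooth multiplicative
#'   sinusoid `1 + A*sin(2*pi*b/period)` emulating wavy coverage artifacts.
#' @param wave_period Bins per wave cycle. Default 150 (~150 Mb at 1-Mb
#'   bins): wavy artifacts undulate at chromosome-arm scale, slow enough
#'   that segmentation emits spurious whole segments one copy above or
#'   below the expected state rather than averaging the wave away.
#' @param seed Integer random seed; identical seed + config gives identical
#'   output.
#' @return A `sim_config` object.
#' @export
sim_config <- function(depth_per_copy = 10, nb_dispersion = 1.3,
                       gc_coefficients = c(1, 0, 0), wave_amplitude = 0,
                       wave_period = 150, seed = 1L) {
  assert_scalar_number(depth_per_copy, "depth_per_copy", min = 0, strict = TRUE)
  assert_scalar_number(nb_dispersion, "nb_dispersion", min = 1)
  if (length(gc_coefficients) != 3) stopf("gc_coefficients must have length 3")
  assert_scalar_number(wave_amplitude, "wave_amplitude", min = 0)
  if (wave_amplitude >= 1) stopf("wave_amplitude must be < 1")
  assert_scalar_number(wave_period, "wave_period", min = 0, strict = TRUE)
  structure(list(depth_per_copy = depth_per_copy, nb_dispersion = nb_dispersion,
                 gc_coefficients = gc_coefficients,
                 wave_amplitude = wave_amplitude, wave_period = wave_period,
                 seed = as.integer(seed)), class = "sim_config")
}

gc_bias_factor <- function(gc, coef) {
  pmax(coef[1] + coef[2] * gc + coef[3] * gc^2, 0)
}

#' Simulate one cell's binned read counts
#'
#' Per-bin counts are drawn from a negative binomial with mean
#' `depth_per_copy * CN(b) * gc_factor(b) * wave(b)` and variance
#' `nb_dispersion * mean` (Poisson when `nb_dispersion == 1`). The ground-truth
#' copy numbers are retained in the returned library.
#'
#' @param grid A [bin_grid].
#' @param karyotype A [karyotype_spec].
#' @param config A [sim_config].
#' @param cell_id,condition Metadata attached to the library; `condition`
#'   defaults to the karyotype label.
#' @return A `cell_library`: list with `cell_id`, `condition`, `counts`,
#'   `total` and `truth` (per-bin copy numbers plus the generating label).
#' @export
simulate_cell_counts <- function(grid, karyotype, config,
                                 cell_id = "cell1", condition = NULL) {
  stopifnot(inherits(grid, "bin_grid"), inherits(config, "sim_config"))
  if (nrow(grid) == 0) stopf("grid is empty")
  cn <- truth_states(karyotype, grid)
  n <- nrow(grid)
  wave <- 1 + config$wave_amplitude * sin(2 * pi * seq_len(n) / config$wave_period)
  mu <- config$depth_per_copy * cn *
    gc_bias_factor(grid$gc, config$gc_coefficients) * wave
  counts <- with_seed(config$seed, {
    out <- numeric(n)
    pos <- mu > 0
    if (config$nb_dispersion > 1) {
      out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos],
                                 size = mu[pos] / (config$nb_dispersion - 1))
    } else {
      out[pos] <- stats::rpois(sum(pos), mu[pos])
    }
    out
  })
  if (is.null(condition)) condition <- karyotype$label
  structure(list(cell_id = cell_id, condition = condition,
                 counts = as.integer(counts), total = sum(counts),
                 truth = list(cn = cn, label = karyotype$label,
                              baseline_ploidy = karyotype$baseline_ploidy)),
            class = "cell_library")
}

#' Simulate a mixed population of cells
#'
#' @param grid A [bin_grid].
#' @param specs List of `list(spec = <karyotype_spec>, n = <cells>)` entries.
#' @param config A [sim_config]; each cell receives a deterministically
#'   derived child seed so the population is reproducible as a whole.
#' @return List of `cell_library` objects, exactly `n` per spec, in spec
#'   order.
#' @export
simulate_population <- function(grid, specs, config) {
  if (length(specs) == 0) stopf("at least one karyotype spec is required")
  out <- list()
  k <- 0L
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    stopifnot(inherits(sp$spec, "karyotype_spec"))
    n_cells <- assert_count(sp$n, "n", min = 0L)
    for (ci in seq_len(n_cells)) {
      k <- k + 1L
      cfg <- config
      cfg$seed <- derive_seed(config$seed, k)
      out[[k]] <- simulate_cell_counts(
        grid, sp$spec, cfg,
        cell_id = sprintf("cell_%03d", k),
        condition = sp$spec$label
      )
    }
  }
  out
}

#' Write / read a bins-by-cells count matrix as TSV
#'
#' First column `bin` (1-based bin index), one integer column per cell named
#' by cell id.
#'
#' @param libraries List of `cell_library` objects on a common grid.
#' @param path TSV path.
#' @return `path` (writer); list of `cell_library` (reader; `truth` is not
#'   part of the interchange format and comes back `NULL`).
#' @export
write_counts_matrix <- function(libraries, path) {
  mat <- sapply(libraries, function(l) l$counts)
  colnames(mat) <- vapply(libraries, function(l) l$cell_id, "")
  df <- data.frame(bin = seq_len(nrow(mat)), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_matrix
#' @param conditions Optional character vector of condition labels, recycled
#'   across cells, used when reading.
#' @export
read_counts_matrix <- function(path, conditions = "") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  cells <- setdiff(names(df), "bin")
  conditions <- rep_len(conditions, length(cells))
  lapply(seq_along(cells), function(i) {
    counts <- as.integer(df[[cells[i]]])
    structure(list(cell_id = cells[i], condition = conditions[i],
                   counts = counts, total = sum(counts), truth = NULL),
              class = "cell_library")
  })
}

#' Write / read simulation ground truth as JSON
#'
#' @param libraries List of `cell_library` objects carrying `truth`.
#' @param path JSON path.
#' @export
write_truth_json <- function(libraries, path) {
  truth <- lapply(libraries, function(l) {
    list(cell_id = l$cell_id, condition = l$condition,
         baseline_ploidy = l$truth$baseline_ploidy, cn = l$truth$cn)
  })
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
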