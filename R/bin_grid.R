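#' Genomic bin grid
#'
#' A `bin_grid` is the tiling all counts and copy-number calls live on: an
#' ordered data frame of 0-based half-open bins with columns `chrom`, `start`,
#' `end`, `gc` (fraction in \[0,1\]) and `blacklisted` (logical). Bins are
#' sorted by (chromosome, start) and non-overlapping.
#'
#' @param df Data frame with the five columns above.
#' @return The validated data frame with class `bin_grid`.
#' @export
bin_grid <- function(df) {
  need <- c("chrom", "start", "end", "gc", "blacklisted")
  if (!all(need %in% names(df))) stopf("bin grid needs columns: %s", paste(need, collapse = ", "))
  df <- as.data.frame(df)[, need]
  if (any(df$end <= df$start)) stopf("bin grid: all bins must satisfy end > start")
  if (any(df$gc < 0 | df$gc > 1)) stopf("bin grid: gc must lie in [0,1]")
  for (ch in unique(df$chrom)) {
    b <- df[df$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE)) stopf("bin grid: bins on %s not sorted", ch)
    if (any(b$start[-1] < b$end[-nrow(b)])) stopf("bin grid: overlapping bins on %s", ch)
  }
  df$blacklisted <- as.logical(df$blacklisted)
  class(df) <- c("bin_grid", "data.frame")
  df
}

#' Build a contiguously tiled toy genome
#'
#' Fixed-width bins tiled contiguously per chromosome (0-based half-open, BED
#' convention). GC content follows a deterministic, seed-free smooth profile
#' in \[0.3, 0.6\]; no bins are blacklisted.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param bins_per_chromosome Bins per chromosome (>= 1).
#' @param bin_width Bin width in bp (>= 1).
#' @return A [bin_grid].
#' @examples
#' g <- make_toy_genome(3, 100, 1e6)
#' nrow(g)  # 300
#' @export
make_toy_genome <- function(n_chromosomes, bins_per_chromosome, bin_width) {
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes")
  bins_per_chromosome <- assert_count(bins_per_chromosome, "bins_per_chromosome")
  bin_width <- assert_count(bin_width, "bin_width")
  n <- n_chromosomes * bins_per_chromosome
  chrom <- rep(paste0("chr", seq_len(n_chromosomes)), each = bins_per_chromosome)
  start <- rep.int(bin_width * (seq_len(bins_per_chromosome) - 1L), n_chromosomes)
  idx <- seq_len(n)
  # deterministic GC profile, bounded in [0.3, 0.6]: slow isochore-scale
  # drift plus fine-scale texture, so GC is not spatially confounded with
  # any one segment of the genome
  gc <- 0.45 + 0.07 * sin(2 * pi * idx / 173) + 0.05 * sin(2 * pi * idx / 19) +
    0.03 * sin(2 * pi * idx / 7)
  gc <- pmin(0.6, pmax(0.3, gc))
  bin_grid(data.frame(
    chrom = chrom, start = start, end = start + bin_width,
    gc = gc, blacklisted = FALSE, stringsAsFactors = FALSE
  ))
}

bin_widths <- function(grid) grid$end - grid$start

same_grid <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) && all(a$start == b$start) &&
    all(a$end == b$end)
}

#' Write / read a bin grid as BED-like TSV
#'
#' Columns: chrom, start, end, gc, blacklisted. Full float precision is kept
#' so the round trip is exact.
#'
#' @param grid A [bin_grid].
#' @param path Output TSV path.
#' @return `path` (writer) or the [bin_grid] (reader).
#' @export
write_bin_grid <- function(grid, path) {
  write_table_full(as.data.frame(grid), path)
}

#' @rdname write_bin_grid
#' @export
read_bin_grid <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  bin_grid(df)
}
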