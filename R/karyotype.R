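#' Aneuploidy score and aneuploid genome fraction of one cell
#'
#' The aneuploidy score is the length-weighted mean over defined bins of
#' `|state - ploidy|`; the aneuploid fraction is the length-weighted
#' fraction of the genome whose state differs from the expected ploidy.
#'
#' @param profile A [cn_profile] with assigned states.
#' @param ploidy Expected ploidy; defaults to the profile's ground ploidy.
#' @return List with `score` (>= 0, 0 iff perfectly euploid) and
#'   `aneuploid_fraction` (in \[0, 1\]).
#' @export
aneuploidy_score <- function(profile, ploidy = profile$ploidy) {
  keep <- !is.na(profile$states)
  if (!any(keep)) stopf("profile has no defined states")
  w <- bin_widths(profile$grid)[keep]
  st <- profile$states[keep]
  list(score = sum(w * abs(st - ploidy)) / sum(w),
       aneuploid_fraction = sum(w * (st != ploidy)) / sum(w))
}

#' Cell-to-cell karyotype heterogeneity
#'
#' Simpson-type diversity per bin: `1 - sum_s f_s^2`, where `f_s` is the
#' fraction of cells in state `s` at that bin; 0 when all cells agree,
#' approaching `1 - 1/n_states` when states are evenly split. The
#' genome-wide value is the length-weighted mean across bins.
#'
#' @param profiles List of >= 2 [cn_profile]s on a shared grid.
#' @return List with `per_bin` (NA where no cell has a defined state) and
#'   `mean` (genome-wide, length-weighted).
#' @export
heterogeneity_score <- function(profiles) {
  if (length(profiles) < 2) stopf("heterogeneity requires >= 2 profiles")
  g <- profiles[[1]]$grid
  for (p in profiles) if (!same_grid(p$grid, g)) stopf("profiles are on different grids")
  mat <- state_matrix(profiles)
  per_bin <- apply(mat, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(NA_real_)
    f <- table(col) / length(col)
    1 - sum(f^2)
  })
  keep <- !is.na(per_bin)
  w <- bin_widths(g)[keep]
  list(per_bin = per_bin, mean = sum(w * per_bin[keep]) / sum(w))
}

#' State matrix of a set of profiles
#'
#' @param profiles List of [cn_profile]s on a shared grid.
#' @return Numeric matrix, one row per cell (named by row order), one
#'   column per bin.
#' @export
state_matrix <- function(profiles) {
  mat <- t(vapply(profiles, function(p) p$states, numeric(nrow(profiles[[1]]$grid))))
  rownames(mat) <- paste0("cell", seq_along(profiles))
  mat
}

#' Genome-wide copy-number heatmap
#'
#' One row per cell in the given order (no clustering), bins in genome
#' order, discrete color per integer state. The underlying state matrix is
#' also written as TSV when `matrix_path` is given, providing a bit-exact
#' test surface next to the rendered figure.
#'
#' @param profiles List of >= 1 [cn_profile]s on a shared grid.
#' @param grid The shared [bin_grid].
#' @param path Output PNG path.
#' @param matrix_path Optional TSV path for the state matrix.
#' @param max_state Top of the color scale; defaults to the observed
#'   maximum.
#' @return The state matrix, invisibly.
#' @export
plot_genome_heatmap <- function(profiles, grid, path, matrix_path = NULL,
                                max_state = NULL) {
  if (length(profiles) == 0) stopf("no profiles to plot")
  mat <- state_matrix(profiles)
  if (is.null(max_state)) max_state <- max(mat, na.rm = TRUE)
  pal <- grDevices::hcl.colors(max_state + 1, "RdBu", rev = TRUE)
  grDevices::png(path, width = 1000, height = 120 + 14 * nrow(mat))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 6), xpd = TRUE)
  graphics::image(x = seq_len(ncol(mat)), y = seq_len(nrow(mat)),
                  z = t(mat[rev(seq_len(nrow(mat))), , drop = FALSE]),
                  zlim = c(0, max_state), col = pal,
                  xlab = "bin (genome order)", ylab = "cell", axes = FALSE)
  graphics::axis(1)
  bks <- cumsum(rle(as.character(grid$chrom))$lengths)
  graphics::abline(v = bks[-length(bks)] + 0.5, col = "grey30", xpd = FALSE)
  graphics::legend("topright", inset = c(-0.06, 0), legend = 0:max_state,
                   fill = pal, title = "state", cex = 0.7, bty = "n")
  if (!is.null(matrix_path)) {
    utils::write.table(mat, matrix_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(mat)
}
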