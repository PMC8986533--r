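#!/usr/bin/env Rscript
# Curate the G2/M tetraploid libraries (dual-caller concordance >= 0.90 for
# polyploid samples, >= 10 reads per chromosome copy per bin, wavy-pattern
# filter at the 0.25 non-rounded deviation cut-off), then score retained
# cells for aneuploidy, aneuploid genome fraction and cell-to-cell
# heterogeneity, and render the genome-wide copy-number heatmap.

suppressMessages(library(wgdqc))

grid <- read_bin_grid("results/bins.tsv")
g1 <- read_counts_matrix("results/counts_g1_reference.tsv", conditions = "4n G1")
grid <- build_blacklist(g1, grid, mad_factor = 4)
reference <- rowMeans(sapply(g1, function(l) l$counts))

cells <- c(read_counts_matrix("results/counts_g2m_clean.tsv",
                              conditions = "4n G2/M clean"),
           read_counts_matrix("results/counts_g2m_aberrant.tsv",
                              conditions = "4n G2/M"))

reports <- list()
profiles <- list()
for (i in seq_along(cells)) {
  calls <- call_copy_number(cells[[i]], grid, reference = reference,
                            ploidy = 8, ploidy_bounds = c(7.5, 8.5),
                            max_state = 10)
  reports[[i]] <- curate_library(cells[[i]], calls$changepoint, calls$hmm,
                                 "8n", corrected = calls$corrected)
  profiles[[i]] <- calls$changepoint
}
summ <- cohort_summary(reports)
write.table(summ, "results/curation_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("curation kept %d of %d libraries\n",
            sum(summ$decision == "keep"), nrow(summ)))

kept <- summ$decision == "keep"
scored <- profiles[kept]
scores <- do.call(rbind, lapply(seq_along(scored), function(i) {
  a <- aneuploidy_score(scored[[i]], ploidy = 8)
  data.frame(cell_id = summ$cell_id[kept][i],
             condition = cells[kept][[i]]$condition,
             aneuploidy = a$score, aneuploid_fraction = a$aneuploid_fraction)
}))
write.table(scores, "results/karyotype_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
if (sum(kept) >= 2) {
  het <- heterogeneity_score(scored)
  cat(sprintf("population heterogeneity (kept cells): %.4f\n", het$mean))
  keepb <- !is.na(het$per_bin)
  write.table(data.frame(chrom = grid$chrom[keepb], start = grid$start[keepb],
                         end = grid$end[keepb],
                         heterogeneity = het$per_bin[keepb]),
              "results/heterogeneity_per_bin.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
}
by_cond <- aggregate(cbind(aneuploidy, aneuploid_fraction) ~ condition,
                     scores, mean)
print(by_cond)

plot_genome_heatmap(scored, grid, "results/karyotype_heatmap.png",
                    matrix_path = "results/state_matrix.tsv", max_state = 10)
cat("wrote results/karyotype_heatmap.png and the exact state matrix\n")
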