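#!/usr/bin/env Rscript
# Simulate the single-cell sequencing arm of the study: G1 tetraploid
# control libraries (the reference pool), clean G2/M tetraploid cells, and
# G2/M tetraploid cells carrying under-/over-replicated territories
# (7 and 9 copies on an 8-copy background), on a ~3,000-bin 1-Mb tiling.
# Writes the bin grid, count matrices and ground truth under results/.

suppressMessages(library(wgdqc))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

dir.create("results", showWarnings = FALSE)
grid <- make_toy_genome(3, 1000, 1e6)
write_bin_grid(grid, "results/bins.tsv")

# G1 tetraploid reference pool (4 copies per bin, euploid)
g1_spec <- karyotype_spec(4, label = "4n G1")
g1 <- simulate_population(grid, list(list(spec = g1_spec, n = 10)),
                          sim_config(depth_per_copy = 12, seed = seed))
write_counts_matrix(g1, "results/counts_g1_reference.tsv")

# clean G2/M tetraploid cells: completed S phase, 8 copies per bin
clean_spec <- karyotype_spec(8, label = "4n G2/M")
clean <- simulate_population(grid, list(list(spec = clean_spec, n = 10)),
                             sim_config(depth_per_copy = 12, seed = seed + 1L))
write_counts_matrix(clean, "results/counts_g2m_clean.tsv")
write_truth_json(clean, "results/truth_g2m_clean.json")

# aberrant G2/M tetraploid cells: 1-3 random 7n/9n territories each
specs <- random_tetraploid_karyotypes(10, grid, baseline = 8, seed = seed + 2L)
aberrant <- lapply(seq_along(specs), function(i) {
  simulate_cell_counts(grid, specs[[i]],
                       sim_config(depth_per_copy = 12, seed = seed + 100L + i),
                       cell_id = sprintf("cell_%03d", i))
})
write_counts_matrix(aberrant, "results/counts_g2m_aberrant.tsv")
write_truth_json(aberrant, "results/truth_g2m_aberrant.json")

cat(sprintf("wrote %d G1 reference, %d clean and %d aberrant G2/M libraries (%d bins)\n",
            length(g1), length(clean), length(aberrant), nrow(grid)))
cat(sprintf("mean total reads, aberrant arm: %.0f (minimum for 8n: %d)\n",
            mean(vapply(aberrant, function(l) as.numeric(l$total), 0)),
            min_required_reads(8, nrow(grid))))
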