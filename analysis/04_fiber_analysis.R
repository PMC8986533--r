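#!/usr/bin/env Rscript
# DNA-combing readouts: simulate a control-like arm and a perturbed arm with
# slower forks and frequent second-pulse stalling, then compute fork speed
# (combined CldU+IdU track length over total label time), CldU/IdU
# asymmetry and inter-origin distances.

suppressMessages(library(wgdqc))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

dir.create("results", showWarnings = FALSE)

arms <- list(
  control = simulate_fibers(350, speed_mean = 1.5, speed_sd = 0.3,
                            stall_probability = 0.05, iod_mean = 200,
                            seed = seed),
  perturbed = simulate_fibers(350, speed_mean = 1.8, speed_sd = 0.4,
                              stall_probability = 0.35, iod_mean = 240,
                              seed = seed + 1L)
)

summary_list <- lapply(names(arms), function(arm) {
  fs <- arms[[arm]]
  write_fibers(fs, sprintf("results/fibers_%s_tracks.csv", arm),
               sprintf("results/fibers_%s_origins.csv", arm))
  fm <- fork_metrics(fs)
  write.table(fm$metrics, sprintf("results/forks_%s.tsv", arm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- summarize_forks(fm)
  iod <- inter_origin_distances(fs)
  cat(sprintf("%s: n=%d forks, median speed %.2f kb/min, median CldU/IdU %.2f, mean IOD %.0f kb (n=%d)\n",
              arm, s$n, s$median_speed, s$median_ratio, mean(iod), length(iod)))
  list(arm = arm, n_forks = s$n, median_speed_kb_min = s$median_speed,
       mean_speed_kb_min = s$mean_speed, median_cldu_idu_ratio = s$median_ratio,
       mean_iod_kb = mean(iod), n_iod = length(iod),
       stretch_kb_per_um = fs$stretch, pulse_minutes = fs$pulse_minutes)
})
jsonlite::write_json(summary_list, "results/fiber_summary.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote per-fork tables, fiber CSVs and results/fiber_summary.json\n")
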