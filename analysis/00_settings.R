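# Shared settings for the analysis drivers: one synthetic "discovery cohort"
# whose structure mirrors the study design (65 subjects x 4 control-subtracted
# conditions, 60 single trials per task), scaled to a 16^3 grid so every
# driver runs in minutes on one CPU.

library(painsig)

SEED <- 1L
OUT <- "results"
dir.create(OUT, showWarnings = FALSE, recursive = TRUE)

# High-contrast regime (per-image noise norm below the signal norm) so the
# desk-scale cohort operates near the ceiling performance the full-scale
# analyses are designed for.
cohort_truth <- function(seed = SEED) {
  synthetic_truth(grid_shape = c(16L, 16L, 16L), subject_count = 65L,
                  rho_shared = 0.5, noise_sd = 0.05,
                  trial_counts = c(Ex = 60L, Sep = 60L), seed = seed)
}

tsv <- function(df, name) {
  path <- file.path(OUT, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
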