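#!/usr/bin/env Rscript
# Rating-stratified forced choice: can the pairwise decoder separate the two
# conditions when trials are matched on subjective rating? Run under the
# amplitude-coupled generator (condition-specific signal scales with the
# rated expression: accuracy should climb with rating) and the
# constant-offset generator (flat profile).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_settings.R"))

for (mode in c("amplitude", "additive")) {
  truth <- synthetic_truth(grid_shape = c(10L, 10L, 10L), subject_count = 65L,
                           noise_sd = 2.5, trial_counts = c(Ex = 60L, Sep = 60L),
                           signal_mode = mode, additive_scale = 4,
                           rating_link = list(intercept = 0, slope = 3,
                                              noise_sd = 0.3),
                           seed = SEED)
  model <- linear_pattern_model(truth$patterns[, "Ex"] -
                                  truth$patterns[, "Sep"])
  rep <- stratified_forced_choice(generate_trial_stack(truth), "Ex", "Sep",
                                  model = model)
  tab <- stratified_accuracy_table(rep)
  message(sprintf("signal_mode = %s:", mode))
  print(tab, digits = 3)
  tsv(tab, sprintf("07_rating_levels_%s.tsv", mode))
}
message("done: rating-level profiles written")
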