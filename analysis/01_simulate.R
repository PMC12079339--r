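#!/usr/bin/env Rscript
# Simulate the synthetic discovery cohort: contrast images (one per subject
# per control-subtracted condition), single-trial images with 1-5 ratings,
# and a 24-ROI / 7-network parcellation. Writes NIfTI + TSV under results/.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_settings.R"))

truth <- cohort_truth()
print(truth)

contrasts <- generate_contrast_stack(truth)
trials <- generate_trial_stack(truth)
parc <- generate_parcellation(truth, n_rois = 24, n_networks = 7)

message(sprintf("contrast stack: %d images (%d subjects x %d conditions)",
                nrow(contrasts$data), truth$subject_count,
                length(truth$conditions)))
message(sprintf("trial stack: %d images; rating distribution:",
                nrow(trials$data)))
print(table(trials$obs_meta$rating))

dir.create(file.path(OUT, "data"), showWarnings = FALSE)
write_stack(contrasts, file.path(OUT, "data", "contrasts"))
write_stack(trials, file.path(OUT, "data", "trials"))
write_parcellation(parc, file.path(OUT, "data", "parcellation"))
tsv(data.frame(condition = truth$conditions,
               amplitude_mean = truth$amplitude_mean),
    "01_condition_amplitudes.tsv")
message("done: synthetic cohort written under results/data/")
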