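#!/usr/bin/env Rscript
# Identify the exclusion decoder's core system: bootstrap the SVM weights
# over subjects (backward model, z/p + FDR), Haufe-transform the weights
# into structure coefficients with a group t-test (forward model), and take
# the conjunction.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_settings.R"))

truth <- cohort_truth()
contrasts <- generate_contrast_stack(truth)
negatives <- setdiff(truth$conditions, "Ex")

model <- train_signature(contrasts, "Ex", negatives, C = 1)
bmap <- bootstrap_weights(contrasts, "Ex", negatives, C = 1,
                          n_boot = 500, q = 0.05, seed = SEED + 200)
emap <- haufe_encode(contrasts, model, q = 0.05)
core <- conjunction_core(bmap, emap, model)
print(bmap); print(emap); print(core)

top <- order(abs(truth$patterns[, "Ex"]),
             decreasing = TRUE)[seq_len(ceiling(0.1 * ncol(contrasts$data)))]
message(sprintf("top-decile true-pattern voxels captured by the core mask: %.1f%%",
                100 * mean(core$mask[top])))

tsv(data.frame(voxel = contrasts$voxel_index, weight = model$weights,
               boot_z = bmap$z, boot_p = bmap$p,
               boot_sig = bmap$significant,
               encoding_t = emap$t, encoding_sig = emap$significant,
               core = core$mask, core_weight = core$weights),
    "05_core_system_voxels.tsv")
message("done: core-system maps written")
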