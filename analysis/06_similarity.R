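#!/usr/bin/env Rscript
# Decompose the exclusion and separation signatures over the synthetic
# 7-network / 24-ROI parcellation: rectified cosine similarity per region
# (ribbons normalized to the maximum) and per-region contribution shares by
# voxel-wise argmax.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_settings.R"))

truth <- cohort_truth()
contrasts <- generate_contrast_stack(truth)
parc <- generate_parcellation(truth, 24, 7)

psse <- train_signature(contrasts, "Ex", setdiff(truth$conditions, "Ex"))
psss <- train_signature(contrasts, "Sep", setdiff(truth$conditions, "Sep"))

for (lvl in c("network", "roi")) {
  sim <- rbind(cbind(model = "PSSE", regional_cosine(psse, parc, lvl)),
               cbind(model = "PSSS", regional_cosine(psss, parc, lvl)))
  shares <- contribution_shares(list(PSSE = psse, PSSS = psss), parc, lvl)
  tsv(sim, sprintf("06_similarity_%s.tsv", lvl))
  tsv(shares, sprintf("06_contribution_%s.tsv", lvl))
}
message("done: similarity decompositions written")
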