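#!/usr/bin/env Rscript
# Train the four linear-SVM signatures on the discovery cohort's contrast
# images: one-vs-all decoders for exclusion (PSSE) and separation (PSSS),
# the pairwise exclusion-vs-separation decoder (PSSEvS), and the combined
# pain-vs-control decoder (PSSEaS). Weight maps go to results/decoders/.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE), value = TRUE))), "00_settings.R"))

truth <- cohort_truth()
contrasts <- generate_contrast_stack(truth)
conds <- truth$conditions

models <- list(
  PSSE = train_signature(contrasts, "Ex", setdiff(conds, "Ex"), C = 1),
  PSSS = train_signature(contrasts, "Sep", setdiff(conds, "Sep"), C = 1),
  PSSEvS = train_signature(contrasts, "Ex", "Sep", C = 1),
  PSSEaS = train_signature(contrasts, c("Ex", "Sep"), c("Inc", "Com"), C = 1))

dir.create(file.path(OUT, "decoders"), showWarnings = FALSE)
for (nm in names(models))
  write_signature(models[[nm]], contrasts, file.path(OUT, "decoders", nm))

recov <- data.frame(
  model = names(models),
  truth_cosine = c(
    cosine_sim(models$PSSE$weights, truth$patterns[, "Ex"]),
    cosine_sim(models$PSSS$weights, truth$patterns[, "Sep"]),
    cosine_sim(models$PSSEvS$weights,
               truth$patterns[, "Ex"] - truth$patterns[, "Sep"]),
    cosine_sim(models$PSSEaS$weights,
               truth$patterns[, "Ex"] + truth$patterns[, "Sep"])))
print(recov)
tsv(recov, "03_decoder_truth_cosine.tsv")
message("done: 4 signatures written under results/decoders/")
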