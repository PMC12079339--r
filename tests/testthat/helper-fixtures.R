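# Small synthetic truths and hand-built stacks shared across tests.

small_truth <- function(..., seed = 1) {
  args <- list(...)
  defaults <- list(grid_shape = c(10L, 10L, 10L), subject_count = 12L,
                   noise_sd = 0.5, trial_counts = c(Ex = 10L, Sep = 10L),
                   seed = seed)
  do.call(synthetic_truth, utils::modifyList(defaults, args))
}

# Stack over a flat 1-D voxel "grid" (V x 1 x 1), handy for hand-set data.
vector_stack <- function(data, condition, subject, rating = NULL) {
  data <- as.matrix(data)
  mask <- array(TRUE, dim = c(ncol(data), 1L, 1L))
  meta <- data.frame(subject = subject, condition = condition,
                     stringsAsFactors = FALSE)
  if (!is.null(rating)) meta$rating <- rating
  masked_image_stack(data, mask, meta)
}

# Brute-force BH step-up used as the independent FDR oracle.
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  sig <- logical(m)
  if (length(k)) sig[p <= ps[max(k)]] <- TRUE
  sig
}
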