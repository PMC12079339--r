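test_that("condition patterns are unit norm with the configured shared cosine", {
  for (rho in c(0.3, 0.5, 0.9)) {
    tr <- small_truth(rho_shared = rho, seed = 4)
    expect_equal(unname(sqrt(colSums(tr$patterns^2))),
                 rep(1, 4), tolerance = 1e-12)
    expect_equal(cosine_sim(tr$patterns[, "Ex"], tr$patterns[, "Sep"]),
                 rho^2, tolerance = 1e-10)
    expect_equal(cosine_sim(tr$patterns[, "Ex"], tr$patterns[, "Inc"]),
                 rho^2, tolerance = 1e-10)
  }
  tr <- small_truth()
  expect_gt(sum(tr$mask), 0)
  expect_equal(cosine_sim(tr$mediator_pattern, tr$patterns[, "Ex"]),
               tr$mediator_overlap, tolerance = 1e-10)
})

test_that("truth construction rejects invalid settings", {
  expect_error(small_truth(noise_sd = -1), "noise_sd")
  expect_error(small_truth(rho_shared = 1.5), "rho_shared")
  expect_error(small_truth(pain_conditions = "Nope"), "subset")
})

test_that("noiseless contrast stack reproduces the patterns exactly", {
  tr <- small_truth(noise_sd = 0, pattern_amplitude_sd = 0, subject_count = 3)
  cs <- generate_contrast_stack(tr)
  ex_rows <- cs$data[cs$obs_meta$condition == "Ex", , drop = FALSE]
  for (i in seq_len(nrow(ex_rows)))
    expect_equal(unname(ex_rows[i, ]), unname(tr$patterns[, "Ex"]),
                 tolerance = 1e-12)
  inc_rows <- cs$data[cs$obs_meta$condition == "Inc", , drop = FALSE]
  expect_equal(max(abs(inc_rows)), 0)
})

test_that("contrast stack is deterministic and sized subjects x conditions", {
  tr <- small_truth(seed = 9)
  s1 <- generate_contrast_stack(tr)
  s2 <- generate_contrast_stack(tr)
  expect_identical(s1$data, s2$data)
  # the full design: 65 subjects x 4 control-subtracted conditions
  tr65 <- synthetic_truth(seed = 2)
  cs <- generate_contrast_stack(tr65)
  expect_equal(nrow(cs$data), 260L)
  expect_equal(nrow(cs$obs_meta), 260L)
})

test_that("subject substreams make subject subsets reproducible", {
  tr_big <- small_truth(subject_count = 10, seed = 5)
  tr_sml <- small_truth(subject_count = 4, seed = 5)
  big <- generate_contrast_stack(tr_big)
  sml <- generate_contrast_stack(tr_sml)
  keep <- big$obs_meta$subject %in% unique(sml$obs_meta$subject)
  expect_identical(big$data[keep, ], sml$data)
})

test_that("empirical noise SD converges to the configured value", {
  tr <- small_truth(subject_count = 30, noise_sd = 1.3,
                    pattern_amplitude_mean = 0, pattern_amplitude_sd = 0,
                    seed = 6)
  cs <- generate_contrast_stack(tr)
  n <- length(cs$data)
  se <- 1.3 / sqrt(2 * n)
  expect_lt(abs(stats::sd(cs$data) - 1.3), 3 * se)
})

test_that("trial stack carries 60+60 trials per subject with valid ratings", {
  tr <- small_truth(subject_count = 3, trial_counts = c(Ex = 60L, Sep = 60L))
  ts <- generate_trial_stack(tr)
  expect_equal(nrow(ts$data), 3 * 120)
  per_sub <- table(ts$obs_meta$subject)
  expect_true(all(per_sub == 120))
  expect_true(all(ts$obs_meta$rating %in% 1:5))
  ts2 <- generate_trial_stack(tr)
  expect_identical(ts$obs_meta$rating, ts2$obs_meta$rating)
  expect_identical(ts$data, ts2$data)
})

test_that("trial generation rejects empty conditions", {
  tr <- small_truth(trial_counts = c(Ex = 0L, Sep = 5L))
  expect_error(generate_trial_stack(tr), "zero trials")
  tr2 <- small_truth()
  tr2$trial_counts <- NULL
  expect_error(generate_trial_stack(tr2), "trial_counts")
})

test_that("noiseless rating link is monotone in trial expression", {
  tr <- small_truth(subject_count = 4,
                    rating_link = list(intercept = 0, slope = 2,
                                       noise_sd = 0))
  ts <- generate_trial_stack(tr)
  expr <- attr(ts, "expression")
  r_sorted <- ts$obs_meta$rating[order(expr)]
  expect_true(all(diff(r_sorted) >= 0))
})

test_that("rating distribution shifts upward with the link slope", {
  means <- vapply(c(0.5, 1.5, 3), function(sl) {
    tr <- small_truth(subject_count = 8,
                      trial_counts = c(Ex = 30L, Sep = 30L),
                      rating_link = list(intercept = 0, slope = sl,
                                         noise_sd = 1), seed = 11)
    mean(generate_trial_stack(tr)$obs_meta$rating)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("default rating marginal is skewed toward rating 1", {
  tr <- small_truth(subject_count = 10, trial_counts = c(Ex = 60L, Sep = 60L),
                    seed = 3)
  counts <- table(factor(generate_trial_stack(tr)$obs_meta$rating,
                         levels = 1:5))
  expect_true(all(diff(as.integer(counts)) <= 0))
  expect_gt(counts[[1]] / sum(counts), 0.35)
})

test_that("parcellation partitions the mask with consistent label tables", {
  tr <- small_truth()
  p <- generate_parcellation(tr, 24, 7)
  expect_equal(nrow(p$roi_table), 24)
  expect_equal(nrow(p$network_table), 7)
  V <- sum(tr$mask)
  expect_equal(length(p$roi), V)
  expect_true(all(sort(unique(p$roi)) == 1:24))
  expect_true(all(table(p$roi) >= 1))
  # many-to-one ROI -> network
  expect_true(all(tapply(p$network, p$roi,
                         function(x) length(unique(x))) == 1))
  p1 <- generate_parcellation(tr, 1, 1)
  expect_true(all(p1$roi == 1))
  expect_error(generate_parcellation(tr, sum(tr$mask) + 1, 1), "exceeds")
  expect_error(generate_parcellation(tr, 3, 5), "n_rois >= n_networks")
})

test_that("time-series generator supports TR = 2 s and is deterministic", {
  tr <- small_truth(subject_count = 2, grid_shape = c(8, 8, 8))
  ev <- data.frame(onset = c(10, 40), duration = 12,
                   trial_type = c("Ex", "Inc"))
  s1 <- generate_timeseries(tr, ev, tr_s = 2)
  s2 <- generate_timeseries(tr, ev, tr_s = 2)
  expect_identical(s1$bold, s2$bold)
  expect_equal(ncol(s1$motion), 6)
  expect_equal(dim(s1$bold)[4], s1$n_scans)
  expect_error(generate_timeseries(tr, ev, tr_s = 0), "positive")
  expect_error(generate_timeseries(tr, ev, tr_s = 2, n_scans = 5),
               "beyond the scan duration")
})
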