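two_point_stack <- function() {
  vector_stack(rbind(c(1, 1), c(-1, -1), c(1, 1), c(-1, -1)),
               condition = rep(c("A", "B"), 2),
               subject = rep(c("s1", "s2"), each = 2))
}

test_that("SVM matches the hard-margin analytic solution on the 2-point toy", {
  st <- two_point_stack()
  m <- train_signature(st, "A", "B", C = 1)
  # maximal-margin hyperplane through (1,1) vs (-1,-1): w = (1/2, 1/2), b = 0
  expect_equal(m$weights, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(m$intercept, 0, tolerance = 1e-6)
})

test_that("swapping label sets negates the signature", {
  st <- two_point_stack()
  m1 <- train_signature(st, "A", "B")
  m2 <- train_signature(st, "B", "A")
  expect_equal(m1$weights, -m2$weights, tolerance = 1e-8)
  expect_equal(m1$intercept, -m2$intercept, tolerance = 1e-8)
})

test_that("training validates condition sets and subject completeness", {
  st <- two_point_stack()
  expect_error(train_signature(st, "A", "A"), "overlap")
  expect_error(train_signature(st, character(0), "B"), "non-empty")
  st2 <- vector_stack(rbind(c(1, 1), c(-1, -1), c(1, 1)),
                      condition = c("A", "B", "A"),
                      subject = c("s1", "s1", "s2"))
  expect_error(train_signature(st2, "A", "B"), "s2")
})

test_that("high-SNR signatures recover the generating discriminative direction", {
  tr <- small_truth(subject_count = 20, noise_sd = 0.02, seed = 2)
  cs <- generate_contrast_stack(tr)
  m <- train_signature(cs, "Ex", c("Inc", "Sep", "Com"))
  # class-mean difference = pattern_Ex (controls have zero mean amplitude)
  expect_gt(cosine_sim(m$weights, tr$patterns[, "Ex"]), 0.8)
  m2 <- train_signature(cs, "Ex", "Sep")
  expect_gt(cosine_sim(m2$weights,
                       tr$patterns[, "Ex"] - tr$patterns[, "Sep"]), 0.8)
})

test_that("pattern response is the (optionally shifted) dot product", {
  w <- c(3, -1, 2)
  m <- linear_pattern_model(w, intercept = 0.7)
  st <- vector_stack(rbind(w / sum(w^2), 0, c(1, 1, 1), c(2, 0, 0)),
                     condition = c("a", "a", "b", "b"),
                     subject = c("s1", "s2", "s1", "s2"))
  r0 <- pattern_response(m, st)
  r1 <- pattern_response(m, st, use_intercept = TRUE)
  expect_equal(r0[1], 1)
  expect_equal(r0[2], 0)
  expect_equal(r1[2], 0.7)
  # additivity: r(x1 + x2) = r(x1) + r(x2) - b with intercepts
  x12 <- vector_stack(st$data[3, , drop = FALSE] + st$data[4, , drop = FALSE],
                      "c", "s1")
  expect_equal(pattern_response(m, x12, TRUE),
               r1[3] + r1[4] - m$intercept, tolerance = 1e-12)
})

test_that("pattern response refuses mismatched voxel spaces", {
  m <- linear_pattern_model(c(1, 2))
  st <- vector_stack(matrix(1, 2, 3), c("a", "a"), c("s1", "s2"))
  expect_error(pattern_response(m, st), "resample")
})

test_that("forced choice scores separated subjects at 100% and is symmetric", {
  set.seed(5)
  n <- 12
  da <- matrix(rnorm(n * 4, mean = 2), n)
  db <- matrix(rnorm(n * 4, mean = 0), n)
  st <- vector_stack(rbind(da, db),
                     condition = rep(c("hi", "lo"), each = n),
                     subject = rep(sprintf("s%02d", 1:n), 2))
  m <- linear_pattern_model(rep(1, 4))
  rpt <- forced_choice(m, st, "hi", "lo")
  expect_equal(rpt$accuracy, 100)
  expect_lt(rpt$p_value, 0.001)
  expect_gt(rpt$auc, 0.95)
  swapped <- forced_choice(m, st, "lo", "hi")
  expect_equal(swapped$accuracy, 0)
  expect_equal(swapped$auc, 1 - rpt$auc, tolerance = 1e-12)
  expect_error(forced_choice(m, st, "hi", "nope"), "lacking")
})

test_that("tied responses are credited half and excluded from the binomial test", {
  # identical images for both conditions: responses tie exactly
  X <- matrix(rnorm(8 * 5), 8)
  st <- vector_stack(rbind(X, X),
                     condition = rep(c("Ex", "Sep"), each = 8),
                     subject = rep(sprintf("s%d", 1:8), 2))
  rpt <- forced_choice(linear_pattern_model(rnorm(5)), st, "Ex", "Sep")
  expect_equal(rpt$accuracy, 50)
  expect_equal(rpt$n_ties, 8L)
  expect_equal(rpt$p_value, 1)
})

test_that("a signature orthogonal to the generating difference scores near chance", {
  tr <- small_truth(subject_count = 40, noise_sd = 0.3, seed = 17)
  cs <- generate_contrast_stack(tr)
  d <- tr$patterns[, "Ex"] - tr$patterns[, "Sep"]
  set.seed(18)
  w <- rnorm(length(d))
  for (cond in c("Ex", "Sep")) {
    p <- tr$patterns[, cond]
    w <- w - p * sum(w * p) / sum(p^2)
  }
  rpt <- forced_choice(linear_pattern_model(w), cs, "Ex", "Sep")
  half_band <- 1.96 * 100 * sqrt(0.25 / 40)
  expect_lt(abs(rpt$accuracy - 50), half_band)
})

test_that("forced choice is invariant to positive weight rescaling and intercept", {
  tr <- small_truth(seed = 8)
  cs <- generate_contrast_stack(tr)
  m <- train_signature(cs, "Ex", "Sep")
  r1 <- forced_choice(m, cs, "Ex", "Sep")
  m2 <- linear_pattern_model(m$weights * 37, intercept = 5)
  r2 <- forced_choice(m2, cs, "Ex", "Sep", use_intercept = TRUE)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$auc, r2$auc)
})

test_that("forced choice warns on very small samples", {
  st <- vector_stack(rbind(c(1, 0), c(0, 0), c(2, 0), c(0, 0)),
                     condition = rep(c("a", "b"), 2),
                     subject = rep(c("s1", "s2"), each = 2))
  expect_warning(forced_choice(linear_pattern_model(c(1, 0)), st, "a", "b"),
                 "unstable")
})

test_that("repeated CV reaches ceiling in the separable limit and reports spread under noise", {
  tr <- small_truth(subject_count = 10, noise_sd = 0.02, seed = 3)
  cs <- generate_contrast_stack(tr)
  cv <- repeated_cv_evaluate(cs, "Ex", setdiff(tr$conditions, "Ex"),
                             pairs = list(c("Ex", "Inc")), k = 5,
                             n_repeats = 5, seed = 2)[[1]]
  expect_true(all(cv$per_rep == 100))
  expect_equal(cv$accuracy_sd, 0)
  trn <- small_truth(subject_count = 10, noise_sd = 2, seed = 3)
  csn <- generate_contrast_stack(trn)
  cvn <- repeated_cv_evaluate(csn, "Ex", setdiff(trn$conditions, "Ex"),
                              pairs = list(c("Ex", "Inc")), k = 5,
                              n_repeats = 8, seed = 2)[[1]]
  expect_gt(cvn$accuracy_sd, 0)
  expect_length(cvn$per_rep, 8)
  expect_error(repeated_cv_evaluate(cs, "Ex", "Inc", list(c("Ex", "Inc")),
                                    k = 11), "exceeds")
})

test_that("repeated CV honors a 10x10-fold configuration", {
  st <- vector_stack(matrix(rnorm(40), 20, 2) +
                       rep(c(1, -1), each = 10) %o% c(1, 1),
                     condition = rep(c("p", "q"), each = 10),
                     subject = rep(sprintf("s%02d", 1:10), 2))
  cv <- repeated_cv_evaluate(st, "p", "q", pairs = list(c("p", "q")),
                             k = 10, n_repeats = 100, seed = 4)[[1]]
  expect_length(cv$per_rep, 100)
  expect_true(all(cv$per_rep >= 0 & cv$per_rep <= 100))
})

test_that("an external weight map reproduces a trained model's report", {
  tr <- small_truth(seed = 12)
  cs <- generate_contrast_stack(tr)
  m <- train_signature(cs, "Ex", "Sep")
  direct <- forced_choice(m, cs, "Ex", "Sep")
  ext <- apply_external_signature(m$weights, cs,
                                  pairs = list(c("Ex", "Sep")))[[1]]
  expect_equal(ext$accuracy, direct$accuracy)
  expect_equal(ext$auc, direct$auc)
  # the generating difference itself is a perfect external decoder noiselessly
  tr0 <- small_truth(noise_sd = 0, pattern_amplitude_sd = 0, subject_count = 6)
  cs0 <- generate_contrast_stack(tr0)
  truth_w <- tr0$patterns[, "Ex"] - tr0$patterns[, "Inc"]
  rpt <- suppressWarnings(
    apply_external_signature(truth_w, cs0, list(c("Ex", "Inc"))))[[1]]
  expect_equal(rpt$accuracy, 100)
  expect_error(apply_external_signature(rep(0, ncol(cs$data)), cs,
                                        list(c("Ex", "Sep"))), "support")
})
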