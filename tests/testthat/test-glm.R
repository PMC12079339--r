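motion0 <- function(n) as.data.frame(matrix(0, n, 6))

test_that("condition design has one task column per condition and 24 nuisance columns", {
  ev <- data.frame(onset = seq(5, 125, by = 25), duration = 10,
                   trial_type = c("Ex", "Inc", "Sep", "Com", "rating"))
  set.seed(51)
  mot <- as.data.frame(matrix(rnorm(80 * 6, sd = 0.1), 80))
  d <- build_design(ev, mot, 80, 2, model = "condition")
  expect_equal(sum(d$is_task), 5)
  expect_equal(sum(grepl("^run1_mot", d$names)), 24)
  expect_true(any(grepl("dct", d$names)))
  expect_true(d$full_rank)
})

test_that("single-trial design emits one regressor per trial", {
  ev <- data.frame(onset = seq(5, by = 15, length.out = 60), duration = 10,
                   trial_type = rep(c("Ex", "Sep"), 30))
  d <- build_design(ev, motion0(460), 460, 2, model = "single_trial")
  expect_equal(sum(d$is_task), 60)
})

test_that("rating-parametric design adds a mean-centered modulator", {
  ev <- data.frame(onset = seq(5, 65, by = 20), duration = 10,
                   trial_type = "Ex", rating = c(1, 3, 4, 5))
  d <- build_design(ev, motion0(60), 60, 2, model = "rating_parametric")
  expect_true("Ex_rating" %in% d$names)
  # modulator orthogonal in amplitude: sum of centered weights is zero, so a
  # constant-rating run would yield an all-zero (dropped) modulator
  ev0 <- ev; ev0$rating <- 3
  d0 <- build_design(ev0, motion0(60), 60, 2, model = "rating_parametric")
  expect_false("Ex_rating" %in% d0$names)
})

test_that("collinear task regressors are rejected by name", {
  ev <- data.frame(onset = c(10, 10), duration = 10,
                   trial_type = c("A", "B"))
  expect_error(build_design(ev, motion0(40), 40, 2, model = "condition"),
               "collinear")
})

test_that("design construction validates events and motion", {
  ev <- data.frame(onset = -1, duration = 10, trial_type = "Ex")
  expect_error(build_design(ev, motion0(40), 40, 2), "non-negative")
  ev2 <- data.frame(onset = 5, duration = 0, trial_type = "Ex")
  expect_error(build_design(ev2, motion0(40), 40, 2), "positive")
  ev3 <- data.frame(onset = 5, duration = 10, trial_type = "Ex")
  expect_error(build_design(ev3, motion0(39), 40, 2), "motion")
})

test_that("OLS betas match the normal-equations oracle", {
  ev <- data.frame(onset = c(6, 30, 54, 78), duration = 10,
                   trial_type = c("A", "B", "A", "B"))
  set.seed(21)
  mot <- as.data.frame(matrix(rnorm(60 * 6, sd = 0.1), 60))
  d <- build_design(ev, mot, 60, 2, model = "condition")
  Y <- matrix(rnorm(60 * 10), 60)
  msk <- array(TRUE, c(10, 1, 1))
  fit <- fit_glm(Y, d, mask = msk)
  oracle <- solve(crossprod(d$X), crossprod(d$X, Y))[d$is_task, ]
  expect_equal(unname(fit$data), unname(oracle), tolerance = 1e-8)
})

test_that("noiseless synthetic series is recovered exactly", {
  tr <- synthetic_truth(grid_shape = c(8, 8, 8), subject_count = 2,
                        noise_sd = 0, seed = 2)
  ev <- data.frame(onset = c(10, 40, 70, 100), duration = 12,
                   trial_type = c("Ex", "Inc", "Sep", "Com"))
  sim <- generate_timeseries(tr, ev, tr_s = 2, noise_sd = 0)
  d <- build_design(ev, sim$motion, sim$n_scans, 2, model = "condition")
  fit <- suppressWarnings(fit_glm(sim$bold, d, mask = sim$mask))
  for (cond in tr$conditions) {
    b <- fit$data[fit$obs_meta$condition == cond, ]
    expect_equal(unname(b),
                 unname(tr$amplitude_mean[[cond]] * tr$patterns[, cond]),
                 tolerance = 1e-8)
  }
  # residual variance is numerically zero on noiseless input
  expect_lt(max(attr(fit, "residual_var")), 1e-16)
})

test_that("initial volumes can be discarded before fitting", {
  tr <- synthetic_truth(grid_shape = c(8, 8, 8), subject_count = 2,
                        noise_sd = 0, seed = 3)
  ev <- data.frame(onset = c(20, 50), duration = 12,
                   trial_type = c("Ex", "Sep"))
  sim <- generate_timeseries(tr, ev, tr_s = 2, noise_sd = 0)
  d <- build_design(ev, sim$motion, sim$n_scans, 2, model = "condition")
  fit <- suppressWarnings(fit_glm(sim$bold, d, mask = sim$mask,
                                  drop_initial = 5))
  b <- fit$data[fit$obs_meta$condition == "Ex", ]
  expect_equal(unname(b), unname(tr$patterns[, "Ex"]), tolerance = 1e-8)
})

test_that("betas are invariant to adding nuisance-space components", {
  ev <- data.frame(onset = c(6, 30, 54), duration = 10, trial_type = "Ex")
  set.seed(31)
  mot <- as.data.frame(matrix(rnorm(70 * 6, sd = 0.2), 70))
  d <- build_design(ev, mot, 70, 2, model = "condition")
  Y <- matrix(rnorm(70 * 6), 70)
  msk <- array(TRUE, c(6, 1, 1))
  nuis <- d$X[, !d$is_task, drop = FALSE]
  shift <- nuis %*% rnorm(ncol(nuis))
  f1 <- fit_glm(Y, d, mask = msk)
  f2 <- fit_glm(Y + shift %*% t(rep(1, 6)), d, mask = msk)
  expect_equal(f1$data, f2$data, tolerance = 1e-8)
})

test_that("high-pass basis removes a 200-s-period drift", {
  n <- 150
  ev <- data.frame(onset = seq(10, 280, by = 30), duration = 12,
                   trial_type = "Ex")
  d <- build_design(ev, motion0(n), n, 2, model = "condition")
  drift <- cos(2 * pi * (0:(n - 1)) * 2 / 200)
  Y <- matrix(drift, n, 5)
  msk <- array(TRUE, c(5, 1, 1))
  fit <- fit_glm(Y, d, mask = msk)
  expect_lt(max(abs(fit$data)), 1e-3)
})

test_that("all-zero voxels warn and yield zero betas", {
  ev <- data.frame(onset = 6, duration = 10, trial_type = "Ex")
  d <- build_design(ev, motion0(30), 30, 2)
  Y <- cbind(rnorm(30), 0)
  msk <- array(TRUE, c(2, 1, 1))
  expect_warning(fit <- fit_glm(Y, d, mask = msk), "all-zero")
  expect_equal(unname(fit$data[, 2]), 0)
})

test_that("condition contrasts subtract controls and validate inputs", {
  betas <- vector_stack(rbind(c(2, 0, 1), c(1, 0, 1),
                              c(2, 0, 1), c(0, 0, 1)),
                        condition = rep(c("Ex", "Con"), 2),
                        subject = rep(c("s1", "s2"), each = 2))
  con <- make_condition_contrasts(betas, list(ExCon = c("Ex", "Con")))
  expect_equal(unname(con$data[1, ]), c(1, 0, 0))
  expect_equal(unname(con$data[2, ]), c(2, 0, 0))
  same <- make_condition_contrasts(betas, list(null = c("Ex", "Ex")))
  expect_equal(max(abs(same$data)), 0)
  expect_error(make_condition_contrasts(betas, list(x = c("Ex", "Nope"))),
               "Nope")
})
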