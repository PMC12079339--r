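# First-level GLM: canonical-HRF design construction and voxelwise OLS.

#' Canonical double-gamma HRF
#'
#' The conventional parameterization: response peak at 6 s, undershoot peak
#' at 16 s, peak-to-undershoot ratio 6, unit time constants.
#'
#' @param t Time in seconds (vector).
#' @param peak,undershoot Gamma shape parameters (seconds to peak).
#' @param ratio Peak/undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  h
}

# Boxcar convolved with the canonical HRF, sampled at scan times.
# Built on a fine microtime grid then decimated to TR resolution.
hrf_regressor <- function(onsets, durations, n_scans, tr_s, dt = 0.1) {
  total <- n_scans * tr_s
  nt <- ceiling(total / dt) + 1L
  box <- numeric(nt)
  for (i in seq_along(onsets)) {
    a <- max(1L, floor(onsets[i] / dt) + 1L)
    b <- min(nt, ceiling((onsets[i] + durations[i]) / dt))
    box[a:b] <- box[a:b] + 1
  }
  hker <- canonical_hrf(seq(0, 32, by = dt)) * dt
  conv <- stats::convolve(box, rev(hker), type = "open")[seq_len(nt)]
  conv[round(((seq_len(n_scans) - 1) * tr_s) / dt) + 1L]
}

# Discrete-cosine high-pass basis with cutoff `hpf_s` seconds (columns are
# the low-frequency components to be regressed out).
dct_highpass_basis <- function(n_scans, tr_s, hpf_s = 128) {
  K <- floor(2 * n_scans * tr_s / hpf_s)
  if (K < 1) return(matrix(numeric(0), n_scans, 0))
  t <- seq_len(n_scans) - 1
  X <- sapply(seq_len(K), function(k)
    sqrt(2 / n_scans) * cos(pi * (2 * t + 1) * k / (2 * n_scans)))
  matrix(X, n_scans, K, dimnames = list(NULL, sprintf("dct%02d", seq_len(K))))
}

# 24-column motion nuisance block: 6 parameters, their squares, their
# first differences, and squared differences.
motion_nuisance <- function(motion) {
  m <- as.matrix(motion)
  if (ncol(m) != 6) stopf("motion table must have 6 columns, got %d", ncol(m))
  d <- rbind(0, diff(m))
  out <- cbind(m, m^2, d, d^2)
  colnames(out) <- c(paste0("mot", 1:6), paste0("mot_sq", 1:6),
                     paste0("mot_d", 1:6), paste0("mot_dsq", 1:6))
  out
}

#' Build a first-level design matrix
#'
#' Task boxcars are convolved with the canonical double-gamma HRF. The
#' nuisance block is the 6 motion parameters plus their squares, derivatives
#' and squared derivatives (24 columns per run), a discrete-cosine high-pass
#' set with a 128 s cutoff, and a run intercept. If `events$run` is present
#' the runs are concatenated: task columns are shared across runs while
#' nuisance, high-pass and intercept columns are run-specific.
#'
#' Three model variants are supported. `"condition"`: one regressor per
#' `trial_type`. `"rating_parametric"`: condition regressors plus, for each
#' condition with ratings, a mean-centered rating modulator (not
#' orthogonalized against the main boxcar). `"single_trial"`: one regressor
#' per event row, estimated simultaneously in a single design.
#'
#' @param events Data frame with `onset`, `duration`, `trial_type`, optional
#'   `rating` and `run`.
#' @param motion Data frame of 6 motion parameters, `sum(n_scans)` rows (or a
#'   list of per-run data frames).
#' @param n_scans Scans per run (scalar or per-run vector).
#' @param tr_s Repetition time (s).
#' @param model One of `"condition"`, `"rating_parametric"`, `"single_trial"`.
#' @param hpf_s High-pass cutoff in seconds (default 128).
#' @return An object of class `design_matrix`: list with the matrix `X`,
#'   logical `is_task`, `run` row index, and column names.
#' @export
build_design <- function(events, motion, n_scans, tr_s,
                         model = c("condition", "rating_parametric",
                                   "single_trial"),
                         hpf_s = 128) {
  model <- match.arg(model)
  if (any(events$onset < 0)) stopf("onsets must be non-negative")
  if (any(events$duration <= 0)) stopf("durations must be positive")
  runs <- if (!is.null(events$run)) sort(unique(events$run)) else 1L
  if (length(n_scans) == 1L) n_scans <- rep(n_scans, length(runs))
  if (is.data.frame(motion) || is.matrix(motion)) {
    if (nrow(motion) != sum(n_scans))
      stopf("motion has %d rows but %d scans expected",
            nrow(motion), sum(n_scans))
    motion <- split.data.frame(as.data.frame(motion),
                               rep(seq_along(runs), n_scans))
  }

  task_names <- switch(model,
    condition = unique(events$trial_type),
    rating_parametric = {
      tt <- unique(events$trial_type)
      rated <- unique(events$trial_type[!is.na(events$rating)])
      c(tt, paste0(rated, "_rating"))
    },
    single_trial = sprintf("trial%03d_%s", seq_len(nrow(events)),
                           events$trial_type))

  task_blocks <- vector("list", length(runs))
  nuis_blocks <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    ev <- if (is.null(events$run)) events
      else events[events$run == runs[ri], , drop = FALSE]
    ns <- n_scans[ri]
    Xt <- matrix(0, ns, length(task_names),
                 dimnames = list(NULL, task_names))
    if (model %in% c("condition", "rating_parametric")) {
      for (cond in unique(ev$trial_type)) {
        sel <- ev$trial_type == cond
        Xt[, cond] <- hrf_regressor(ev$onset[sel], ev$duration[sel], ns, tr_s)
      }
    }
    if (model == "rating_parametric") {
      all_ratings <- events$rating
      for (cond in unique(events$trial_type[!is.na(events$rating)])) {
        sel <- ev$trial_type == cond & !is.na(ev$rating)
        if (!any(sel)) next
        ctr <- mean(all_ratings[events$trial_type == cond], na.rm = TRUE)
        mod <- numeric(ns)
        for (i in which(sel)) {
          mod <- mod + (ev$rating[i] - ctr) *
            hrf_regressor(ev$onset[i], ev$duration[i], ns, tr_s)
        }
        Xt[, paste0(cond, "_rating")] <- mod
      }
    }
    if (model == "single_trial") {
      if (is.null(events$run)) {
        rows <- seq_len(nrow(events))
      } else rows <- which(events$run == runs[ri])
      for (i in rows)
        Xt[, task_names[i]] <- hrf_regressor(events$onset[i],
                                             events$duration[i], ns, tr_s)
    }
    task_blocks[[ri]] <- Xt
    nb <- cbind(motion_nuisance(motion[[ri]]),
                dct_highpass_basis(ns, tr_s, hpf_s),
                intercept = 1)
    colnames(nb) <- sprintf("run%d_%s", ri, colnames(nb))
    nuis_blocks[[ri]] <- nb
  }
  Xtask <- do.call(rbind, task_blocks)
  keep <- colSums(abs(Xtask)) > 0
  Xtask <- Xtask[, keep, drop = FALSE]
  r <- qr(Xtask)$rank
  if (r < ncol(Xtask)) {
    qrx <- qr(Xtask)
    bad <- colnames(Xtask)[qrx$pivot[(r + 1):ncol(Xtask)]]
    stopf("task regressors are collinear: %s", paste(bad, collapse = ", "))
  }
  nuis_all <- matrix(0, sum(n_scans),
                     sum(vapply(nuis_blocks, ncol, 0L)))
  cn <- character(0); off <- 0L; roff <- 0L
  for (ri in seq_along(runs)) {
    nb <- nuis_blocks[[ri]]
    nuis_all[roff + seq_len(nrow(nb)), off + seq_len(ncol(nb))] <- nb
    cn <- c(cn, colnames(nb)); off <- off + ncol(nb); roff <- roff + nrow(nb)
  }
  colnames(nuis_all) <- cn
  X <- cbind(Xtask, nuis_all)
  full_rank <- qr(X)$rank == ncol(X)
  structure(list(
    X = X, names = colnames(X),
    is_task = c(rep(TRUE, ncol(Xtask)), rep(FALSE, ncol(nuis_all))),
    run = rep(seq_along(runs), n_scans), tr_s = tr_s, model = model,
    full_rank = full_rank
  ), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d scans x %d regressors (%d task), model '%s'%s\n",
              nrow(x$X), ncol(x$X), sum(x$is_task), x$model,
              if (x$full_rank) "" else " [rank-deficient]"))
  invisible(x)
}

#' Fit a voxelwise OLS GLM
#'
#' Ordinary least squares per voxel (no prewhitening). Returns the task-column
#' betas as a `masked_image_stack` (one observation per task regressor), with
#' the per-voxel residual variance attached as an attribute.
#'
#' @param series 4-D array (x, y, z, t) or a scans x voxels matrix already
#'   restricted to the mask.
#' @param design A `design_matrix`.
#' @param mask Logical 3-D mask (required for 4-D input).
#' @param subject Subject id stored in the output metadata.
#' @param drop_initial Number of initial volumes to discard per run before
#'   fitting (both data and design rows), e.g. 5 to match dummy-scan removal.
#' @return A `masked_image_stack` of task betas with `condition` set to the
#'   task regressor names; attribute `residual_var` holds per-voxel residual
#'   variance.
#' @export
fit_glm <- function(series, design, mask = NULL, subject = "sub001",
                    drop_initial = 0) {
  X <- design$X
  if (is.array(series) && length(dim(series)) == 4L) {
    if (is.null(mask)) stopf("mask required for 4-D input")
    flat <- matrix(as.numeric(series), prod(dim(series)[1:3]),
                   dim(series)[4])
    Y <- t(flat[which(mask), , drop = FALSE])
  } else {
    Y <- as.matrix(series)
    if (is.null(mask)) stopf("mask required for matrix input")
    if (ncol(Y) != sum(mask))
      stopf("series has %d voxels but mask has %d", ncol(Y), sum(mask))
  }
  if (nrow(Y) != nrow(X))
    stopf("series has %d scans but design has %d rows", nrow(Y), nrow(X))
  if (drop_initial > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(X)), design$run),
                          function(i) i[-seq_len(drop_initial)]))
    X <- X[keep, , drop = FALSE]
    Y <- Y[keep, , drop = FALSE]
  }
  zero_vox <- colSums(Y != 0) == 0
  if (any(zero_vox))
    warnf("%d voxel(s) have all-zero time courses; betas set to 0",
          sum(zero_vox))
  qrx <- qr(X)
  beta <- qr.coef(qrx, Y)
  beta[is.na(beta)] <- 0
  res <- qr.resid(qrx, Y)
  dfres <- nrow(Y) - qrx$rank
  task_beta <- beta[design$is_task, , drop = FALSE]
  meta <- data.frame(subject = subject,
                     condition = design$names[design$is_task],
                     stringsAsFactors = FALSE)
  out <- masked_image_stack(task_beta, mask, meta)
  attr(out, "residual_var") <- colSums(res^2) / max(dfres, 1)
  out
}

#' Build condition contrast images
#'
#' One contrast image per subject per named pair, e.g. `Ex - Con` per subject.
#'
#' @param betas A `masked_image_stack` of condition betas (rows identified by
#'   `subject` and `condition` metadata).
#' @param scheme Named list; each element is `c(minuend, subtrahend)`.
#' @return A `masked_image_stack` with one observation per subject per
#'   contrast; `condition` carries the contrast names.
#' @export
make_condition_contrasts <- function(betas, scheme) {
  stopifnot(inherits(betas, "masked_image_stack"))
  need <- unique(unlist(scheme))
  have <- unique(betas$obs_meta$condition)
  missing <- setdiff(need, have)
  if (length(missing))
    stopf("conditions absent from betas: %s", paste(missing, collapse = ", "))
  subs <- unique(betas$obs_meta$subject)
  out <- matrix(0, length(subs) * length(scheme), ncol(betas$data))
  meta <- data.frame(subject = rep(subs, each = length(scheme)),
                     condition = rep(names(scheme), length(subs)),
                     stringsAsFactors = FALSE)
  row <- 1L
  for (s in subs) {
    sel <- betas$obs_meta$subject == s
    for (nm in names(scheme)) {
      pair <- scheme[[nm]]
      i1 <- which(sel & betas$obs_meta$condition == pair[1])
      i2 <- which(sel & betas$obs_meta$condition == pair[2])
      if (length(i1) < 1 || length(i2) < 1)
        stopf("subject %s lacks condition %s", s,
              paste(pair[c(length(i1) < 1, length(i2) < 1)], collapse = ", "))
      out[row, ] <- colMeans(betas$data[i1, , drop = FALSE]) -
        colMeans(betas$data[i2, , drop = FALSE])
      row <- row + 1L
    }
  }
  masked_image_stack(out, betas$mask, meta, betas$affine)
}
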