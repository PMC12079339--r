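#' Define a synthetic ground truth for signature simulations
#'
#' Constructs the fixed "truth" object all generators draw from: a voxel grid
#' with an ellipsoidal brain mask, unit-norm condition patterns built as
#' `rho_shared * g + sqrt(1 - rho_shared^2) * u_c` from orthonormal Gaussian
#' draws (so every pairwise pattern cosine equals `rho_shared^2` exactly), a
#' mediator pattern with a stated cosine overlap to the first pain condition's
#' pattern, per-condition amplitude means (positive for the "pain" conditions,
#' zero for their controls), and a latent-Gaussian rating link.
#'
#' Defaults mirror the study design being emulated: 65 subjects, four
#' control-subtracted conditions (Ex, Inc, Sep, Com), 60 single trials per
#' task condition, ratings on a 1-5 scale.
#'
#' @param grid_shape Integer 3-vector voxel grid (default 16^3).
#' @param subject_count Number of subjects (default 65).
#' @param conditions Condition labels; the first and third are treated as the
#'   "pain" conditions by default (see `pain_conditions`).
#' @param pain_conditions Conditions carrying positive pattern amplitude.
#' @param rho_shared Mixing weight of the shared component in `[0, 1]`.
#' @param pattern_amplitude_mean,pattern_amplitude_sd Per-subject signal
#'   amplitude distribution (arbitrary beta units).
#' @param noise_sd Voxelwise Gaussian noise SD; must be >= 0.
#' @param trial_counts Named integer vector of trials per condition for the
#'   single-trial generator.
#' @param trial_amplitude_sd SD of trial-level amplitude jitter.
#' @param rating_link List with `intercept`, `slope`, `noise_sd`: the latent
#'   rating is `intercept + slope * expression + N(0, noise_sd)`, rounded and
#'   clipped to 1..5.
#' @param mediator_overlap Cosine between the mediator pattern and the first
#'   pain condition's pattern.
#' @param subject_pattern_jitter SD of per-subject pattern perturbation
#'   (default 0: identical true patterns across subjects).
#' @param signal_mode `"amplitude"`: trial signal is
#'   `expression * pattern_c`, so the condition-specific signal scales with
#'   the rated expression. `"additive"`: trial signal is
#'   `expression * shared + additive_scale * specific_c`, so the
#'   condition-specific signal is constant across rating levels.
#' @param additive_scale Scale of the condition-specific component in
#'   `"additive"` mode.
#' @param seed Integer RNG seed; one global seed fans out to deterministic
#'   per-subject substreams.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(grid_shape = c(16L, 16L, 16L),
                            subject_count = 65L,
                            conditions = c("Ex", "Inc", "Sep", "Com"),
                            pain_conditions = c("Ex", "Sep"),
                            rho_shared = 0.5,
                            pattern_amplitude_mean = 1,
                            pattern_amplitude_sd = 0.2,
                            noise_sd = 1,
                            trial_counts = c(Ex = 60L, Sep = 60L),
                            trial_amplitude_sd = 0.5,
                            rating_link = list(intercept = 0, slope = 1.5,
                                               noise_sd = 1.25),
                            mediator_overlap = 0.5,
                            subject_pattern_jitter = 0,
                            signal_mode = c("amplitude", "additive"),
                            additive_scale = 1,
                            seed = 1L) {
  signal_mode <- match.arg(signal_mode)
  if (noise_sd < 0) stopf("noise_sd must be non-negative, got %g", noise_sd)
  if (rho_shared < 0 || rho_shared > 1)
    stopf("rho_shared must lie in [0, 1]")
  if (!all(pain_conditions %in% conditions))
    stopf("pain_conditions must be a subset of conditions")
  grid_shape <- as.integer(grid_shape)
  mask <- ellipsoid_mask(grid_shape)
  V <- sum(mask)
  nc <- length(conditions)
  if (V < nc + 2) stopf("mask too small for %d condition patterns", nc)

  basis <- local_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(V * (nc + 2)), V)))   # orthonormal columns
  })
  g <- basis[, 1]
  specific <- basis[, 2:(nc + 1), drop = FALSE]
  colnames(specific) <- conditions
  patterns <- rho_shared * g +
    sqrt(1 - rho_shared^2) * specific                  # unit norm by construction
  colnames(patterns) <- conditions
  u_med <- basis[, nc + 2]
  mediator <- mediator_overlap * patterns[, pain_conditions[1]] +
    sqrt(1 - mediator_overlap^2) * u_med

  amp_mean <- stats::setNames(rep(0, nc), conditions)
  amp_mean[pain_conditions] <- pattern_amplitude_mean

  structure(list(
    grid_shape = grid_shape, mask = mask, voxel_index = which(mask),
    conditions = conditions, pain_conditions = pain_conditions,
    rho_shared = rho_shared, patterns = patterns, shared_pattern = g,
    specific_patterns = specific, mediator_pattern = mediator,
    mediator_overlap = mediator_overlap,
    amplitude_mean = amp_mean,
    pattern_amplitude_mean = pattern_amplitude_mean,
    pattern_amplitude_sd = pattern_amplitude_sd,
    noise_sd = noise_sd, subject_count = as.integer(subject_count),
    trial_counts = trial_counts, trial_amplitude_sd = trial_amplitude_sd,
    rating_link = rating_link,
    subject_pattern_jitter = subject_pattern_jitter,
    signal_mode = signal_mode, additive_scale = additive_scale,
    seed = as.integer(seed)
  ), class = "synthetic_truth")
}

# Contiguous near-equal integer blocks 1..k over n items.
split_blocks <- function(n, k) {
  if (k == 1L) return(rep(1L, n))
  as.integer(cut(seq_len(n), breaks = k, labels = FALSE))
}

# Ellipsoidal mask inscribed in the grid (semi-axes dim/2 - 1).
ellipsoid_mask <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  semi <- pmax(grid_shape / 2 - 1, 1)
  idx <- arrayInd(seq_len(prod(grid_shape)), grid_shape)
  r2 <- ((idx[, 1] - ctr[1]) / semi[1])^2 +
        ((idx[, 2] - ctr[2]) / semi[2])^2 +
        ((idx[, 3] - ctr[3]) / semi[3])^2
  array(r2 <= 1, dim = grid_shape)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> grid %s, %d in-mask voxels, %d ",
                     "subjects, conditions %s (rho_shared = %g)\n"),
              paste(x$grid_shape, collapse = "x"), sum(x$mask),
              x$subject_count, paste(x$conditions, collapse = "/"),
              x$rho_shared))
  invisible(x)
}

subject_ids <- function(n) sprintf("sub%03d", seq_len(n))

subject_amplitudes <- function(truth, s) {
  # Subject-level condition amplitudes from the subject's substream.
  local_seed(substream_seed(truth$seed, s, purpose = 1L), {
    truth$amplitude_mean +
      stats::rnorm(length(truth$conditions)) * truth$pattern_amplitude_sd
  })
}

subject_patterns <- function(truth, s) {
  if (truth$subject_pattern_jitter == 0) return(truth$patterns)
  local_seed(substream_seed(truth$seed, s, purpose = 4L), {
    p <- truth$patterns +
      matrix(stats::rnorm(length(truth$patterns)), nrow(truth$patterns)) *
        truth$subject_pattern_jitter
    sweep(p, 2, sqrt(colSums(p^2)), "/")
  })
}

#' Generate a subjects x conditions contrast stack
#'
#' One control-subtracted contrast image per subject per condition:
#' `amplitude_sc * pattern_c + N(0, noise_sd)` per voxel. Amplitudes are
#' drawn per subject around the condition mean (positive for the pain
#' conditions, zero for their matched controls).
#'
#' @param truth A `synthetic_truth`.
#' @return A `masked_image_stack` with `subject_count * length(conditions)`
#'   observations.
#' @export
generate_contrast_stack <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  V <- length(truth$voxel_index)
  nc <- length(truth$conditions)
  n <- truth$subject_count * nc
  data <- matrix(0, n, V)
  meta <- data.frame(subject = rep(subject_ids(truth$subject_count), each = nc),
                     condition = rep(truth$conditions, truth$subject_count),
                     stringsAsFactors = FALSE)
  row <- 1L
  for (s in seq_len(truth$subject_count)) {
    amp <- subject_amplitudes(truth, s)
    pat <- subject_patterns(truth, s)
    noise <- local_seed(substream_seed(truth$seed, s, purpose = 2L),
                        matrix(stats::rnorm(nc * V), nc) * truth$noise_sd)
    for (ci in seq_len(nc)) {
      data[row, ] <- amp[ci] * pat[, ci] + noise[ci, ]
      row <- row + 1L
    }
  }
  masked_image_stack(data, truth$mask, meta)
}

#' Generate a single-trial stack with ratings
#'
#' Per-trial images with trial-level amplitude jitter around the subject's
#' condition amplitude, plus 1-5 ratings produced by the latent-Gaussian
#' rating link applied to each trial's true expression. Under
#' `signal_mode = "amplitude"` the condition pattern is scaled by the rated
#' expression; under `"additive"` a constant condition-specific component
#' rides on a rated shared component.
#'
#' @param truth A `synthetic_truth` with non-empty `trial_counts`.
#' @return A `masked_image_stack` with `trial` and `rating` metadata and an
#'   attribute `expression` holding each trial's true pattern expression.
#' @export
generate_trial_stack <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  tc <- truth$trial_counts
  if (is.null(tc) || length(tc) == 0L) stopf("trial_counts not set")
  if (any(tc <= 0))
    stopf("zero trials requested for condition(s): %s",
          paste(names(tc)[tc <= 0], collapse = ", "))
  conds <- names(tc)
  V <- length(truth$voxel_index)
  per_sub <- sum(tc)
  n <- truth$subject_count * per_sub
  data <- matrix(0, n, V)
  meta <- data.frame(subject = rep(subject_ids(truth$subject_count),
                                   each = per_sub),
                     condition = rep(rep(conds, tc), truth$subject_count),
                     trial = rep(unlist(lapply(tc, seq_len), use.names = FALSE),
                                 truth$subject_count),
                     rating = NA_integer_, stringsAsFactors = FALSE)
  expression <- numeric(n)
  rl <- truth$rating_link
  row <- 1L
  for (s in seq_len(truth$subject_count)) {
    amp <- stats::setNames(subject_amplitudes(truth, s), truth$conditions)
    pat <- subject_patterns(truth, s)
    local_seed(substream_seed(truth$seed, s, purpose = 3L), {
      for (cond in conds) {
        for (t in seq_len(tc[[cond]])) {
          expr <- amp[[cond]] + stats::rnorm(1) * truth$trial_amplitude_sd
          signal <- if (truth$signal_mode == "amplitude") {
            expr * pat[, cond]
          } else {
            expr * truth$shared_pattern +
              truth$additive_scale * truth$specific_patterns[, cond]
          }
          data[row, ] <- signal + stats::rnorm(V) * truth$noise_sd
          latent <- rl$intercept + rl$slope * expr +
            stats::rnorm(1) * rl$noise_sd
          meta$rating[row] <- as.integer(min(5, max(1, round(latent))))
          expression[row] <- expr
          row <- row + 1L
        }
      }
    })
  }
  out <- masked_image_stack(data, truth$mask, meta)
  attr(out, "expression") <- expression
  out
}

#' Generate a contiguous-blocks parcellation of the mask
#'
#' Splits the in-mask voxels (in linear-index order) into `n_rois` contiguous
#' near-equal blocks, mapped many-to-one onto `n_networks` networks. With the
#' default 24 ROIs / 7 networks the label tables use the conventional
#' large-scale network abbreviations (VN, SMN, DAN, VAN, LN, FPN, DMN).
#'
#' @param truth A `synthetic_truth` (supplies mask and grid).
#' @param n_rois Number of ROIs (default 24).
#' @param n_networks Number of networks (default 7); must be <= `n_rois`.
#' @return An object of class `parcellation`.
#' @export
generate_parcellation <- function(truth, n_rois = 24L, n_networks = 7L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  V <- length(truth$voxel_index)
  if (n_networks < 1 || n_rois < n_networks)
    stopf("need n_rois >= n_networks >= 1")
  if (n_rois > V) stopf("n_rois (%d) exceeds voxel count (%d)", n_rois, V)
  roi <- split_blocks(V, n_rois)
  roi_to_net <- split_blocks(n_rois, n_networks)
  network <- roi_to_net[roi]
  roi_names <- if (n_rois == 24L) {
    c("Amyg", "BG", "CG", "FuG", "Hipp", "IFG", "INS", "IPL", "ITG", "LOcC",
      "MFG", "MTG", "MVOcC", "OrG", "PCL", "PCun", "PhG", "PoG", "PrG",
      "SFG", "SPL", "STG", "Thal", "pSTS")
  } else sprintf("ROI%02d", seq_len(n_rois))
  net_names <- if (n_networks == 7L) {
    c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN")
  } else sprintf("Net%d", seq_len(n_networks))
  parcellation(roi, network,
               data.frame(label = seq_len(n_rois), roi_name = roi_names,
                          network_label = roi_to_net,
                          network_name = net_names[roi_to_net],
                          stringsAsFactors = FALSE),
               mask = truth$mask)
}

#' Construct a parcellation object
#'
#' @param roi Integer ROI label per in-mask voxel (1..R).
#' @param network Integer network label per in-mask voxel (1..N).
#' @param roi_table Data frame with columns `label`, `roi_name`,
#'   `network_label`, `network_name`.
#' @param mask Logical 3-D mask array the labels refer to.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(roi, network, roi_table, mask) {
  V <- sum(mask)
  if (length(roi) != V || length(network) != V)
    stopf("labels must cover every in-mask voxel exactly once")
  if (anyNA(roi) || anyNA(network)) stopf("unlabeled in-mask voxels")
  net_of_roi <- tapply(network, roi, function(x) length(unique(x)))
  if (any(net_of_roi != 1))
    stopf("ROI -> network map must be many-to-one")
  structure(list(roi = as.integer(roi), network = as.integer(network),
                 roi_table = roi_table, mask = mask,
                 network_table = unique(roi_table[, c("network_label",
                                                     "network_name")])),
            class = "parcellation")
}

#' Write a parcellation as integer NIfTI + TSV label table
#'
#' @param parc A `parcellation`.
#' @param prefix Path prefix.
#' @param affine Optional 4x4 affine (defaults to the standard grid affine).
#' @return Invisibly, the paths written.
#' @export
write_parcellation <- function(parc, prefix, affine = NULL) {
  if (is.null(affine)) affine <- default_affine(dim(parc$mask))
  vol <- array(0L, dim = dim(parc$mask))
  vol[which(parc$mask)] <- parc$roi
  RNifti::writeNifti(as_nifti(vol, affine), paste0(prefix, ".nii.gz"),
                     datatype = "int16")
  utils::write.table(parc$roi_table, paste0(prefix, "_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paste0(prefix, ".nii.gz"), paste0(prefix, "_labels.tsv")))
}

#' Generate a raw 4-D time series from a synthetic truth
#'
#' The BOLD signal at each voxel is the condition boxcars convolved with the
#' canonical double-gamma HRF, scaled by the condition amplitude and the
#' condition's voxel pattern, plus a slow cosine drift and white noise. A
#' 6-column motion table (smooth random walk) is emitted alongside.
#'
#' @param truth A `synthetic_truth`.
#' @param events Event table: data frame with `onset`, `duration`,
#'   `trial_type` (seconds).
#' @param tr_s Repetition time in seconds (> 0).
#' @param n_scans Number of volumes; defaults to covering the last event
#'   plus 16 s.
#' @param drift_amplitude Amplitude of the slow drift (default 0 for exact
#'   noiseless recovery when `noise_sd = 0`).
#' @param noise_sd Time-series noise SD; defaults to `truth$noise_sd`.
#' @return List with `bold` (4-D array), `motion` (n_scans x 6 data frame),
#'   `mask`, `tr_s` and the per-condition true amplitudes.
#' @export
generate_timeseries <- function(truth, events, tr_s, n_scans = NULL,
                                drift_amplitude = 0, noise_sd = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (tr_s <= 0) stopf("tr_s must be positive")
  if (is.null(noise_sd)) noise_sd <- truth$noise_sd
  if (is.null(n_scans))
    n_scans <- ceiling((max(events$onset + events$duration) + 16) / tr_s)
  if (max(events$onset + events$duration) > n_scans * tr_s)
    stopf("events extend beyond the scan duration")
  V <- length(truth$voxel_index)
  amp <- truth$amplitude_mean
  ts_mat <- matrix(0, n_scans, V)
  for (cond in intersect(unique(events$trial_type), truth$conditions)) {
    ev <- events[events$trial_type == cond, , drop = FALSE]
    reg <- hrf_regressor(ev$onset, ev$duration, n_scans, tr_s)
    ts_mat <- ts_mat + outer(reg, amp[[cond]] * truth$patterns[, cond])
  }
  local_seed(substream_seed(truth$seed, 0L, purpose = 5L), {
    if (drift_amplitude > 0) {
      drift <- drift_amplitude *
        cos(pi * seq(0, 1, length.out = n_scans) * stats::runif(1, 0.5, 1.5))
      ts_mat <- ts_mat + outer(drift, rep(1, V))
    }
    if (noise_sd > 0)
      ts_mat <- ts_mat + matrix(stats::rnorm(n_scans * V), n_scans) * noise_sd
    motion <- as.data.frame(apply(matrix(stats::rnorm(n_scans * 6, sd = 0.02),
                                         n_scans), 2, cumsum))
  })
  names(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  bold <- array(0, dim = c(truth$grid_shape, n_scans))
  flat <- matrix(0, prod(truth$grid_shape), n_scans)
  flat[truth$voxel_index, ] <- t(ts_mat)
  bold[] <- flat
  list(bold = bold, motion = motion, mask = truth$mask, tr_s = tr_s,
       amplitudes = amp, n_scans = n_scans)
}
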