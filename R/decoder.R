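# Linear-SVM pattern signatures and forced-choice evaluation.

#' Construct a linear pattern model
#'
#' @param weights Numeric voxel weight vector.
#' @param intercept Scalar intercept.
#' @param label_map List with `positive` and `negative` condition sets.
#' @param training Optional list of training provenance (C, n_obs, subjects).
#' @return Object of class `linear_pattern_model`.
#' @export
linear_pattern_model <- function(weights, intercept = 0,
                                 label_map = list(positive = NA,
                                                  negative = NA),
                                 training = list()) {
  weights <- as.numeric(weights)
  if (anyNA(weights) || any(!is.finite(weights)))
    stopf("non-finite weights")
  structure(list(weights = weights, intercept = as.numeric(intercept),
                 label_map = label_map, training = training),
            class = "linear_pattern_model")
}

#' @export
print.linear_pattern_model <- function(x, ...) {
  cat(sprintf("<linear_pattern_model> %d voxels; +1 = {%s}, -1 = {%s}\n",
              length(x$weights),
              paste(x$label_map$positive, collapse = ","),
              paste(x$label_map$negative, collapse = ",")))
  invisible(x)
}

#' Train a linear-SVM signature
#'
#' Soft-margin linear SVM (C-classification) on raw, unscaled contrast
#' values; observations whose condition is in `positive` are labeled +1 and
#' those in `negative` are labeled -1. One-vs-all signatures are obtained by
#' putting one condition in `positive` and the rest in `negative`; pairwise
#' signatures by one condition on each side.
#'
#' @param stack A `masked_image_stack`.
#' @param positive,negative Disjoint, non-empty condition sets.
#' @param C Soft-margin cost (default 1).
#' @return A `linear_pattern_model`. The decision value for an image `x` is
#'   `sum(w * x) + b`, positive for the `positive` set.
#' @export
train_signature <- function(stack, positive, negative, C = 1) {
  stopifnot(inherits(stack, "masked_image_stack"))
  if (length(intersect(positive, negative)))
    stopf("positive and negative sets overlap")
  if (!length(positive) || !length(negative))
    stopf("both condition sets must be non-empty")
  cond <- stack$obs_meta$condition
  used <- cond %in% c(positive, negative)
  subs <- unique(stack$obs_meta$subject[used])
  if (length(subs) < 2) stopf("need >= 2 subjects")
  for (s in subs) {
    hc <- cond[used & stack$obs_meta$subject == s]
    lack <- c(positive, negative)[!(c(positive, negative) %in% hc)]
    if (length(lack))
      stopf("subject %s missing condition(s): %s", s,
            paste(lack, collapse = ", "))
  }
  X <- stack$data[used, , drop = FALSE]
  y <- factor(ifelse(cond[used] %in% positive, "pos", "neg"),
              levels = c("pos", "neg"))
  fit <- e1071::svm(X, y, scale = FALSE, kernel = "linear", cost = C,
                    type = "C-classification")
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # Orient the decision function so the positive set scores higher.
  f <- X %*% w + b
  if (mean(f[y == "pos"]) < mean(f[y == "neg"])) { w <- -w; b <- -b }
  linear_pattern_model(w, b,
                       label_map = list(positive = positive,
                                        negative = negative),
                       training = list(C = C, n_obs = nrow(X),
                                       subjects = subs))
}

#' Pattern response of a signature on a stack
#'
#' Dot product between each image and the signature weights; linear in the
#' image.
#'
#' @param model A `linear_pattern_model`.
#' @param stack A `masked_image_stack` in the same voxel space (same voxel
#'   count; use [resample_weights()] first if grids differ).
#' @param use_intercept Add the intercept to each response (default FALSE).
#' @return Numeric vector, one response per observation.
#' @export
pattern_response <- function(model, stack, use_intercept = FALSE) {
  if (length(model$weights) != ncol(stack$data))
    stopf("model has %d voxels but stack has %d; resample first",
          length(model$weights), ncol(stack$data))
  drop(stack$data %*% model$weights) +
    if (use_intercept) model$intercept else 0
}

new_forced_choice_report <- function(accuracy, accuracy_sd, per_rep, p_value,
                                     auc, cohens_d, n_subjects, n_ties = 0L) {
  structure(list(accuracy = accuracy, accuracy_sd = accuracy_sd,
                 per_rep = per_rep, p_value = p_value, auc = auc,
                 cohens_d = cohens_d, n_subjects = n_subjects,
                 n_ties = n_ties),
            class = "forced_choice_report")
}

#' @export
print.forced_choice_report <- function(x, ...) {
  cat(sprintf("<forced_choice> accuracy %.1f%%%s, p = %.3g, AUC = %.3f, d = %.2f (n = %d)\n",
              x$accuracy,
              if (is.finite(x$accuracy_sd)) sprintf(" ± %.1f", x$accuracy_sd) else "",
              x$p_value, x$auc, x$cohens_d, x$n_subjects))
  invisible(x)
}

# Paired forced choice from per-subject response differences.
forced_choice_from_diffs <- function(diffs, resp_a = NULL, resp_b = NULL) {
  n <- length(diffs)
  ties <- sum(diffs == 0)
  correct <- sum(diffs > 0) + 0.5 * ties
  accuracy <- 100 * correct / n
  nz <- diffs[diffs != 0]
  p <- if (length(nz)) stats::binom.test(sum(nz > 0), length(nz),
                                         0.5)$p.value else 1
  d <- if (stats::sd(diffs) > 0) mean(diffs) / stats::sd(diffs) else Inf * sign(mean(diffs))
  auc <- if (!is.null(resp_a)) {
    # Single-interval ROC: P(response_a > response_b) over all pairs.
    cmp <- outer(resp_a, resp_b, "-")
    mean(cmp > 0) + 0.5 * mean(cmp == 0)
  } else (sum(diffs > 0) + 0.5 * ties) / n
  new_forced_choice_report(accuracy, NA_real_, accuracy, p, auc, d, n, ties)
}

#' Two-alternative forced-choice evaluation
#'
#' For each subject, the image (or mean image) of `cond_a` is predicted to be
#' `cond_a` when its pattern response exceeds that of `cond_b`. Exact ties are
#' credited 0.5 and excluded from the binomial test. The p-value is a
#' two-sided exact binomial test against chance; Cohen's d is the mean over
#' SD of the paired response differences; the AUC is the single-interval
#' (Mann-Whitney) area over the pooled responses.
#'
#' @param model A `linear_pattern_model` (or bare weight vector).
#' @param stack A `masked_image_stack`; every subject must have both
#'   conditions.
#' @param cond_a,cond_b Condition labels to discriminate (`cond_a` = target).
#' @param use_intercept Passed to [pattern_response()] (irrelevant for the
#'   within-subject comparison; kept for completeness).
#' @return A `forced_choice_report`.
#' @export
forced_choice <- function(model, stack, cond_a, cond_b,
                          use_intercept = FALSE) {
  if (!inherits(model, "linear_pattern_model"))
    model <- linear_pattern_model(model)
  meta <- stack$obs_meta
  subs <- unique(meta$subject)
  ok <- vapply(subs, function(s)
    any(meta$subject == s & meta$condition == cond_a) &&
    any(meta$subject == s & meta$condition == cond_b), TRUE)
  if (!all(ok))
    stopf("subject(s) lacking both conditions: %s",
          paste(subs[!ok], collapse = ", "))
  if (length(subs) < 5)
    warnf("only %d subjects; forced-choice estimates will be unstable",
          length(subs))
  r <- pattern_response(model, stack, use_intercept)
  ra <- vapply(subs, function(s)
    mean(r[meta$subject == s & meta$condition == cond_a]), 0)
  rb <- vapply(subs, function(s)
    mean(r[meta$subject == s & meta$condition == cond_b]), 0)
  forced_choice_from_diffs(ra - rb, ra, rb)
}

#' Repeated k-fold cross-validated forced-choice evaluation
#'
#' Folds partition subjects (all of a subject's images share a fold). Per
#' repetition the folds are redrawn; per fold a signature is trained on the
#' remaining folds and the held-out subjects are scored by forced choice for
#' each requested condition pair. The report aggregates the per-repetition
#' accuracies (mean and SD) and the per-subject response differences averaged
#' across repetitions.
#'
#' @param stack A `masked_image_stack`.
#' @param positive,negative Training condition sets (see [train_signature()]).
#' @param pairs List of `c(cond_a, cond_b)` pairs to evaluate.
#' @param C Soft-margin cost.
#' @param k Folds (default 10); must not exceed the subject count.
#' @param n_repeats Full CV rounds (default 50; the reference analysis uses
#'   1000).
#' @param seed RNG seed for fold assignment.
#' @return Named list of `forced_choice_report`s, one per pair.
#' @export
repeated_cv_evaluate <- function(stack, positive, negative, pairs,
                                 C = 1, k = 10, n_repeats = 50, seed = 1) {
  subs <- unique(stack$obs_meta$subject)
  if (k > length(subs))
    stopf("k = %d exceeds the %d subjects", k, length(subs))
  if (!is.list(pairs)) pairs <- list(pairs)
  names(pairs) <- vapply(pairs, paste, "", collapse = "_vs_")
  acc <- matrix(NA_real_, n_repeats, length(pairs),
                dimnames = list(NULL, names(pairs)))
  diff_sum <- matrix(0, length(subs), length(pairs),
                     dimnames = list(subs, names(pairs)))
  local_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      fold <- sample(rep_len(seq_len(k), length(subs)))
      rep_diffs <- matrix(NA_real_, length(subs), length(pairs))
      for (f in seq_len(k)) {
        train_subs <- subs[fold != f]
        test_subs <- subs[fold == f]
        m <- train_signature(
          stack_subset(stack, stack$obs_meta$subject %in% train_subs),
          positive, negative, C)
        test <- stack_subset(stack, stack$obs_meta$subject %in% test_subs)
        r <- pattern_response(m, test)
        for (pi in seq_along(pairs)) {
          pr <- pairs[[pi]]
          for (s in test_subs) {
            sel_a <- test$obs_meta$subject == s & test$obs_meta$condition == pr[1]
            sel_b <- test$obs_meta$subject == s & test$obs_meta$condition == pr[2]
            rep_diffs[match(s, subs), pi] <- mean(r[sel_a]) - mean(r[sel_b])
          }
        }
      }
      diff_sum <- diff_sum + rep_diffs
      acc[rep_i, ] <- 100 * colMeans(rep_diffs > 0) +
        50 * colMeans(rep_diffs == 0)
    }
  })
  out <- lapply(seq_along(pairs), function(pi) {
    rpt <- forced_choice_from_diffs(diff_sum[, pi] / n_repeats)
    rpt$accuracy <- mean(acc[, pi])
    rpt$accuracy_sd <- stats::sd(acc[, pi])
    rpt$per_rep <- acc[, pi]
    rpt
  })
  names(out) <- names(pairs)
  out
}

#' Apply an externally supplied weight map as a signature
#'
#' Identical contract to [forced_choice()] with a fixed weight map and no
#' retraining; the map is nearest-neighbour resampled onto the stack's grid
#' when given as a NIfTI image or path.
#'
#' @param weights A numeric vector over the stack's voxels, an RNifti image,
#'   or a path to a weight NIfTI.
#' @param stack A `masked_image_stack`.
#' @param pairs List of `c(cond_a, cond_b)` pairs.
#' @return Named list of `forced_choice_report`s.
#' @export
apply_external_signature <- function(weights, stack, pairs) {
  if (!is.numeric(weights)) weights <- resample_weights(weights, stack)
  if (all(weights == 0))
    stopf("external weight map has no support inside the mask")
  if (!is.list(pairs)) pairs <- list(pairs)
  model <- linear_pattern_model(weights)
  out <- lapply(pairs, function(pr) forced_choice(model, stack, pr[1], pr[2]))
  names(out) <- vapply(pairs, paste, "", collapse = "_vs_")
  out
}
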