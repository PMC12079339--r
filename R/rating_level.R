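# Rating-stratified forced choice: does a pairwise signature still separate
# two conditions when the compared trials share the same subjective rating?

#' Rating-stratified forced-choice classification
#'
#' For each rating level, each subject's same-rating trial images are
#' averaged per condition (an approximation of the rating-parametric GLM's
#' per-level betas); subjects lacking the level in either condition are
#' excluded at that level. With a fixed `model` the averaged pairs are scored
#' in a single forced-choice pass; with `train` given instead, a signature is
#' retrained per level under repeated subject-fold cross-validation via
#' [repeated_cv_evaluate()].
#'
#' @param trial_stack A single-trial `masked_image_stack` with `rating`
#'   metadata for both conditions.
#' @param cond_a,cond_b Conditions to discriminate.
#' @param model A fixed `linear_pattern_model` (or NULL to retrain).
#' @param train List with `positive`, `negative`, and optional `C`, `k`,
#'   `n_repeats`, `seed`; used when `model` is NULL.
#' @param levels Rating levels to test (default 1:5).
#' @return Object of class `rating_stratified_report`: per-level list of
#'   `forced_choice_report`s (NULL where a level is empty), a `counts` table
#'   of trials per level per condition, usable-subject counts, and a
#'   `flagged` vector marking levels with < 2 usable subjects.
#' @export
stratified_forced_choice <- function(trial_stack, cond_a, cond_b,
                                     model = NULL, train = NULL,
                                     levels = 1:5) {
  meta <- trial_stack$obs_meta
  if (is.null(meta$rating) || all(is.na(meta$rating)))
    stopf("trial stack has no rating metadata")
  if (is.null(model) && is.null(train))
    stopf("either a fixed model or a training spec is required")
  counts <- table(factor(meta$rating, levels = levels),
                  factor(meta$condition, levels = c(cond_a, cond_b)))
  reports <- vector("list", length(levels))
  names(reports) <- paste0("rating", levels)
  usable <- integer(length(levels))
  for (li in seq_along(levels)) {
    lv <- levels[li]
    subs <- unique(meta$subject)
    keep_subs <- subs[vapply(subs, function(s)
      any(meta$subject == s & meta$rating == lv & meta$condition == cond_a,
          na.rm = TRUE) &&
      any(meta$subject == s & meta$rating == lv & meta$condition == cond_b,
          na.rm = TRUE), TRUE)]
    usable[li] <- length(keep_subs)
    if (length(keep_subs) < 2) next
    rows_a <- lapply(keep_subs, function(s)
      which(meta$subject == s & meta$rating == lv & meta$condition == cond_a))
    rows_b <- lapply(keep_subs, function(s)
      which(meta$subject == s & meta$rating == lv & meta$condition == cond_b))
    avg <- rbind(
      t(vapply(rows_a, function(i)
        colMeans(trial_stack$data[i, , drop = FALSE]),
        numeric(ncol(trial_stack$data)))),
      t(vapply(rows_b, function(i)
        colMeans(trial_stack$data[i, , drop = FALSE]),
        numeric(ncol(trial_stack$data)))))
    lvl_stack <- masked_image_stack(
      avg, trial_stack$mask,
      data.frame(subject = rep(keep_subs, 2),
                 condition = rep(c(cond_a, cond_b), each = length(keep_subs)),
                 stringsAsFactors = FALSE),
      trial_stack$affine)
    reports[[li]] <- if (!is.null(model)) {
      suppressWarnings(forced_choice(model, lvl_stack, cond_a, cond_b))
    } else {
      k <- min(train$k %||% 5, length(keep_subs))
      repeated_cv_evaluate(lvl_stack, train$positive, train$negative,
                           pairs = list(c(cond_a, cond_b)),
                           C = train$C %||% 1, k = k,
                           n_repeats = train$n_repeats %||% 10,
                           seed = train$seed %||% 1)[[1]]
    }
  }
  structure(list(reports = reports, counts = counts, levels = levels,
                 usable_subjects = usable, flagged = usable < 2),
            class = "rating_stratified_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rating_stratified_report <- function(x, ...) {
  cat("<rating_stratified_report>\n")
  for (li in seq_along(x$levels)) {
    r <- x$reports[[li]]
    if (is.null(r)) {
      cat(sprintf("  rating %d: <%d usable subjects, skipped>\n",
                  x$levels[li], x$usable_subjects[li]))
    } else {
      cat(sprintf("  rating %d: %.1f%% accuracy (n = %d)\n",
                  x$levels[li], r$accuracy, r$n_subjects))
    }
  }
  invisible(x)
}

#' Per-level accuracy table from a stratified report
#'
#' @param report A `rating_stratified_report`.
#' @return Data frame with `rating`, `accuracy`, `accuracy_sd`, `p_value`,
#'   `n_subjects`, `flagged`.
#' @export
stratified_accuracy_table <- function(report) {
  do.call(rbind, lapply(seq_along(report$levels), function(li) {
    r <- report$reports[[li]]
    data.frame(rating = report$levels[li],
               accuracy = if (is.null(r)) NA_real_ else r$accuracy,
               accuracy_sd = if (is.null(r)) NA_real_ else r$accuracy_sd,
               p_value = if (is.null(r)) NA_real_ else r$p_value,
               n_subjects = report$usable_subjects[li],
               flagged = report$flagged[li])
  }))
}
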