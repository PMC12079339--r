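# Core-system identification: bootstrap-thresholded weight maps (backward
# model), Haufe-transformed encoding maps (forward model), and their
# conjunction.

#' Bootstrap test of signature weights
#'
#' Resamples subjects with replacement (all of a subject's images travel
#' together), retrains the SVM on each sample, and converts each voxel's
#' bootstrap weight distribution to `z = mean / SD` with a two-tailed
#' normal-theory p, then applies Benjamini-Hochberg FDR across in-mask
#' voxels. Degenerate voxels (zero bootstrap SD) get `z = 0`, `p = 1`.
#'
#' @param stack A `masked_image_stack`.
#' @param positive,negative Training condition sets.
#' @param C Soft-margin cost.
#' @param n_boot Bootstrap samples (>= 100; the reference analysis uses
#'   10000, desk default 1000).
#' @param q FDR level (default 0.05).
#' @param seed RNG seed.
#' @return Object of class `bootstrap_map`: per-voxel `mean`, `sd`, `z`, `p`,
#'   logical `significant`, plus `n_boot`, `q` and the redraw count.
#' @export
bootstrap_weights <- function(stack, positive, negative, C = 1,
                              n_boot = 1000, q = 0.05, seed = 1) {
  if (n_boot < 100) stopf("n_boot must be >= 100")
  subs <- unique(stack$obs_meta$subject)
  ns <- length(subs)
  V <- ncol(stack$data)
  W <- matrix(0, n_boot, V)
  redraws <- 0L
  local_seed(seed, {
    for (b in seq_len(n_boot)) {
      ok <- FALSE; tries <- 0L
      while (!ok) {
        draw <- sample(subs, ns, replace = TRUE)
        rows <- unlist(lapply(draw, function(s)
          which(stack$obs_meta$subject == s)), use.names = FALSE)
        cond <- stack$obs_meta$condition[rows]
        ok <- any(cond %in% positive) && any(cond %in% negative)
        if (!ok) {
          tries <- tries + 1L; redraws <- redraws + 1L
          if (tries >= 50L)
            stopf("50 consecutive bootstrap samples lacked a class")
        }
      }
      # Re-tag duplicated subjects so the per-subject completeness check in
      # train_signature sees each draw as its own unit.
      bs <- masked_image_stack(stack$data[rows, , drop = FALSE], stack$mask,
                               data.frame(
                                 subject = rep(sprintf("bs%03d", seq_len(ns)),
                                               vapply(draw, function(s)
                                                 sum(stack$obs_meta$subject == s),
                                                 0L)),
                                 condition = cond,
                                 stringsAsFactors = FALSE),
                               stack$affine)
      W[b, ] <- train_signature(bs, positive, negative, C)$weights
    }
  })
  m <- colMeans(W)
  s <- sqrt(colSums(sweep(W, 2, m)^2) / (n_boot - 1))
  z <- ifelse(s > 0, m / s, 0)
  p <- ifelse(s > 0, pmax(2 * stats::pnorm(-abs(z)), 1e-300), 1)
  fdr <- bh_fdr(p, q)
  structure(list(mean = m, sd = s, z = z, p = p,
                 significant = fdr$significant, p_adjusted = fdr$p_adjusted,
                 n_boot = n_boot, q = q, redraws = redraws),
            class = "bootstrap_map")
}

#' @export
print.bootstrap_map <- function(x, ...) {
  cat(sprintf("<bootstrap_map> %d voxels, n_boot = %d; %d significant at q = %g\n",
              length(x$z), x$n_boot, sum(x$significant), x$q))
  invisible(x)
}

#' Haufe forward-model encoding map
#'
#' Transforms a backward-model weight vector into forward-model "structure
#' coefficients": per subject, the covariance between each voxel's values and
#' the signature response over that subject's observations (equivalently
#' `Sigma_x %*% w` with the subject's sample covariance). A group one-sample
#' t-test per voxel with Benjamini-Hochberg FDR gives the encoding mask.
#' With `unit = "group"` a single pooled-covariance map is returned instead
#' (no t-test).
#'
#' @param stack A `masked_image_stack`; each subject needs >= 2 observations.
#' @param model A `linear_pattern_model`.
#' @param q FDR level (default 0.05).
#' @param unit `"subject"` (default) or `"group"`.
#' @param conditions Optional condition subset entering the covariance
#'   (default: all observations).
#' @return Object of class `encoding_map`: subject x voxel matrix `A` of
#'   structure coefficients, group `t`, `p`, `significant`, `mean`.
#' @export
haufe_encode <- function(stack, model, q = 0.05,
                         unit = c("subject", "group"), conditions = NULL) {
  unit <- match.arg(unit)
  if (!is.null(conditions))
    stack <- stack_subset(stack, stack$obs_meta$condition %in% conditions)
  r_all <- pattern_response(model, stack)
  if (unit == "group") {
    Xc <- scale(stack$data, center = TRUE, scale = FALSE)
    a <- drop(crossprod(Xc, r_all - mean(r_all))) / (nrow(Xc) - 1)
    return(structure(list(A = matrix(a, 1), t = NULL, p = NULL,
                          significant = NULL, mean = a, q = q,
                          unit = "group"),
                     class = "encoding_map"))
  }
  subs <- unique(stack$obs_meta$subject)
  A <- matrix(NA_real_, length(subs), ncol(stack$data))
  keep <- logical(length(subs))
  for (i in seq_along(subs)) {
    sel <- stack$obs_meta$subject == subs[i]
    if (sum(sel) < 2)
      stopf("subject %s has fewer than 2 observations", subs[i])
    r <- r_all[sel]
    if (stats::sd(r) == 0) {
      warnf("subject %s has zero response variance; excluded", subs[i])
      next
    }
    Xc <- scale(stack$data[sel, , drop = FALSE], center = TRUE, scale = FALSE)
    A[i, ] <- drop(crossprod(Xc, r - mean(r))) / (sum(sel) - 1)
    keep[i] <- TRUE
  }
  A <- A[keep, , drop = FALSE]
  n <- nrow(A)
  if (n < 3) stopf("group t-test needs >= 3 contributing subjects, got %d", n)
  m <- colMeans(A)
  s <- sqrt(colSums(sweep(A, 2, m)^2) / (n - 1))
  t <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  p <- ifelse(s > 0, pmax(2 * stats::pt(-abs(t), n - 1), 1e-300), 1)
  fdr <- bh_fdr(p, q)
  structure(list(A = A, t = t, p = p, significant = fdr$significant,
                 p_adjusted = fdr$p_adjusted, mean = m, q = q,
                 unit = "subject", n_subjects = n),
            class = "encoding_map")
}

#' @export
print.encoding_map <- function(x, ...) {
  cat(sprintf("<encoding_map> %d voxels (%s level)%s\n",
              length(x$mean), x$unit,
              if (!is.null(x$significant))
                sprintf("; %d significant at q = %g", sum(x$significant), x$q)
              else ""))
  invisible(x)
}

#' Conjunction core-system map
#'
#' Voxels surviving both the bootstrap weight test (backward model) and the
#' encoding-map group t-test (forward model). Weights outside the conjunction
#' are set to 0. The core map is a visualization/interpretation product:
#' classification always uses the full weight vector, never this map.
#'
#' @param bmap A `bootstrap_map`.
#' @param emap An `encoding_map` with a significance mask.
#' @param model The `linear_pattern_model` whose weights are retained inside
#'   the conjunction.
#' @return Object of class `core_system_map`: logical `mask` and `weights`.
#' @export
conjunction_core <- function(bmap, emap, model) {
  if (length(bmap$z) != length(emap$mean) ||
      length(bmap$z) != length(model$weights))
    stopf("bootstrap, encoding and model voxel spaces differ")
  if (is.null(emap$significant))
    stopf("encoding map carries no significance mask (group unit)")
  mask <- bmap$significant & emap$significant
  if (!any(mask)) warnf("empty core-system conjunction")
  w <- model$weights
  w[!mask] <- 0
  structure(list(mask = mask, weights = w,
                 n_voxels = sum(mask)), class = "core_system_map")
}

#' @export
print.core_system_map <- function(x, ...) {
  cat(sprintf("<core_system_map> %d / %d voxels in conjunction\n",
              x$n_voxels, length(x$mask)))
  invisible(x)
}
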