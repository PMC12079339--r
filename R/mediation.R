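# Multilevel two-path mediation: per-subject OLS path coefficients with
# bootstrap (over subjects) inference on the indirect effect a*b.

#' Multilevel two-path mediation
#'
#' Per subject, OLS regressions give the paths: `a` from `m ~ x`, `b` and
#' `c'` from `y ~ x + m`, `c` from `y ~ x`; the OLS identity `c = c' + a*b`
#' holds exactly per subject. Group-level inference bootstraps subjects with
#' replacement: the statistic for each path is the across-subject mean of the
#' per-subject coefficients (for the indirect effect, the mean of the
#' per-subject products `a_i * b_i`), with percentile CIs and two-tailed
#' bootstrap p-values. The mediation verdict requires `a`, `b` and `a*b` all
#' significant; it is labeled partial when `c'` remains significant,
#' complete otherwise.
#'
#' @param x,m,y Per-trial numeric vectors: predictor response, mediator
#'   response, and outcome rating.
#' @param subject Per-trial subject ids.
#' @param n_boot Bootstrap iterations (default 2000; the reference analysis
#'   uses 10000).
#' @param seed RNG seed.
#' @param standardize Z-score `x` and `m` within subject before fitting
#'   (default TRUE; `y` is used raw).
#' @param conf_level CI level (default 0.95).
#' @return Object of class `mediation_result` with per-subject `paths`
#'   (a, b, c, c_prime, ab), group `estimates`, bootstrap `ci` and `p`,
#'   `verdict` and `label`.
#' @export
mediate <- function(x, m, y, subject, n_boot = 2000, seed = 1,
                    standardize = TRUE, conf_level = 0.95) {
  n <- length(x)
  if (length(m) != n || length(y) != n || length(subject) != n)
    stopf("x, m, y, subject must have equal length")
  subs <- unique(subject)
  if (length(subs) < 10)
    warnf("only %d subjects; multilevel inference will be unstable",
          length(subs))
  paths <- matrix(NA_real_, length(subs), 5,
                  dimnames = list(subs, c("a", "b", "c", "c_prime", "ab")))
  dropped <- character(0)
  for (i in seq_along(subs)) {
    sel <- subject == subs[i]
    xi <- x[sel]; mi <- m[sel]; yi <- y[sel]
    if (sum(sel) < 3 || stats::sd(xi) == 0 || stats::sd(mi) == 0) {
      dropped <- c(dropped, subs[i])
      next
    }
    if (standardize) {
      xi <- (xi - mean(xi)) / stats::sd(xi)
      mi <- (mi - mean(mi)) / stats::sd(mi)
    }
    if (abs(stats::cor(xi, mi)) > 0.999)
      stopf("x and m are collinear within subject %s; c' unidentifiable",
            subs[i])
    a <- stats::coef(stats::lm.fit(cbind(1, xi), mi))[2]
    cf <- stats::coef(stats::lm.fit(cbind(1, xi, mi), yi))
    cc <- stats::coef(stats::lm.fit(cbind(1, xi), yi))[2]
    paths[i, ] <- c(a, cf[3], cc, cf[2], a * cf[3])
  }
  if (length(dropped)) {
    warnf("dropped %d subject(s) with zero-variance responses: %s",
          length(dropped), paste(dropped, collapse = ", "))
    if (length(dropped) > 0.3 * length(subs))
      stopf("more than 30%% of subjects dropped (%d / %d)",
            length(dropped), length(subs))
  }
  paths <- paths[!rownames(paths) %in% dropped, , drop = FALSE]
  nk <- nrow(paths)
  est <- colMeans(paths)
  boot <- local_seed(seed, {
    t(vapply(seq_len(n_boot), function(b)
      colMeans(paths[sample.int(nk, nk, replace = TRUE), , drop = FALSE]),
      numeric(5)))
  })
  alpha <- 1 - conf_level
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2))
  pv <- apply(boot, 2, function(bb) {
    lo <- (1 + sum(bb <= 0)) / (1 + length(bb))
    hi <- (1 + sum(bb >= 0)) / (1 + length(bb))
    min(1, 2 * min(lo, hi))
  })
  sig <- pv < alpha
  verdict <- sig[["a"]] && sig[["b"]] && sig[["ab"]]
  label <- if (!verdict) "none"
    else if (sig[["c_prime"]]) "partial" else "complete"
  structure(list(paths = paths, estimates = est, boot = boot, ci = ci,
                 p = pv, n_boot = n_boot, conf_level = conf_level,
                 n_subjects = nk, dropped = dropped,
                 verdict = verdict, label = label),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> n = %d subjects, %d bootstrap samples\n",
              x$n_subjects, x$n_boot))
  for (p in colnames(x$paths))
    cat(sprintf("  %-7s %7.3f  CI [%7.3f, %7.3f]  p = %.4f\n", p,
                x$estimates[[p]], x$ci[1, p], x$ci[2, p], x$p[[p]]))
  cat(sprintf("  mediation: %s\n", x$label))
  invisible(x)
}

#' Signature-level mediation on a single-trial stack
#'
#' Computes the per-trial pattern responses of two signatures on a
#' single-trial stack, takes the trial ratings as the outcome, and runs
#' [mediate()] in both directions (X -> M -> Y and M -> X -> Y).
#'
#' @param stack Single-trial `masked_image_stack` with ratings.
#' @param sig_x,sig_m `linear_pattern_model`s (or weight vectors) aligned to
#'   the stack.
#' @param ... Passed to [mediate()].
#' @return List with elements `forward` (`sig_x` as predictor, `sig_m` as
#'   mediator) and `reverse` (roles swapped), each a `mediation_result`.
#' @export
signature_mediation <- function(stack, sig_x, sig_m, ...) {
  if (is.null(stack$obs_meta$rating) || all(is.na(stack$obs_meta$rating)))
    stopf("stack has no ratings")
  if (!inherits(sig_x, "linear_pattern_model"))
    sig_x <- linear_pattern_model(sig_x)
  if (!inherits(sig_m, "linear_pattern_model"))
    sig_m <- linear_pattern_model(sig_m)
  x <- pattern_response(sig_x, stack)
  m <- pattern_response(sig_m, stack)
  y <- stack$obs_meta$rating
  sub <- stack$obs_meta$subject
  list(forward = mediate(x, m, y, sub, ...),
       reverse = mediate(m, x, y, sub, ...))
}
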