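# Shared statistical primitives: summary-statistic t-tests, Cohen's d,
# paired t, Benjamini-Hochberg FDR.

#' Summary statistics for one group
#'
#' @param mean,sd,n Group mean, standard deviation (>= 0) and size (>= 2).
#' @return Object of class `summary_stats`.
#' @export
summary_stats <- function(mean, sd, n) {
  if (sd < 0) stopf("sd must be non-negative")
  if (n < 2) stopf("n must be >= 2")
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stats")
}

#' Two-sample t-test from printed summary statistics
#'
#' Pooled (equal-variance) variant:
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`,
#' `t = (m1 - m2) / (sp sqrt(1/n1 + 1/n2))`, `df = n1 + n2 - 2`. The Welch
#' variant uses per-group variances and Satterthwaite df.
#'
#' @param g1,g2 `summary_stats` objects (or lists with mean, sd, n).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-tailed) and a `degenerate` flag set
#'   when both SDs are zero with differing means (infinite t).
#' @export
two_sample_t_from_summary <- function(g1, g2,
                                      variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  m1 <- g1$mean; s1 <- g1$sd; n1 <- g1$n
  m2 <- g2$mean; s2 <- g2$sd; n2 <- g2$n
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p = 1,
                              degenerate = FALSE))
    return(list(t = Inf * sign(m1 - m2), df = n1 + n2 - 2, p = 0,
                degenerate = TRUE))
  }
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
    t <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Cohen's d from condition summary statistics
#'
#' Average-variance pooling of the two condition SDs:
#' `d = (m2 - m1) / sqrt((s1^2 + s2^2) / 2)`.
#'
#' @param g1,g2 `summary_stats` objects.
#' @return List with `d` and a `degenerate` flag (zero pooled SD).
#' @export
cohens_d_summary <- function(g1, g2) {
  sp <- sqrt((g1$sd^2 + g2$sd^2) / 2)
  if (sp == 0) return(list(d = NA_real_, degenerate = TRUE))
  list(d = (g2$mean - g1$mean) / sp, degenerate = FALSE)
}

#' Paired t-test with effect size
#'
#' Standard paired t on the differences with `df = n - 1`;
#' `d_z = mean(diff) / sd(diff)`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return List with `t`, `df`, `p`, `d_z`, `mean_diff` and a `degenerate`
#'   flag set when the differences have zero variance.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2) stopf("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) <= 1e-12 * (1 + abs(mean(d))))
    return(list(t = NA_real_, df = length(d) - 1, p = NA_real_,
                d_z = NA_real_, mean_diff = mean(d), degenerate = TRUE))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d_z = mean(d) / stats::sd(d), mean_diff = mean(d),
       degenerate = FALSE)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `q`; adjusted p-values via
#' `p.adjust(method = "BH")`.
#'
#' @param p Vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with logical `significant`, `p_adjusted`, and `threshold`
#'   (largest raw p declared significant; 0 if none).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!length(p))
    return(list(significant = logical(0), p_adjusted = numeric(0),
                threshold = 0))
  if (any(p <= 0 | p > 1 | is.na(p))) stopf("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  sig <- adj <= q
  list(significant = sig, p_adjusted = adj,
       threshold = if (any(sig)) max(p[sig]) else 0)
}
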