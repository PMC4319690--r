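#' One-sample contrast of percent-change values
#'
#' Two-tailed one-sample Student's t-test of per-subject percent-change
#' values against zero, reported with Cohen's d (`mean / sd`) as the effect
#' size since planned contrasts inflate the type-I risk.
#'
#' @param values numeric vector, one value per subject (n >= 2, finite).
#' @param condition optional label carried into the output.
#' @return one-row tibble of class `tremor_contrast`: `condition`, `n`,
#'   `mean_pct_change`, `sem`, `t_stat`, `df`, `p_two_sided`, `cohens_d`.
#' @examples
#' one_sample_contrast(c(12, 18, 25, 9, 14, 21))
#' @export
one_sample_contrast <- function(values, condition = NA_character_) {
  if (length(values) < 2L) {
    stop_tremor("Need at least 2 values for a one-sample contrast.", "validation")
  }
  if (any(!is.finite(values))) stop_tremor("Values must be finite.", "validation")
  n <- length(values)
  s <- sd(values)
  if (s < .Machine$double.eps) {
    stop_tremor("Zero variance: the contrast is degenerate.", "degenerate")
  }
  m <- mean(values)
  sem <- s / sqrt(n)
  t_stat <- m / sem
  out <- tibble(
    condition = condition, n = n, mean_pct_change = m, sem = sem,
    t_stat = t_stat, df = n - 1L,
    p_two_sided = 2 * pt(-abs(t_stat), df = n - 1L),
    cohens_d = m / s
  )
  structure(out, class = c("tremor_contrast", class(out)))
}

#' Exact Wilcoxon signed-rank test against zero
#'
#' Ranks the absolute values of the nonzero observations (midranks on ties;
#' zeros dropped, the standard convention) and reports the sum of ranks of
#' the positive observations. For n <= 25 the two-sided p-value is exact,
#' computed from the null distribution over all 2^n equiprobable sign
#' assignments (a shift-algorithm convolution, so tied ranks are handled
#' exactly); beyond that a normal approximation with tie correction is used.
#'
#' @param values numeric vector (e.g. ordinal ratings); zeros are dropped.
#' @return one-row tibble: `statistic` (positive-rank sum), `n_nonzero`,
#'   `p_two_sided`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(0, rep(c(3, 5, 7), length.out = 11)))
#' @export
wilcoxon_signed_rank <- function(values) {
  if (any(!is.finite(values))) stop_tremor("Values must be finite.", "validation")
  v <- values[values != 0]
  n <- length(v)
  if (n == 0L) stop_tremor("All values are zero; test is degenerate.", "degenerate")
  r <- rank(abs(v))
  w_pos <- sum(r[v > 0])
  if (n <= 25L) {
    # exact null over sign assignments: convolve P(W = s) with half-integer
    # midranks doubled to integers
    r2 <- round(2 * r)
    total <- sum(r2)
    probs <- numeric(total + 1L)  # index s -> P(2W = s)
    probs[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), probs[seq_len(total + 1L - ri)])
      probs <- (probs + shifted) / 2
    }
    w2 <- round(2 * w_pos)
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approx"
  }
  tibble(statistic = w_pos, n_nonzero = n, p_two_sided = p, method = method)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a user-declared family of p-values (delegating
#' to `stats::p.adjust`). Adjusted values are monotone after sorting and
#' capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @examples
#' bh_fdr(c(0.001, 0.2, 0.6, 0.3, 0.67))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) stop_tremor("Empty p-value vector.", "validation")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_tremor("p-values must lie in [0, 1].", "validation")
  }
  p.adjust(p, method = "BH")
}

#' Contrast table across conditions
#'
#' One-sample contrasts of per-subject percent change for every condition in
#' a multi-subject condition-summary table, FDR-adjusted within the table's
#' family of comparisons.
#'
#' @param summaries tibble with columns `subject_id`, `condition`,
#'   `pct_change` (as produced by stacking [condition_summary()] rows over
#'   subjects). The sham rows (pct_change identically 0) are excluded.
#' @param adjust apply [bh_fdr()] across the condition family.
#' @return tibble with one `tremor_contrast` row per condition (+ `p_fdr`).
#' @export
contrast_table <- function(summaries, adjust = TRUE) {
  stopifnot(all(c("condition", "pct_change") %in% names(summaries)))
  conds <- setdiff(unique(summaries$condition), c("sham", "initial"))
  out <- list_rbind(map(conds, function(cc) {
    one_sample_contrast(summaries$pct_change[summaries$condition == cc],
                        condition = cc)
  }))
  if (adjust) out$p_fdr <- bh_fdr(out$p_two_sided)
  out
}
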