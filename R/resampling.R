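#' One-tailed bootstrap comparison of two groups
#'
#' Resamples each group with replacement at its own size; the statistic is
#' `mean(b) - mean(a)`. The p-value is the plus-one-corrected fraction of
#' resampled statistics on the non-alternative side of 0, with exact zeros
#' counted half: `p = (1 + #violations) / (n_boot + 1)`.
#'
#' @param a,b numeric samples (e.g. per-session values per cohort).
#' @param n_boot bootstrap resamples (>= 1000).
#' @param tail "greater" tests b > a; "less" tests b < a.
#' @param seed integer seed for the resampling.
#' @return list of class `bootstrap_result`: `observed_diff`, `p_value`,
#'   `n_boot`, `tail`.
#' @export
bootstrap_diff_test <- function(a, b, n_boot = 1000, tail = c("greater", "less"),
                                seed = 1L) {
  tail <- match.arg(tail)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  if (n_boot < 1000) stop("n_boot must be >= 1000")
  set.seed(seed)
  na <- length(a); nb <- length(b)
  d <- vapply(seq_len(n_boot), function(i) {
    mean(b[sample.int(nb, nb, replace = TRUE)]) -
      mean(a[sample.int(na, na, replace = TRUE)])
  }, numeric(1))
  viol <- if (tail == "greater") sum(d < 0) + 0.5 * sum(d == 0)
          else sum(d > 0) + 0.5 * sum(d == 0)
  structure(list(observed_diff = mean(b) - mean(a),
                 p_value = (1 + viol) / (n_boot + 1),
                 n_boot = as.integer(n_boot), tail = tail),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> diff = %.4g, one-tailed (%s) p = %.4g (B = %d)\n",
              x$observed_diff, x$tail, x$p_value, x$n_boot))
  invisible(x)
}

#' Benjamini-Hochberg FDR step-up rule
#'
#' Rejects all hypotheses with rank at most the largest k such that
#' `p_(k) <= k q / m`.
#'
#' @param p_values numeric vector of p-values in \[0,1\].
#' @param q target false discovery rate, in (0,1).
#' @return logical rejection mask aligned with `p_values`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0,1)")
  m <- length(p)
  if (m == 0) return(logical(0))
  o <- order(p)
  ok <- p[o] <= seq_len(m) * q / m
  kmax <- if (any(ok)) max(which(ok)) else 0L
  rej <- logical(m)
  if (kmax > 0) rej[o[seq_len(kmax)]] <- TRUE
  rej
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of comparisons.
#' @return per-comparison threshold `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}
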