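# shared numeric helpers

#' Centered boxcar smoothing with reflected edges
#'
#' Window width is forced odd so the filter is symmetric; edge handling is
#' half-sample symmetric reflection, which preserves the trace mean exactly.
#'
#' @param x numeric vector or matrix (rows smoothed independently).
#' @param window_s smoothing window in seconds.
#' @param rate sampling rate in Hz.
#' @return smoothed object of the same shape.
#' @export
smooth_boxcar <- function(x, window_s = 0.5, rate = 9.35) {
  w <- max(1L, round(window_s * rate))
  if (w %% 2 == 0) w <- w + 1L
  if (is.matrix(x)) return(t(apply(x, 1, .boxcar1, w = w)))
  .boxcar1(x, w)
}

.boxcar1 <- function(x, w) {
  if (w <= 1 || length(x) < 2) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  h <- min(h, n)                                     # degenerate short traces
  pad <- c(rev(x[seq_len(h)]), x, rev(x[seq.int(n - h + 1L, n)]))
  as.numeric(stats::filter(pad, rep(1 / (2 * h + 1), 2 * h + 1),
                           sides = 2))[seq.int(h + 1L, h + n)]
}

# per-target normalized squared error: SSE / SS_total, averaged over targets
normalized_sq_error <- function(Y, Yhat) {
  nse <- vapply(seq_len(ncol(Y)), function(j) {
    ss <- sum((Y[, j] - mean(Y[, j]))^2)
    if (ss == 0) return(NA_real_)
    sum((Y[, j] - Yhat[, j])^2) / ss
  }, numeric(1))
  mean(nse, na.rm = TRUE)
}

# contiguous-block fold assignment for t samples
fold_blocks <- function(t, folds) {
  if (t < folds) stop("fewer samples (", t, ") than folds (", folds, ")")
  sort(rep_len(seq_len(folds), t))
}

# empty-safe column orthonormalization; errors on rank loss
orthonormalize <- function(B) {
  B <- as.matrix(B)
  if (ncol(B) == 0) stop("zero-dimensional basis")
  q <- qr(B)
  if (q$rank < ncol(B)) stop("basis is rank-deficient")
  qr.Q(q)[, seq_len(ncol(B)), drop = FALSE]
}
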