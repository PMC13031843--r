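# Communication subspaces: ridge / reduced-rank regression, principal-angle
# subspace similarity, spatial and temporal degeneracy, and ablation of
# predictive dimensions.

#' Ridge regression with cross-validated regularizer
#'
#' `B = (X'X + lambda I)^{-1} X'Y` with `lambda` chosen from a grid by
#' 10-fold cross-validation (normalized squared error). `lambda = 0` with
#' rank-deficient `X` raises an explicit singularity error.
#'
#' @param X t x p source matrix (t > p).
#' @param Y t x q target matrix.
#' @param lambda_grid candidate regularizers; a single value skips CV.
#' @param folds CV folds.
#' @return list of class `ridge_fit`: `B_ridge`, `lambda`, `cv_table`.
#' @export
ridge_fit <- function(X, Y, lambda_grid = 10^seq(-3, 3, length.out = 10),
                      folds = 10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (nrow(X) <= ncol(X))
    warning("t <= p: ridge fit is underdetermined without regularization")
  cv_table <- NULL
  if (length(lambda_grid) > 1) {
    perf <- ridge_cv_performance(X, Y, lambda_grid, folds)
    lambda <- attr(perf, "lambda")
    cv_table <- attr(perf, "cv_table")
  } else lambda <- lambda_grid
  B <- .ridge_solve(X, Y, lambda)
  structure(list(B_ridge = B, lambda = lambda, cv_table = cv_table),
            class = "ridge_fit")
}

.ridge_solve <- function(X, Y, lambda) {
  A <- crossprod(X) + lambda * diag(ncol(X))
  tryCatch(solve(A, crossprod(X, Y)),
           error = function(e)
             stop("singular system: X is rank-deficient and lambda = ",
                  lambda, call. = FALSE))
}

#' Reduced-rank regression via the ridge solution
#'
#' The rank of the coefficient matrix is limited to `m` by projecting the
#' ridge solution onto the top-`m` principal directions `V` of the
#' ridge-predicted targets `Yhat = X B_ridge` (default), or of the
#' cross-covariance `cov(X, Y)` (`v_from = "cross"`):
#' `B_rrr = B_ridge V V'`; the predictive dimensions are the columns of
#' `B_bar = B_ridge V`.
#'
#' @param X t x p source matrix.
#' @param Y t x q target matrix.
#' @param m rank, `0 <= m <= q`.
#' @param lambda regularizer; `NULL` selects by CV via [ridge_fit()].
#' @param v_from "predicted" (default) or "cross".
#' @return list of class `rrr_fit`: `V` (q x m, orthonormal), `B_bar`
#'   (p x m), `B_rrr` (p x q), `B_ridge`, `rank`, `lambda`.
#' @export
rrr_fit <- function(X, Y, m, lambda = NULL, v_from = c("predicted", "cross")) {
  v_from <- match.arg(v_from)
  X <- as.matrix(X); Y <- as.matrix(Y)
  q <- ncol(Y)
  if (m < 0 || m > q) stop("rank m must satisfy 0 <= m <= q")
  rf <- if (is.null(lambda)) ridge_fit(X, Y) else ridge_fit(X, Y, lambda)
  B <- rf$B_ridge
  if (m == 0) {
    V <- matrix(0, q, 0)
  } else {
    V <- if (v_from == "predicted") svd(X %*% B, nu = 0, nv = m)$v[, seq_len(m), drop = FALSE]
         else svd(stats::cov(X, Y), nu = 0, nv = m)$v[, seq_len(m), drop = FALSE]
  }
  structure(list(V = V, B_bar = B %*% V, B_rrr = B %*% tcrossprod(V),
                 B_ridge = B, rank = m, lambda = rf$lambda),
            class = "rrr_fit")
}

#' @export
predict.rrr_fit <- function(object, newdata, ...) {
  as.matrix(newdata) %*% object$B_rrr
}

#' Cross-validated performance by rank and the one-SEM optimal rank
#'
#' Per fold, a ridge fit and its principal directions are estimated on the
#' training block and evaluated on the held-out block at every requested
#' rank; performance is `1 - cvl`. The optimal rank is the smallest rank
#' whose performance is within one SEM (across folds, at the peak) of the
#' peak performance.
#'
#' @param X,Y source/target matrices.
#' @param ranks ranks evaluated (default 1:10).
#' @param folds CV folds.
#' @param lambda regularizer (`NULL`: CV-selected once on the full data).
#' @param v_from see [rrr_fit()].
#' @return list: `perf_by_rank` (data.frame rank/performance/sem),
#'   `optimal_rank`.
#' @export
performance_curve <- function(X, Y, ranks = 1:10, folds = 10, lambda = NULL,
                              v_from = c("predicted", "cross")) {
  v_from <- match.arg(v_from)
  X <- as.matrix(X); Y <- as.matrix(Y)
  ranks <- sort(unique(as.integer(ranks)))
  if (max(ranks) > ncol(Y)) stop("rank exceeds number of targets")
  if (is.null(lambda)) {
    p0 <- ridge_cv_performance(X, Y, folds = folds)
    lambda <- attr(p0, "lambda")
  }
  fb <- fold_blocks(nrow(X), folds)
  perf <- matrix(NA_real_, folds, length(ranks))
  for (f in seq_len(folds)) {
    tr <- fb != f
    B <- .ridge_solve(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], lambda)
    V <- if (v_from == "predicted")
      svd(X[tr, , drop = FALSE] %*% B, nu = 0)$v
    else svd(stats::cov(X[tr, , drop = FALSE], Y[tr, , drop = FALSE]), nu = 0)$v
    for (ri in seq_along(ranks)) {
      Vm <- V[, seq_len(ranks[ri]), drop = FALSE]
      Yhat <- X[!tr, , drop = FALSE] %*% B %*% tcrossprod(Vm)
      perf[f, ri] <- 1 - normalized_sq_error(Y[!tr, , drop = FALSE], Yhat)
    }
  }
  mu <- colMeans(perf)
  sem <- apply(perf, 2, stats::sd) / sqrt(folds)
  peak <- which.max(mu)
  optimal <- ranks[min(which(mu >= mu[peak] - sem[peak]))]
  list(perf_by_rank = data.frame(rank = ranks, performance = mu, sem = sem),
       optimal_rank = optimal)
}

#' Cosine of the principal angle between two subspaces
#'
#' Bases are orthonormalized by QR; the singular values of `Qa' Qb` are the
#' cosines of the principal angles. The reported similarity is the cosine
#' of the largest principal angle (the smallest singular value) by default.
#'
#' @param basis_a,basis_b p x k matrices spanning the subspaces.
#' @param angle "largest" (default) or "smallest" principal angle.
#' @return cosine in \[0,1\].
#' @export
subspace_similarity <- function(basis_a, basis_b,
                                angle = c("largest", "smallest")) {
  angle <- match.arg(angle)
  Qa <- orthonormalize(basis_a)
  Qb <- orthonormalize(basis_b)
  if (nrow(Qa) != nrow(Qb)) stop("bases live in different ambient spaces")
  s <- svd(crossprod(Qa, Qb), nu = 0, nv = 0)$d
  s <- pmin(pmax(s, 0), 1)
  if (angle == "largest") min(s) else max(s)
}

#' Spatial degeneracy: similarity of subspaces toward two targets
#'
#' Fits reduced-rank regressions from one source population to two target
#' populations and reports the principal-angle similarity of the first
#' `dims` predictive dimensions (columns of `B_bar`).
#'
#' @param source t x p source activity.
#' @param target_a,target_b t x q activity of the two targets.
#' @param dims subspace dimensionality compared (default 3).
#' @param lambda regularizer (`NULL`: CV).
#' @param ... passed to [subspace_similarity()].
#' @return similarity in \[0,1\]; attribute `fits` holds the two `rrr_fit`s.
#' @export
spatial_degeneracy <- function(source, target_a, target_b, dims = 3,
                               lambda = NULL, ...) {
  fa <- rrr_fit(source, target_a, m = dims, lambda = lambda)
  fb <- rrr_fit(source, target_b, m = dims, lambda = lambda)
  if (ncol(fa$B_bar) < dims || ncol(fb$B_bar) < dims)
    stop("a fit has rank below dims")
  structure(subspace_similarity(fa$B_bar, fb$B_bar, ...),
            fits = list(a = fa, b = fb))
}

#' One-second trial windows for temporal degeneracy
#'
#' Frame indices (concatenated over trials) for the seven 1-s windows: ITI
#' (−1 to 0 s), stimulus, delay 1-4, action (first second).
#'
#' @param session a `cortex_session`.
#' @param trials trial indices (default all).
#' @return named list of frame-index vectors.
#' @export
one_second_windows <- function(session, trials = seq_len(nrow(session$trials))) {
  rate <- session$frame_rate_hz
  bounds <- list(ITI = c(-1, 0), stimulus = c(0, 1), delay1 = c(1, 2),
                 delay2 = c(2, 3), delay3 = c(3, 4), delay4 = c(4, 5),
                 action = c(5, 6))
  lapply(bounds, function(b) {
    unlist(lapply(trials, function(t) {
      onset <- session$trials$onset_frame[t]
      seq.int(sec_to_frame(b[1], rate) + onset + 1L,
              sec_to_frame(b[2], rate) + onset)
    }), use.names = FALSE)
  })
}

#' Temporal degeneracy: subspace similarity across trial windows
#'
#' Fits one reduced-rank regression per time window and returns the matrix
#' of pairwise similarities between the per-window predictive subspaces
#' (diagonal = 1).
#'
#' @param source p-neuron source activity, neurons x frames (full session).
#' @param target q-neuron target activity, neurons x frames.
#' @param windows named list of frame-index vectors (e.g.
#'   [one_second_windows()]).
#' @param dims subspace dimensionality (default 3).
#' @param lambda regularizer (`NULL`: CV per window).
#' @param ... passed to [subspace_similarity()].
#' @return k x k similarity matrix with window names.
#' @export
temporal_degeneracy <- function(source, target, windows, dims = 3,
                                lambda = NULL, ...) {
  k <- length(windows)
  fits <- lapply(windows, function(fr) {
    if (length(fr) <= nrow(source))
      stop("window with insufficient frames (", length(fr), " frames for ",
           nrow(source), " source neurons)")
    rrr_fit(t(source[, fr, drop = FALSE]), t(target[, fr, drop = FALSE]),
            m = dims, lambda = lambda)
  })
  sim <- matrix(1, k, k, dimnames = list(names(windows), names(windows)))
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    sim[i, j] <- sim[j, i] <-
      subspace_similarity(fits[[i]]$B_bar, fits[[j]]$B_bar, ...)
  }
  sim
}

#' Ablate source activity along predictive dimensions
#'
#' Removes the source-activity component correlated with the first
#' `m_remove` predictive dimensions of a fitted communication subspace:
#' `M = B_bar' Sigma` (Sigma = source covariance), `Q` = the last
#' `p - m_remove` right-singular vectors of `M` (so `M Q = 0`,
#' `Q'Q = I`), and the ablated activity is `X_hat = X Q`.
#'
#' @param X t x p source activity.
#' @param fit an `rrr_fit` from `X` to some target.
#' @param m_remove number of predictive dimensions removed (0-3 typical;
#'   must be < p).
#' @return list of class `ablation_projection`: `M`, `Sigma`, `Q`, `X_hat`.
#' @export
ablate_predictive_dims <- function(X, fit, m_remove) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (m_remove >= p) stop("m_remove must be smaller than the source dimension")
  Sigma <- stats::cov(X)
  if (m_remove == 0) {
    Q <- diag(p)
    M <- matrix(0, 0, p)
  } else {
    if (ncol(fit$B_bar) < m_remove) stop("fit has rank below m_remove")
    M <- t(fit$B_bar[, seq_len(m_remove), drop = FALSE]) %*% Sigma
    Q <- svd(M, nu = 0, nv = p)$v[, seq.int(m_remove + 1, p), drop = FALSE]
    if (max(abs(M %*% Q)) > 1e-8)
      stop("ablation failed: M Q not numerically zero")
  }
  structure(list(M = M, Sigma = Sigma, Q = Q, X_hat = X %*% Q),
            class = "ablation_projection")
}

#' Prediction performance after predictive-dimension ablation
#'
#' Re-fits a cross-validated ridge prediction of any predicted population
#' from the ablated source activity and reports performance normalized by
#' the matched unablated performance.
#'
#' @param X t x p source activity.
#' @param Y_pred t x q activity of the predicted population.
#' @param fit `rrr_fit` of the source onto the *target* population whose
#'   dimensions are ablated (the predicted population may differ).
#' @param m_remove dimensions removed.
#' @param ... passed to [ridge_cv_performance()].
#' @return list: `performance` (ablated), `baseline` (unablated),
#'   `normalized` (ratio), `ablation` (the projection).
#' @export
ablated_prediction <- function(X, Y_pred, fit, m_remove, ...) {
  ab <- ablate_predictive_dims(X, fit, m_remove)
  perf_ab <- as.numeric(ridge_cv_performance(ab$X_hat, Y_pred, ...))
  perf_un <- as.numeric(ridge_cv_performance(X, Y_pred, ...))
  list(performance = perf_ab, baseline = perf_un,
       normalized = perf_ab / perf_un, ablation = ab)
}
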