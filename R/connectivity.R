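# The three functional-interaction metrics: ITI pairwise correlation,
# trial-by-trial correlation, and cross-validated ridge population prediction.

#' Activity-inclusion gate
#'
#' A neuron is "active" if its z-scored activity exceeds `thresh` at least
#' once in every `span_min`-minute span of the recording.
#'
#' @param session a `cortex_session`.
#' @param thresh activity threshold (default 10).
#' @param span_min span length in minutes (default 10).
#' @return logical vector over neurons.
#' @export
active_neurons <- function(session, thresh = 10, span_min = 10) {
  nf <- ncol(session$activity)
  span <- max(1L, as.integer(round(span_min * 60 * session$frame_rate_hz)))
  starts <- seq.int(1L, nf, by = span)
  ok <- rep(TRUE, nrow(session$activity))
  for (s in starts) {
    idx <- seq.int(s, min(s + span - 1L, nf))
    ok <- ok & (apply(session$activity[, idx, drop = FALSE], 1, max) > thresh)
  }
  ok
}

#' Subsample neurons to match activity levels across cohorts
#'
#' Per region, neurons above a preset activity threshold (default: the
#' pooled-cohort median of per-neuron mean activity over the analysis
#' window) are greedily matched one-to-one across cohorts on mean activity
#' with a caliper, guaranteeing that post-subsampling cohort means differ
#' by less than 0.1 pooled SD. Regions that cannot reach `min_matched`
#' matched pairs are dropped with a warning.
#'
#' @param sessions_a,sessions_b lists of `cortex_session` per cohort.
#' @param threshold activity threshold; `NULL` = pooled median.
#' @param window "iti" or "trial" analysis window.
#' @param caliper maximum within-pair activity difference, in pooled SDs.
#' @param min_matched minimum matched pairs per region.
#' @param seed seed for tie-breaking shuffles.
#' @return list with per-cohort per-session retained-neuron index lists
#'   (`a`, `b`), the `threshold` used and the per-region matched counts.
#' @export
subsample_matched <- function(sessions_a, sessions_b, threshold = NULL,
                              window = c("iti", "trial"), caliper = 0.05,
                              min_matched = 10, seed = 1L) {
  window <- match.arg(window)
  epoch <- if (window == "iti") "iti_window" else "trial_window"
  set.seed(seed)
  tab <- function(sessions, cohort) {
    do.call(rbind, lapply(seq_along(sessions), function(si) {
      s <- sessions[[si]]
      fr <- epoch_frames_all(s, epoch)
      data.frame(cohort = cohort, session = si,
                 neuron = seq_len(nrow(s$activity)), region = s$region,
                 activity = rowMeans(s$activity[, fr, drop = FALSE]))
    }))
  }
  all <- rbind(tab(sessions_a, "a"), tab(sessions_b, "b"))
  if (is.null(threshold)) threshold <- stats::median(all$activity)
  all <- all[all$activity > threshold, , drop = FALSE]
  sd_pool <- stats::sd(all$activity)
  if (!is.finite(sd_pool) || sd_pool == 0) sd_pool <- 1
  keep <- all[0, ]
  matched <- stats::setNames(integer(8), CORTEX_REGIONS)
  for (r in CORTEX_REGIONS) {
    xa <- all[all$cohort == "a" & all$region == r, , drop = FALSE]
    xb <- all[all$cohort == "b" & all$region == r, , drop = FALSE]
    if (nrow(xa) == 0 || nrow(xb) == 0) next
    xa <- xa[order(xa$activity), ]
    xb <- xb[order(xb$activity), ]
    used <- logical(nrow(xb))
    sel_a <- integer(0); sel_b <- integer(0)
    for (i in sample(nrow(xa))) {
      d <- abs(xb$activity - xa$activity[i])
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= caliper * sd_pool) {
        used[j] <- TRUE
        sel_a <- c(sel_a, i); sel_b <- c(sel_b, j)
      }
    }
    if (length(sel_a) < min_matched) {
      warning("region ", r, " dropped: only ", length(sel_a), " matched pairs")
      next
    }
    matched[r] <- length(sel_a)
    keep <- rbind(keep, xa[sel_a, ], xb[sel_b, ])
  }
  to_lists <- function(sessions, cohort)
    lapply(seq_along(sessions), function(si)
      sort(keep$neuron[keep$cohort == cohort & keep$session == si]))
  list(a = to_lists(sessions_a, "a"), b = to_lists(sessions_b, "b"),
       threshold = threshold, matched = matched)
}

# shared core: mean pairwise Pearson r per region pair on a frame window
.pairwise_matrix <- function(sessions, epoch, metric_name, min_neurons = 10,
                             min_pairs = 10, neurons = NULL) {
  acc <- matrix(0, 8, 8, dimnames = list(CORTEX_REGIONS, CORTEX_REGIONS))
  cnt <- acc
  npairs <- acc
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    keep <- if (is.null(neurons)) seq_len(nrow(s$activity)) else neurons[[si]]
    fr <- epoch_frames_all(s, epoch)
    X <- s$activity[keep, fr, drop = FALSE]
    reg <- s$region[keep]
    v <- apply(X, 1, stats::sd)
    if (any(v == 0)) {
      X <- X[v > 0, , drop = FALSE]
      reg <- reg[v > 0]
    }
    counts <- table(factor(reg, levels = CORTEX_REGIONS))
    ok_reg <- names(counts)[counts >= min_neurons]
    if (length(ok_reg) == 0) next
    C <- stats::cor(t(X))
    for (a in ok_reg) for (b in ok_reg) {
      if (match(b, CORTEX_REGIONS) < match(a, CORTEX_REGIONS)) next
      ia <- which(reg == a); ib <- which(reg == b)
      if (a == b) {
        sub <- C[ia, ia, drop = FALSE]
        vals <- sub[upper.tri(sub)]
      } else {
        vals <- as.vector(C[ia, ib, drop = FALSE])
      }
      if (length(vals) < min_pairs) next
      acc[a, b] <- acc[a, b] + mean(vals)
      cnt[a, b] <- cnt[a, b] + 1
      npairs[a, b] <- npairs[a, b] + length(vals)
    }
  }
  val <- acc / cnt
  val[cnt == 0] <- NA_real_
  val[lower.tri(val)] <- t(val)[lower.tri(val)]       # correlations symmetric
  npairs[lower.tri(npairs)] <- t(npairs)[lower.tri(npairs)]
  structure(list(value = val, n = npairs, metric = metric_name),
            class = "region_pair_matrix")
}

#' @export
print.region_pair_matrix <- function(x, ...) {
  cat("<region_pair_matrix>", x$metric, "\n")
  print(round(x$value, 3))
  invisible(x)
}

#' Functional connectivity from inter-trial-interval activity
#'
#' Pairwise Pearson correlation of concatenated ITI activity (−5 to −1 s
#' relative to each trial onset), averaged over neuron pairs within each
#' region pair and then across sessions (unweighted). Cells with fewer than
#' `min_pairs` neuron pairs are absent (NA); regions with fewer than
#' `min_neurons` neurons are skipped; zero-variance traces are dropped.
#'
#' @param sessions list of `cortex_session`.
#' @param min_neurons,min_pairs inclusion gates.
#' @param neurons optional per-session retained-neuron index lists (e.g.
#'   from [subsample_matched()]).
#' @return a `region_pair_matrix`.
#' @export
iti_functional_connectivity <- function(sessions, min_neurons = 10,
                                        min_pairs = 10, neurons = NULL) {
  .pairwise_matrix(sessions, "iti_window", "iti_functional_connectivity",
                   min_neurons, min_pairs, neurons)
}

#' Trial-by-trial correlation of trial-window activity
#'
#' As [iti_functional_connectivity()] but on activity from −1 to 7 s around
#' each trial onset, concatenated across trials.
#'
#' @inheritParams iti_functional_connectivity
#' @return a `region_pair_matrix`.
#' @export
trial_by_trial_correlation <- function(sessions, min_neurons = 10,
                                       min_pairs = 10, neurons = NULL) {
  .pairwise_matrix(sessions, "trial_window", "trial_by_trial_correlation",
                   min_neurons, min_pairs, neurons)
}

#' Cross-validated ridge performance
#'
#' 10-fold cross-validated normalized squared error of ridge predictions of
#' `Y` from `X`, with the regularizer chosen on a log grid by the same
#' cross-validation. Performance is `1 - cvl`, where `cvl` is the mean
#' across folds of the per-target `SSE / SS_total`, averaged over targets.
#'
#' @param X t x p source matrix.
#' @param Y t x q target matrix.
#' @param lambda_grid candidate regularizers (default 10 log-spaced points
#'   in \[1e-3, 1e3\]).
#' @param folds cross-validation folds (contiguous blocks).
#' @return scalar performance (may be slightly negative for unrelated data);
#'   attributes `lambda` and `cv_table`.
#' @export
ridge_cv_performance <- function(X, Y, lambda_grid = 10^seq(-3, 3, length.out = 10),
                                 folds = 10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  fb <- fold_blocks(nrow(X), folds)
  loss <- matrix(NA_real_, folds, length(lambda_grid))
  for (f in seq_len(folds)) {
    tr <- fb != f
    XtX <- crossprod(X[tr, , drop = FALSE])
    XtY <- crossprod(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
    for (li in seq_along(lambda_grid)) {
      B <- tryCatch(solve(XtX + lambda_grid[li] * diag(ncol(X)), XtY),
                    error = function(e) NULL)
      if (is.null(B)) next
      loss[f, li] <- normalized_sq_error(Y[!tr, , drop = FALSE],
                                         X[!tr, , drop = FALSE] %*% B)
    }
  }
  cvl <- colMeans(loss)
  li <- which.min(cvl)
  structure(1 - cvl[li], lambda = lambda_grid[li],
            cv_table = data.frame(lambda = lambda_grid, cvl = cvl))
}

#' Population-prediction performance between two populations
#'
#' Repeatedly samples `n_sample` source and `n_sample` target neurons
#' (disjoint when source and target are the same population), computes the
#' cross-validated ridge performance, and averages across repeats.
#'
#' @param source_act,target_act neurons x frames activity matrices; pass
#'   the same matrix for the intra-regional case.
#' @param repeats sampling repeats (default 20).
#' @param n_sample neurons sampled per side (default 10).
#' @param seed sampling seed.
#' @param ... passed to [ridge_cv_performance()].
#' @return mean performance across repeats.
#' @export
population_prediction <- function(source_act, target_act, repeats = 20,
                                  n_sample = 10, seed = 1L, ...) {
  same <- identical(source_act, target_act)
  ns <- nrow(source_act); nt <- nrow(target_act)
  if (same && ns < 2 * n_sample)
    stop("intra-regional prediction needs at least ", 2 * n_sample, " neurons")
  if (!same && (ns < n_sample || nt < n_sample))
    stop("inter-regional prediction needs at least ", n_sample,
         " neurons per region")
  set.seed(seed)
  perf <- vapply(seq_len(repeats), function(i) {
    if (same) {
      idx <- sample.int(ns, 2 * n_sample)
      si <- idx[seq_len(n_sample)]
      ti <- idx[n_sample + seq_len(n_sample)]
      ridge_cv_performance(t(source_act[si, , drop = FALSE]),
                           t(source_act[ti, , drop = FALSE]), ...)
    } else {
      ridge_cv_performance(t(source_act[sample.int(ns, n_sample), , drop = FALSE]),
                           t(target_act[sample.int(nt, n_sample), , drop = FALSE]),
                           ...)
    }
  }, numeric(1))
  mean(perf)
}

#' Region-pair matrix of population-prediction performance
#'
#' @param sessions list of `cortex_session`.
#' @param epoch analysis window (default `trial_window`).
#' @param repeats,n_sample,seed passed to [population_prediction()].
#' @param neurons optional per-session retained-neuron lists.
#' @param ... passed to [ridge_cv_performance()].
#' @return a `region_pair_matrix` (asymmetric: source rows, target columns).
#' @export
population_prediction_matrix <- function(sessions, epoch = "trial_window",
                                         repeats = 20, n_sample = 10,
                                         seed = 1L, neurons = NULL, ...) {
  acc <- matrix(0, 8, 8, dimnames = list(CORTEX_REGIONS, CORTEX_REGIONS))
  cnt <- acc
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    keep <- if (is.null(neurons)) seq_len(nrow(s$activity)) else neurons[[si]]
    fr <- epoch_frames_all(s, epoch)
    X <- s$activity[keep, fr, drop = FALSE]
    reg <- s$region[keep]
    for (a in CORTEX_REGIONS) for (b in CORTEX_REGIONS) {
      ia <- which(reg == a); ib <- which(reg == b)
      enough <- if (a == b) length(ia) >= 2 * n_sample
                else length(ia) >= n_sample && length(ib) >= n_sample
      if (!enough) next
      p <- population_prediction(X[ia, , drop = FALSE], X[ib, , drop = FALSE],
                                 repeats = repeats, n_sample = n_sample,
                                 seed = seed + si, ...)
      acc[a, b] <- acc[a, b] + p
      cnt[a, b] <- cnt[a, b] + 1
    }
  }
  val <- acc / cnt
  val[cnt == 0] <- NA_real_
  structure(list(value = val, n = cnt, metric = "population_prediction"),
            class = "region_pair_matrix")
}

#' Consistency between two functional-interaction metrics
#'
#' Squared Pearson correlation over the vectorized region-pair cells
#' present in both matrices.
#'
#' @param m1,m2 `region_pair_matrix` objects (or plain 8x8 matrices).
#' @return list: `r_squared`, `p_value` (two-tailed), `n` cells compared.
#' @export
metric_consistency <- function(m1, m2) {
  v1 <- if (inherits(m1, "region_pair_matrix")) m1$value else as.matrix(m1)
  v2 <- if (inherits(m2, "region_pair_matrix")) m2$value else as.matrix(m2)
  ok <- is.finite(v1) & is.finite(v2)
  if (sum(ok) < 3) stop("need at least 3 matched cells")
  ct <- stats::cor.test(v1[ok], v2[ok])
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value, n = sum(ok))
}
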