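# Pseudo-mouse population decoding: region pools, pluggable 3-d embedding
# backend, cosine kNN decoding, relative accuracy, region ablation.

#' Region pools for pseudo-mouse construction
#'
#' For every session, samples a matched number of trials per condition
#' (`n_nd` per side from non-distractor trials, `n_d` per side from each
#' distractor condition), extracts delay-period frames and stacks the
#' neurons of each region across sessions. Sessions with fewer available
#' trials are excluded. Frame columns are aligned across regions and
#' sessions by (condition, side, replicate, time) so cells from different
#' sessions form consistent pseudo-trials.
#'
#' @param sessions list of `cortex_session`.
#' @param label "stimulus" (side = stimulus side; all responded trials) or
#'   "choice" (side = lick direction; no-response trials excluded).
#' @param n_nd non-distractor trials sampled per side per session.
#' @param n_d trials per side per distractor condition per session.
#' @param seed sampling seed.
#' @return list of class `region_pools`: `activity` (list per region,
#'   cells x frames), `labels` (frame-level data.frame: condition, side,
#'   pseudo_trial, time_idx), `frames_per_trial`, `label`.
#' @export
region_pools <- function(sessions, label = c("stimulus", "choice"),
                         n_nd = 40, n_d = 4, seed = 1L) {
  label <- match.arg(label)
  set.seed(seed)
  conds <- DISTRACTOR_LEVELS
  picked <- list()
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    side <- if (label == "stimulus") s$trials$stimulus_side else s$trials$choice_side
    ok <- side %in% SIDE_LEVELS
    sel <- list()
    short <- FALSE
    for (cd in conds) for (sd in SIDE_LEVELS) {
      pool <- which(ok & s$trials$distractor == cd & side == sd)
      need <- if (cd == "none") n_nd else n_d
      if (length(pool) < need) { short <- TRUE; break }
      sel[[paste(cd, sd)]] <- sample(pool, need)
    }
    if (short) {
      warning("session ", si, " excluded: too few trials for pseudo-mouse")
      next
    }
    picked[[length(picked) + 1L]] <- list(session = s, sel = sel)
  }
  if (!length(picked)) stop("no session has enough trials per condition")
  fpt <- local({
    s <- picked[[1]]$session
    iv <- epoch_frames(s, 1, "delay")
    iv[2] - iv[1]
  })
  labels <- do.call(rbind, lapply(conds, function(cd) {
    need <- if (cd == "none") n_nd else n_d
    do.call(rbind, lapply(SIDE_LEVELS, function(sd)
      data.frame(condition = cd, side = sd,
                 replicate = rep(seq_len(need), each = fpt),
                 time_idx = rep(seq_len(fpt), need))))
  }))
  labels$pseudo_trial <- cumsum(labels$time_idx == 1)
  acts <- lapply(CORTEX_REGIONS, function(r) {
    do.call(rbind, lapply(picked, function(pk) {
      s <- pk$session
      rows <- which(s$region == r)
      cols <- unlist(lapply(conds, function(cd) {
        unlist(lapply(SIDE_LEVELS, function(sd) {
          unlist(lapply(pk$sel[[paste(cd, sd)]], function(t) {
            iv <- epoch_frames(s, t, "delay")
            seq.int(iv[1] + 1L, iv[1] + fpt)
          }))
        }))
      }))
      s$activity[rows, cols, drop = FALSE]
    }))
  })
  names(acts) <- CORTEX_REGIONS
  structure(list(activity = acts, labels = labels, frames_per_trial = fpt,
                 label = label),
            class = "region_pools")
}

#' Build a pseudo-mouse
#'
#' Samples a fixed number of cells per region (200 in stimulus and
#' unsupervised modes, 145 in choice mode, so the stacked matrix has 1600
#' or 1160 rows) and stacks them across the eight regions over the aligned
#' delay-period frames.
#'
#' @param pools a `region_pools` (built with the matching `label`).
#' @param mode "stimulus", "choice" or "unsupervised" (time labels only).
#' @param cells_per_region override the per-region cell count.
#' @param seed sampling seed.
#' @return list of class `pseudo_mouse`: `activity` (rows x frames),
#'   `region_of` rows, `labels`, `mode`.
#' @export
build_pseudo_mouse <- function(pools, mode = c("stimulus", "choice",
                                               "unsupervised"),
                               cells_per_region = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(cells_per_region))
    cells_per_region <- if (mode == "choice") 145L else 200L
  if (mode == "choice" && pools$label != "choice")
    stop("choice mode requires pools built with label = 'choice'")
  set.seed(seed)
  rows <- lapply(CORTEX_REGIONS, function(r) {
    pool <- pools$activity[[r]]
    if (nrow(pool) < cells_per_region)
      stop("region ", r, " pool has only ", nrow(pool), " cells; ",
           cells_per_region, " required")
    pool[sample.int(nrow(pool), cells_per_region), , drop = FALSE]
  })
  structure(list(activity = do.call(rbind, rows),
                 region_of = rep(CORTEX_REGIONS, each = cells_per_region),
                 labels = pools$labels, mode = mode,
                 frames_per_trial = pools$frames_per_trial),
            class = "pseudo_mouse")
}

# ---- embedding backend ------------------------------------------------------

#' Supervised linear 3-d embedding backend
#'
#' The default, fully offline embedding backend: dimension 1 is a
#' shrinkage-regularized discriminant axis (per-cell standardized class-mean
#' difference divided by `var + gamma`), dimensions 2-3 the top principal
#' components of the residual frame cloud (deterministic power iteration).
#' A contrastive backend (e.g. CEBRA with architecture "offset1-model",
#' temperature 1, 2000 iterations, output dimension 3) can be substituted by
#' any object with the same `fit`/`transform` contract.
#'
#' @param gamma shrinkage added to per-cell variances (the tunable
#'   hyperparameter of this backend).
#' @return list of class `embedding_backend` with `fit(X, side)` and
#'   `transform(X)`; `fit` returns a fitted copy, `transform` maps a
#'   cells x frames matrix to frames x 3.
#' @export
linear_backend <- function(gamma = 0.1) {
  be <- list(gamma = gamma, dim = 3L, fitted = FALSE)
  class(be) <- "embedding_backend"
  be
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat("<embedding_backend> supervised linear 3-d, gamma =", x$gamma,
      if (x$fitted) "(fitted)" else "(unfitted)", "\n")
  invisible(x)
}

#' Fit the embedding backend
#'
#' @param backend an `embedding_backend`.
#' @param X cells x frames training activity.
#' @param side per-frame side labels ("left"/"right"); ignored by an
#'   unsupervised fit (`side = NULL`), which uses pure PCA.
#' @return fitted backend.
#' @export
backend_fit <- function(backend, X, side = NULL) {
  X <- as.matrix(X)
  mu <- rowMeans(X)
  sd <- apply(X, 1, stats::sd)
  sd[sd == 0] <- 1
  Z <- (X - mu) / sd
  if (!is.null(side)) {
    d <- rowMeans(Z[, side == "right", drop = FALSE]) -
      rowMeans(Z[, side == "left", drop = FALSE])
    w1 <- d / (apply(Z, 1, stats::var) + backend$gamma)
    n1 <- sqrt(sum(w1^2))
    if (n1 < 1e-12) w1 <- c(1, rep(0, nrow(Z) - 1)) else w1 <- w1 / n1
    R <- Z - w1 %*% crossprod(w1, Z)          # project out the label axis
    W <- cbind(w1, .top_pcs(R, 2))
  } else {
    W <- .top_pcs(Z, 3)
  }
  backend$W <- W
  backend$center <- mu
  backend$scale <- sd
  backend$fitted <- TRUE
  backend
}

# deterministic top-k principal directions of the row space via
# orthogonalized power iteration on the cell covariance
.top_pcs <- function(Z, k, iters = 60) {
  C <- tcrossprod(Z) / max(1, ncol(Z) - 1)
  p <- nrow(C)
  init <- order(diag(C), decreasing = TRUE)[seq_len(k)]
  V <- diag(p)[, init, drop = FALSE]
  for (i in seq_len(iters)) V <- qr.Q(qr(C %*% V))
  V
}

#' Embed activity with a fitted backend
#'
#' @param backend fitted `embedding_backend`.
#' @param X cells x frames activity.
#' @return frames x 3 embedding.
#' @export
backend_transform <- function(backend, X) {
  if (!isTRUE(backend$fitted)) stop("backend is not fitted")
  Z <- (as.matrix(X) - backend$center) / backend$scale
  crossprod(Z, backend$W)
}

# ---- splitting / tuning -----------------------------------------------------

#' Balanced train/test split and hyperparameter tuning
#'
#' Non-distractor pseudo-trials are balanced across sides, split 80/20 into
#' training and test trials, and the backend hyperparameter grid is scored
#' by 5-fold cross-validation on the training set (loss = 1 − kNN decoding
#' accuracy for the supervised backend). The first grid point in declared
#' order wins ties; the backend is refit on the full training set.
#'
#' @param pm a `pseudo_mouse`.
#' @param backend an `embedding_backend` prototype.
#' @param grid list of hyperparameter sets (e.g.
#'   `list(list(gamma = 0.01), list(gamma = 0.1))`).
#' @param seed seed for the trial split and folds.
#' @param train_frac training fraction (default 0.8).
#' @param folds CV folds (default 5).
#' @param k kNN neighbors for the validation loss.
#' @return list: `backend` (fitted), `train_trials`, `test_trials`,
#'   `chosen` (grid index), `grid_loss`.
#' @export
split_and_tune <- function(pm, backend, grid = list(list(gamma = 0.1)),
                           seed = 1L, train_frac = 0.8, folds = 5, k = 5) {
  set.seed(seed)
  lab <- pm$labels
  nd <- lab[lab$condition == "none" & lab$time_idx == 1, ]
  per_side <- split(nd$pseudo_trial, nd$side)
  n_bal <- min(lengths(per_side))
  if (n_bal < folds) stop("fewer than ", folds, " trials per class")
  bal <- unlist(lapply(per_side, function(x) sample(x, n_bal)))
  split_side <- lapply(per_side, function(x) {
    x <- intersect(bal, x)
    tr <- sample(x, round(train_frac * length(x)))
    list(train = tr, test = setdiff(x, tr))
  })
  train_trials <- unlist(lapply(split_side, `[[`, "train"))
  test_trials <- unlist(lapply(split_side, `[[`, "test"))
  frames_of <- function(trials) which(lab$pseudo_trial %in% trials)
  fold_of <- stats::setNames(
    unlist(lapply(split_side, function(s)
      sample(rep_len(seq_len(folds), length(s$train))))),
    unlist(lapply(split_side, `[[`, "train")))
  losses <- vapply(grid, function(g) {
    be <- linear_backend(gamma = g$gamma)
    fl <- vapply(seq_len(folds), function(f) {
      tr <- train_trials[fold_of[as.character(train_trials)] != f]
      va <- train_trials[fold_of[as.character(train_trials)] == f]
      if (!length(va)) return(NA_real_)
      ftr <- frames_of(tr); fva <- frames_of(va)
      fit <- backend_fit(be, pm$activity[, ftr, drop = FALSE],
                         side = if (pm$mode == "unsupervised") NULL
                                else lab$side[ftr])
      emb_tr <- backend_transform(fit, pm$activity[, ftr, drop = FALSE])
      emb_va <- backend_transform(fit, pm$activity[, fva, drop = FALSE])
      1 - knn_decode(emb_tr, lab$side[ftr], emb_va, lab$side[fva], k = k)$overall
    }, numeric(1))
    mean(fl, na.rm = TRUE)
  }, numeric(1))
  chosen <- which.min(losses)                       # ties: first in order
  ftr <- frames_of(train_trials)
  fitted <- backend_fit(linear_backend(gamma = grid[[chosen]]$gamma),
                        pm$activity[, ftr, drop = FALSE],
                        side = if (pm$mode == "unsupervised") NULL
                               else lab$side[ftr])
  list(backend = fitted, train_trials = sort(train_trials),
       test_trials = sort(test_trials), chosen = chosen, grid_loss = losses)
}

# ---- kNN decoding -----------------------------------------------------------

#' Cosine-distance k-nearest-neighbor decoding
#'
#' Majority vote among the `k` nearest training embeddings under cosine
#' distance. Zero-norm embedding rows are rejected.
#'
#' @param train_emb frames x d training embedding.
#' @param train_lab training labels.
#' @param query_emb frames x d query embedding.
#' @param query_lab optional query labels (enables accuracy).
#' @param time_idx optional per-query time index (enables the per-frame
#'   accuracy time series).
#' @param k neighbors (odd; default 5).
#' @return list: `pred`, `overall` accuracy (NA without labels),
#'   `per_frame` (data.frame time_idx/accuracy, NULL without `time_idx`).
#' @export
knn_decode <- function(train_emb, train_lab, query_emb, query_lab = NULL,
                       time_idx = NULL, k = 5) {
  normalize <- function(E) {
    E <- as.matrix(E)
    nrm <- sqrt(rowSums(E^2))
    if (any(nrm == 0)) stop("zero-norm embedding row")
    E / nrm
  }
  A <- normalize(train_emb)
  B <- normalize(query_emb)
  k <- min(k, nrow(A))
  S <- tcrossprod(B, A)                      # cosine similarity
  pred <- apply(S, 1, function(s) {
    nb <- train_lab[order(s, decreasing = TRUE)[seq_len(k)]]
    names(sort(table(nb), decreasing = TRUE))[1]
  })
  overall <- if (!is.null(query_lab)) mean(pred == query_lab) else NA_real_
  per_frame <- NULL
  if (!is.null(time_idx) && !is.null(query_lab)) {
    acc <- tapply(pred == query_lab, time_idx, mean)
    per_frame <- data.frame(time_idx = as.integer(names(acc)),
                            accuracy = as.numeric(acc))
  }
  list(pred = pred, overall = overall, per_frame = per_frame)
}

#' Relative decoding accuracy under distraction
#'
#' Pointwise difference between distractor-trial and non-distractor
#' test-set accuracy time series, plus its mean over the 1-s window
#' following the distractor (window anchored at distractor offset,
#' onset + 0.2 s, within the delay).
#'
#' @param acc_distractor,acc_test per-frame accuracy data.frames
#'   (`time_idx`, `accuracy`) on the delay time base.
#' @param distractor_type "early", "middle" or "late".
#' @param rate frame rate (Hz).
#' @return list: `series` (data.frame time_idx/relative), `window_mean`,
#'   `window_idx`.
#' @export
relative_accuracy <- function(acc_distractor, acc_test, distractor_type,
                              rate = 9.35) {
  distractor_type <- match.arg(distractor_type, c("early", "middle", "late"))
  m <- merge(acc_distractor, acc_test, by = "time_idx",
             suffixes = c("_dist", "_test"))
  m <- m[order(m$time_idx), ]
  series <- data.frame(time_idx = m$time_idx,
                       relative = m$accuracy_dist - m$accuracy_test)
  t_d <- c(early = 1, middle = 2, late = 3)[[distractor_type]] + 0.2
  tc <- (series$time_idx - 0.5) / rate              # s after delay onset
  win <- which(tc >= t_d & tc < t_d + 1)
  list(series = series, window_mean = mean(series$relative[win]),
       window_idx = win)
}

#' Decoding with a single region intact
#'
#' Replaces the activity of every other region by its per-cell mean (over
#' all pseudo-mouse frames), embeds the result with the fitted backend and
#' decodes the requested frames with the training-set kNN reference.
#'
#' @param split output of [split_and_tune()].
#' @param pm the `pseudo_mouse`.
#' @param region region kept intact ("none" substitutes nothing, giving
#'   the baseline).
#' @param trials pseudo-trials decoded (default the test trials).
#' @param k kNN neighbors.
#' @return list as returned by [knn_decode()].
#' @export
region_contribution <- function(split, pm, region, trials = split$test_trials,
                                k = 5) {
  lab <- pm$labels
  X <- pm$activity
  if (region != "none") {
    if (!region %in% CORTEX_REGIONS) stop("unknown region: ", region)
    sub <- pm$region_of != region
    X[sub, ] <- rowMeans(X[sub, , drop = FALSE])
  }
  ftr <- which(lab$pseudo_trial %in% split$train_trials)
  fq <- which(lab$pseudo_trial %in% trials)
  emb_tr <- backend_transform(split$backend,
                              pm$activity[, ftr, drop = FALSE])
  emb_q <- backend_transform(split$backend, X[, fq, drop = FALSE])
  knn_decode(emb_tr, lab$side[ftr], emb_q, lab$side[fq],
             time_idx = lab$time_idx[fq], k = k)
}
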