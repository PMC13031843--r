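# Single-neuron selectivity and distractor-mediated modulation.

# two-tailed rank-sum label for one neuron's per-trial epoch means
.ranksum_label <- function(left_vals, right_vals, p_thresh = 0.01) {
  if (length(left_vals) == 0 || length(right_vals) == 0) return(NULL)
  p <- suppressWarnings(stats::wilcox.test(left_vals, right_vals,
                                           exact = FALSE)$p.value)
  if (is.na(p) || p >= p_thresh) return(NULL)
  list(preferred_side = if (mean(right_vals) > mean(left_vals)) "right" else "left",
       p_value = p)
}

#' Classify epoch selectivity of single neurons
#'
#' For every neuron and task epoch, the per-trial mean activity on correct
#' left vs. correct right trials is compared with a two-tailed Wilcoxon
#' rank-sum test; a neuron is labeled selective at `p < p_thresh` (default
#' 0.01) with the higher-mean side as its preference. Regions with fewer
#' than `min_neurons` recorded neurons are excluded.
#'
#' @param session a `cortex_session`.
#' @param epochs epochs to test (default stimulus, delay, early_delay,
#'   late_delay, action).
#' @param p_thresh significance threshold (default 0.01).
#' @param min_neurons minimum recorded neurons for a region to be analyzed.
#' @param distractor trial distractor conditions included (default "none").
#' @return data.frame (neuron, region, epoch, preferred_side, p_value);
#'   attribute `analyzed_regions` lists regions that passed the size gate.
#' @export
classify_epoch_selectivity <- function(session,
                                       epochs = c("stimulus", "delay",
                                                  "early_delay", "late_delay",
                                                  "action"),
                                       p_thresh = 0.01, min_neurons = 10,
                                       distractor = "none") {
  tr <- session$trials
  use <- which(tr$outcome == "correct" & tr$distractor %in% distractor)
  left <- use[tr$stimulus_side[use] == "left"]
  right <- use[tr$stimulus_side[use] == "right"]
  counts <- table(factor(session$region, levels = CORTEX_REGIONS))
  analyzed <- names(counts)[counts >= min_neurons]
  out <- list()
  if (length(left) == 0 || length(right) == 0) {
    warning("no correct trials on one side; no selectivity labels emitted")
  } else {
    for (ep in epochs) {
      ml <- .epoch_trial_means(session, ep, left)    # neurons x trials
      mr <- .epoch_trial_means(session, ep, right)
      for (i in which(session$region %in% analyzed)) {
        lab <- .ranksum_label(ml[i, ], mr[i, ], p_thresh)
        if (!is.null(lab))
          out[[length(out) + 1L]] <-
            data.frame(neuron = i, region = session$region[i], epoch = ep,
                       preferred_side = lab$preferred_side,
                       p_value = lab$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(neuron = integer(0), region = character(0),
                  epoch = character(0), preferred_side = character(0),
                  p_value = numeric(0))
  attr(res, "analyzed_regions") <- analyzed
  res
}

# neurons x trials matrix of mean epoch activity
.epoch_trial_means <- function(session, epoch, trial_idx) {
  vapply(trial_idx, function(t) {
    iv <- epoch_frames(session, t, epoch)
    rowMeans(session$activity[, seq.int(iv[1] + 1L, iv[2]), drop = FALSE])
  }, numeric(nrow(session$activity)))
}

#' Fraction of selective neurons in a region
#'
#' @param labels output of [classify_epoch_selectivity()].
#' @param session the session the labels came from.
#' @param region region name.
#' @param epoch epoch name.
#' @return fraction labeled / analyzed in \[0,1\]; `NA` if the region was
#'   excluded by the size gate.
#' @export
selectivity_fraction <- function(labels, session, region, epoch) {
  analyzed <- attr(labels, "analyzed_regions")
  if (!region %in% analyzed) return(NA_real_)
  n <- sum(session$region == region)
  k <- sum(labels$region == region & labels$epoch == epoch)
  k / n
}

#' Trial-type selectivity profile of delay-selective neurons
#'
#' For each delay-selective neuron, mean activity on left trials is
#' subtracted from mean activity on right trials over the trial window
#' (−1 to 7 s), so right-preferring neurons deflect upward and
#' left-preferring neurons downward. The population traces of the two
#' groups and their difference (the selectivity trace) are smoothed with an
#' identical 0.5-s boxcar (reflected edges).
#'
#' @param session a `cortex_session`.
#' @param delay_labels rows of [classify_epoch_selectivity()] output with
#'   `epoch == "delay"` (other epochs may be passed to reuse the machinery).
#' @param outcome outcomes included (default "correct").
#' @param distractor distractor conditions included (default "none").
#' @param smooth_s smoothing window in seconds.
#' @return list of class `selectivity_profile`: `time_axis` (s, relative to
#'   stimulus onset), `right_trace`, `left_trace`, `selectivity`,
#'   `per_neuron` (smoothed per-neuron difference traces), `normalized`
#'   (per-neuron min-max normalized concatenated right/left mean traces),
#'   `peak_order`.
#' @export
trial_type_selectivity_profile <- function(session, delay_labels,
                                           outcome = "correct",
                                           distractor = "none",
                                           smooth_s = 0.5) {
  rate <- session$frame_rate_hz
  tr <- session$trials
  use_r <- which(tr$outcome %in% outcome & tr$distractor %in% distractor &
                   tr$stimulus_side == "right")
  use_l <- which(tr$outcome %in% outcome & tr$distractor %in% distractor &
                   tr$stimulus_side == "left")
  nwin <- sec_to_frame(7, rate) - sec_to_frame(-1, rate)
  time_axis <- (seq_len(nwin) - 1 + sec_to_frame(-1, rate) + 0.5) / rate
  if (nrow(delay_labels) == 0) {
    return(structure(list(time_axis = time_axis,
                          right_trace = rep(NA_real_, nwin),
                          left_trace = rep(NA_real_, nwin),
                          selectivity = rep(NA_real_, nwin),
                          per_neuron = matrix(numeric(0), 0, nwin),
                          normalized = matrix(numeric(0), 0, 2 * nwin),
                          peak_order = integer(0)),
                     class = "selectivity_profile"))
  }
  mean_trace <- function(neuron, trials) {
    acc <- numeric(nwin)
    for (t in trials) {
      iv <- epoch_frames(session, t, "trial_window")
      acc <- acc + session$activity[neuron, seq.int(iv[1] + 1L, iv[2])]
    }
    acc / length(trials)
  }
  nn <- nrow(delay_labels)
  diff_tr <- matrix(0, nn, nwin)
  norm_tr <- matrix(0, nn, 2 * nwin)
  for (j in seq_len(nn)) {
    i <- delay_labels$neuron[j]
    mr <- mean_trace(i, use_r)
    ml <- mean_trace(i, use_l)
    diff_tr[j, ] <- smooth_boxcar(mr - ml, smooth_s, rate)
    cc <- c(mr, ml)
    rng <- range(cc)
    norm_tr[j, ] <- if (diff(rng) == 0) rep(0, 2 * nwin)
                    else (cc - rng[1]) / diff(rng)
  }
  pref_r <- delay_labels$preferred_side == "right"
  # a missing preference group deflects nowhere: zero trace
  right_trace <- if (any(pref_r)) colMeans(diff_tr[pref_r, , drop = FALSE])
                 else rep(0, nwin)
  left_trace <- if (any(!pref_r)) colMeans(diff_tr[!pref_r, , drop = FALSE])
                else rep(0, nwin)
  structure(list(time_axis = time_axis, right_trace = right_trace,
                 left_trace = left_trace,
                 selectivity = right_trace - left_trace,
                 per_neuron = diff_tr, normalized = norm_tr,
                 peak_order = order(apply(norm_tr[, seq_len(nwin), drop = FALSE],
                                          1, which.max))),
            class = "selectivity_profile")
}

#' Distractor-mediated modulation of trial-type selectivity
#'
#' Selectivity is computed (correct and incorrect trials combined) for
#' distractor trials of the requested type and for non-distractor trials;
#' both are averaged over a 1-s window following the distractor, and the
#' non-distractor value is subtracted. The window is anchored at the
#' distractor offset (onset + 0.2 s) by default; onset anchoring is
#' available.
#'
#' @param session a `cortex_session`.
#' @param labels delay-selectivity labels ([classify_epoch_selectivity()]).
#' @param distractor_type "early", "middle" or "late".
#' @param anchor "offset" (default) or "onset".
#' @param window_s analysis window length (default 1 s).
#' @return named numeric vector over regions (NA where no delay-selective
#'   neurons); attribute `window_s_rel` gives the window in seconds
#'   relative to stimulus onset.
#' @export
distractor_modulation <- function(session, labels, distractor_type,
                                  anchor = c("offset", "onset"),
                                  window_s = 1) {
  distractor_type <- match.arg(distractor_type, c("early", "middle", "late"))
  anchor <- match.arg(anchor)
  if (!any(session$trials$distractor == distractor_type))
    stop("no trials with distractor type '", distractor_type, "'")
  rate <- session$frame_rate_hz
  t_on <- 1 + c(early = 1, middle = 2, late = 3)[[distractor_type]]
  t0 <- if (anchor == "offset") t_on + 0.2 else t_on
  idx0 <- sec_to_frame(-1, rate)      # trial-window start offset
  win <- seq.int(sec_to_frame(t0, rate) - idx0 + 1L,
                 sec_to_frame(t0 + window_s, rate) - idx0)
  out <- stats::setNames(rep(NA_real_, 8), CORTEX_REGIONS)
  both <- c("correct", "incorrect")
  for (r in CORTEX_REGIONS) {
    lab_r <- labels[labels$region == r & labels$epoch == "delay", , drop = FALSE]
    if (nrow(lab_r) == 0) next
    pd <- trial_type_selectivity_profile(session, lab_r, outcome = both,
                                         distractor = distractor_type)
    pn <- trial_type_selectivity_profile(session, lab_r, outcome = both,
                                         distractor = "none")
    out[r] <- mean(pd$selectivity[win]) - mean(pn$selectivity[win])
  }
  attr(out, "window_s_rel") <- c(t0, t0 + window_s)
  out
}
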