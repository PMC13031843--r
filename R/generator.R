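#' Configuration for the synthetic cohort generator
#'
#' The generator emulates trial-structured multi-region population imaging:
#' a 1-s stimulus / 4-s delay / 4-s action trial with 6-8-s inter-trial
#' intervals, ~30% distractor trials (~10% at each of three delay time
#' points), epoch-selective neurons, latent-factor-induced intra/inter-region
#' correlations, low-rank lagged inter-regional transmission, a logistic
#' behavioral readout of the end-of-delay choice latent, and a
#' reduced-connectivity cohort preset.
#'
#' Latent layout per region (when `latent_dim_per_region >= 7`): paired
#' side-specific task latents (choice R/L ramping over the delay and held
#' through action, stimulus R/L active during the stimulus epoch, action R/L
#' active during the response epoch) followed by background AR(1) latents of
#' unit stationary variance. Neurons mix latents through nonnegative
#' loadings plus private Gaussian noise, then are z-scored. With fewer than
#' 7 latents all latents are background noise (no task structure).
#'
#' @param neurons_per_region neurons simulated in each of the 8 regions.
#' @param n_trials trials per session (default 180).
#' @param distractor_fractions named or plain numeric triple, fractions of
#'   early/middle/late distractor trials (default 0.1 each).
#' @param latent_dim_per_region total latents per region (default 9 =
#'   6 task + 3 background).
#' @param coupling 8x8 nonnegative matrix of inter-regional transmission
#'   gains (source x target, zero diagonal).
#' @param coupling_rank rank of each inter-regional transmission map.
#' @param selectivity_fractions named triple (stimulus, delay, action):
#'   fraction of neurons per region loading on each task-latent pair.
#' @param private_noise_sd SD of per-neuron private Gaussian noise.
#' @param distractor_susceptibility gain mapping the distractor pulse into
#'   the opposite-side choice latents (with a 1-s decay tail); higher values
#'   mean larger end-of-delay displacement, hence worse distractor-trial
#'   performance and larger decoding drops.
#' @param channel_overlap in \[0,1\]: how much the source-side transmission
#'   channels toward different targets share directions. High overlap =
#'   spatially degenerate routing.
#' @param iti_range_s inter-trial interval bounds in whole seconds
#'   (sampled uniformly on the integers, default {6,7,8}).
#' @param frame_rate_hz imaging rate (default 9.35).
#' @param distractor_allocation "multinomial" (sampled per trial) or
#'   "exact" (deterministic counts `round(fraction * n_trials)`).
#' @param loading_mode "random" (default) or "unit" (every neuron loads
#'   `loading_scale` on latent 1 only; used for calibration checks).
#' @param loading_scale loading used by `loading_mode = "unit"`.
#' @param zscore z-score each neuron's trace (default TRUE, matching the
#'   preprocessing of the emulated data).
#' @param no_response_rate fraction of trials without a behavioral response.
#' @param seed integer; fully determines the cohort.
#' @return list of class `cortexcomm_config`.
#' @export
generator_config <- function(neurons_per_region = 40,
                             n_trials = 180,
                             distractor_fractions = c(early = 0.1, middle = 0.1, late = 0.1),
                             latent_dim_per_region = 9,
                             coupling = default_coupling(),
                             coupling_rank = 3,
                             selectivity_fractions = c(stimulus = 0.20, delay = 0.25, action = 0.20),
                             private_noise_sd = 1.0,
                             distractor_susceptibility = 0.4,
                             channel_overlap = 0.9,
                             iti_range_s = c(6, 8),
                             frame_rate_hz = 9.35,
                             distractor_allocation = c("multinomial", "exact"),
                             loading_mode = c("random", "unit"),
                             loading_scale = 1.0,
                             zscore = TRUE,
                             no_response_rate = 0.03,
                             seed = 1L) {
  distractor_allocation <- match.arg(distractor_allocation)
  loading_mode <- match.arg(loading_mode)
  if (neurons_per_region <= 0 || n_trials <= 0)
    stop("neuron and trial counts must be positive")
  df <- as.numeric(distractor_fractions)
  if (length(df) != 3 || any(df < 0) || any(df > 1) || sum(df) >= 1)
    stop("distractor fractions must lie in [0,1] and sum to < 1")
  sf <- as.numeric(selectivity_fractions)
  if (length(sf) != 3 || any(sf < 0) || any(sf > 1) || sum(sf) > 1)
    stop("selectivity fractions must lie in [0,1] and sum to <= 1")
  coupling <- as.matrix(coupling)
  if (!all(dim(coupling) == c(8, 8)) || any(coupling < 0))
    stop("coupling must be a nonnegative 8x8 matrix")
  cfg <- list(neurons_per_region = as.integer(neurons_per_region),
              n_trials = as.integer(n_trials),
              distractor_fractions = stats::setNames(df, c("early", "middle", "late")),
              latent_dim_per_region = as.integer(latent_dim_per_region),
              coupling = coupling,
              coupling_rank = as.integer(coupling_rank),
              selectivity_fractions = stats::setNames(sf, c("stimulus", "delay", "action")),
              private_noise_sd = private_noise_sd,
              distractor_susceptibility = distractor_susceptibility,
              channel_overlap = channel_overlap,
              iti_range_s = iti_range_s,
              frame_rate_hz = frame_rate_hz,
              distractor_allocation = distractor_allocation,
              loading_mode = loading_mode,
              loading_scale = loading_scale,
              zscore = zscore,
              no_response_rate = no_response_rate,
              seed = as.integer(seed))
  class(cfg) <- "cortexcomm_config"
  cfg
}

#' Default inter-regional coupling matrix
#'
#' Uniform moderate gain between all distinct region pairs.
#'
#' @param gain off-diagonal transmission gain (default 0.25).
#' @return 8x8 matrix, zero diagonal, dimnames = regions.
#' @export
default_coupling <- function(gain = 0.25) {
  m <- matrix(gain, 8, 8, dimnames = list(CORTEX_REGIONS, CORTEX_REGIONS))
  diag(m) <- 0
  m
}

#' Cohort presets
#'
#' `control` uses the defaults of [generator_config()]. The
#' `reduced_connectivity` preset scales all inter-regional coupling gains by
#' 0.4, lowers the cross-target channel overlap from 0.9 to 0.15 and raises
#' the distractor susceptibility from 0.4 to 1.0 — the stated degradations
#' of the reduced cohort (weaker functional coupling, less degenerate
#' routing, larger distractor leakage).
#'
#' @param cohort "control" or "reduced_connectivity".
#' @param ... overrides passed to [generator_config()].
#' @return a `cortexcomm_config` with matching `cohort` attribute.
#' @export
cohort_preset <- function(cohort = c("control", "reduced_connectivity"), ...) {
  cohort <- match.arg(cohort)
  cfg <- if (cohort == "control") generator_config(...)
  else {
    dots <- list(...)
    base <- do.call(generator_config, dots)
    if (is.null(dots$coupling)) base$coupling <- base$coupling * 0.4
    if (is.null(dots$channel_overlap)) base$channel_overlap <- 0.15
    if (is.null(dots$distractor_susceptibility)) base$distractor_susceptibility <- 1.0
    base
  }
  attr(cfg, "cohort") <- cohort
  cfg
}

# YAML round trip for configs ------------------------------------------------

#' Read / write a generator configuration as YAML
#' @param path YAML file path.
#' @return for `read_generator_config`, a `cortexcomm_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$coupling)) raw$coupling <- matrix(unlist(raw$coupling), 8, 8)
  do.call(generator_config, raw)
}

#' @rdname read_generator_config
#' @param config a `cortexcomm_config`.
#' @export
write_generator_config <- function(config, path) {
  out <- unclass(config)
  out$coupling <- lapply(seq_len(ncol(out$coupling)), function(j) out$coupling[, j])
  yaml::write_yaml(out, path)
  invisible(path)
}

# internals -------------------------------------------------------------------

# side-specific task-latent amplitude per region
.region_amp <- function() {
  list(stim   = stats::setNames(c(0.4, 0.4, 0.4, 0.4, 1.2, 1.5, 0.4, 0.7), CORTEX_REGIONS),
       choice = stats::setNames(c(1.2, 0.5, 0.5, 1.0, 0.4, 0.4, 0.5, 1.0), CORTEX_REGIONS),
       action = stats::setNames(c(1.2, 1.0, 1.0, 0.8, 0.5, 0.4, 0.4, 0.6), CORTEX_REGIONS))
}

# Rank-limited transmission maps for every coupled ordered pair, built from
# sparse nonnegative channels so that transmitted activity correlates
# positively with target loadings (as empirical inter-areal correlations
# do). Source-side channels for different targets of the same source share
# a fraction `channel_overlap` of their structure (the spatial-degeneracy
# knob). Target-side mixing lands on background latents; side-specific
# choice latents additionally pass through with a fixed gain, so weaker
# coupling weakens transmitted delay-period selectivity.
.make_transmission <- function(cfg) {
  d <- cfg$latent_dim_per_region
  k <- max(1L, min(cfg$coupling_rank, d))
  has_task <- d >= 7
  bg_idx <- if (has_task) 6L + seq_len(d - 6L) else seq_len(d)
  channel <- function(pool, nsup) {
    w <- numeric(d)
    sup <- if (length(pool) == 1) pool else sample(pool, min(nsup, length(pool)))
    w[sup] <- stats::runif(length(sup), 0.5, 1)
    w / sqrt(sum(w^2))
  }
  chans <- function(pool)
    matrix(vapply(seq_len(k), function(c) channel(pool, 3), numeric(d)), d, k)
  maps <- vector("list", 64)
  dim(maps) <- c(8, 8)
  for (s in 1:8) {
    v_shared <- chans(seq_len(d))
    for (r in 1:8) {
      if (s == r || cfg$coupling[s, r] <= 0) next
      v <- sqrt(cfg$channel_overlap) * v_shared +
        sqrt(1 - cfg$channel_overlap) * chans(seq_len(d))
      v <- apply(v, 2, function(x) x / sqrt(sum(x^2)))
      u <- chans(bg_idx)
      # decaying channel strengths keep the transmitted spectrum ordered,
      # so "the first m predictive dimensions" is well defined
      w <- 0.8^(seq_len(k) - 1)
      Tm <- matrix(v, d, k) %*% (w * t(matrix(u, d, k)))
      if (has_task) {
        Tm[1, 1] <- Tm[1, 1] + 0.5       # choice R passthrough
        Tm[2, 2] <- Tm[2, 2] + 0.5       # choice L passthrough
      }
      maps[[s, r]] <- Tm
    }
  }
  maps
}

.ar1 <- function(n, phi = 0.8, sd_stat = 1) {
  innov <- stats::rnorm(n, sd = sd_stat * sqrt(1 - phi^2))
  stats::filter(innov, phi, method = "recursive")
}

#' Generate one synthetic session
#'
#' See [generator_config()] for the generative model. Exposed mainly for
#' tests; [generate_cohort()] is the normal entry point.
#'
#' @param config a `cortexcomm_config`.
#' @param transmission precomputed transmission maps (internal).
#' @param cohort_tag tag stored in the session.
#' @return a `cortex_session`.
#' @export
generate_session <- function(config, transmission = NULL, cohort_tag = "other") {
  cfg <- config
  rate <- cfg$frame_rate_hz
  nt <- cfg$n_trials
  d <- cfg$latent_dim_per_region
  has_task <- d >= 7
  n_bg <- if (has_task) d - 6L else d
  if (is.null(transmission)) transmission <- .make_transmission(cfg)

  # --- trial schedule -------------------------------------------------------
  iti <- sample(seq(cfg$iti_range_s[1], cfg$iti_range_s[2]), nt, replace = TRUE)
  onset_s <- cumsum(c(6, 9 + iti[-nt]))
  total_s <- onset_s[nt] + 9 + 6
  nf <- as.integer(ceiling(total_s * rate))
  onset_f <- sec_to_frame(onset_s, rate)

  stim_side <- sample(SIDE_LEVELS, nt, replace = TRUE)
  dists <- if (cfg$distractor_allocation == "exact") {
    k <- round(cfg$distractor_fractions * nt)
    lab <- rep(c(names(k), "none"), c(k, nt - sum(k)))
    sample(lab)
  } else {
    p <- c(cfg$distractor_fractions, none = 1 - sum(cfg$distractor_fractions))
    sample(names(p), nt, replace = TRUE, prob = p)
  }

  # --- per-region latents ---------------------------------------------------
  # task latent indices: 1 choice_R, 2 choice_L, 3 stim_R, 4 stim_L,
  #                      5 action_R, 6 action_L; then background.
  amp <- .region_amp()
  sens <- c("vS1", "S1fl")
  lat <- vector("list", 8)
  names(lat) <- CORTEX_REGIONS

  frames_of <- function(t0, t1, tr) {    # trial-relative seconds -> frame idx
    a <- sec_to_frame(t0, rate) + onset_f[tr]
    b <- sec_to_frame(t1, rate) + onset_f[tr]
    if (b <= a) integer(0) else seq.int(a + 1L, b)   # 1-based
  }

  d_amp <- 2.0                      # distractor pulse amplitude on latents
  d_time <- c(early = 1, middle = 2, late = 3)

  # choice-latent profiles (incl. distractor leakage) are shared in shape
  # across regions; amplitudes differ by region.
  base_choice <- matrix(0, nf, 2)   # columns: R, L profile at unit amplitude
  base_stim <- matrix(0, nf, 2)
  base_act <- matrix(0, nf, 2)      # filled after choices are drawn
  leak <- matrix(0, nf, 2)          # distractor leakage into choice R/L
  for (tr in seq_len(nt)) {
    sgn <- if (stim_side[tr] == "right") 1L else 2L
    fs <- frames_of(0, 1, tr)
    base_stim[fs, sgn] <- 1
    fd <- frames_of(1, 5, tr)
    if (length(fd)) base_choice[fd, sgn] <- seq(0, 1, length.out = length(fd))
    fa <- frames_of(5, 9, tr)
    base_choice[fa, sgn] <- 1
    if (dists[tr] != "none") {
      t0 <- 1 + d_time[[dists[tr]]]
      fp <- frames_of(t0, t0 + 0.2, tr)
      ft <- frames_of(t0 + 0.2, min(t0 + 3.2, 9), tr)   # decay tail
      other <- 3L - sgn
      leak[fp, other] <- leak[fp, other] + d_amp
      if (length(ft))
        leak[ft, other] <- leak[ft, other] +
          d_amp * exp(-(seq_along(ft) - 1) / (1.5 * rate))
    }
  }

  # behavioral readout: mean (choice_R - choice_L) over the last 0.5 s of the
  # delay, averaged over regions via mean choice amplitude.
  mean_amp <- mean(amp$choice)
  z_end <- vapply(seq_len(nt), function(tr) {
    fe <- frames_of(4.5, 5, tr)
    prof <- mean_amp * (base_choice[fe, 1] - base_choice[fe, 2]) +
      cfg$distractor_susceptibility * mean_amp * (leak[fe, 1] - leak[fe, 2])
    mean(prof)
  }, numeric(1))
  p_right <- stats::plogis(3 * z_end)
  choice <- ifelse(stats::runif(nt) < p_right, "right", "left")
  no_resp <- stats::runif(nt) < cfg$no_response_rate
  choice[no_resp] <- "none"
  outcome <- ifelse(no_resp, "no_response",
                    ifelse(choice == stim_side, "correct", "incorrect"))
  for (tr in seq_len(nt)) {
    if (choice[tr] == "none") next
    sgn <- if (choice[tr] == "right") 1L else 2L
    base_act[frames_of(5, 9, tr), sgn] <- 1
  }

  ar_sd_task <- 0.3
  for (r in CORTEX_REGIONS) {
    L <- matrix(0, nf, d)
    if (has_task) {
      lk <- cfg$distractor_susceptibility * leak
      L[, 1] <- amp$choice[r] * (base_choice[, 1] + lk[, 1])
      L[, 2] <- amp$choice[r] * (base_choice[, 2] + lk[, 2])
      L[, 3] <- amp$stim[r] * base_stim[, 1]
      L[, 4] <- amp$stim[r] * base_stim[, 2]
      if (r %in% sens && any(dists != "none")) {
        # bilateral distractor pulse hits both sensory stimulus latents
        for (tr in which(dists != "none")) {
          t0 <- 1 + d_time[[dists[tr]]]
          fp <- frames_of(t0, t0 + 0.2, tr)
          L[fp, 3] <- L[fp, 3] + d_amp
          L[fp, 4] <- L[fp, 4] + d_amp
        }
      }
      L[, 5] <- amp$action[r] * base_act[, 1]
      L[, 6] <- amp$action[r] * base_act[, 2]
      for (j in seq_len(6)) L[, j] <- L[, j] + .ar1(nf, sd_stat = ar_sd_task)
      for (j in seq_len(n_bg)) L[, 6 + j] <- .ar1(nf)
    } else {
      for (j in seq_len(d)) L[, j] <- .ar1(nf)
    }
    lat[[r]] <- L
  }

  # --- lagged low-rank inter-regional transmission --------------------------
  lag1 <- function(m) rbind(0, m[-nrow(m), , drop = FALSE])
  F_lat <- lat
  for (r in 1:8) {
    for (s in 1:8) {
      if (s == r || cfg$coupling[s, r] <= 0) next
      F_lat[[r]] <- F_lat[[r]] +
        cfg$coupling[s, r] * (lag1(lat[[s]]) %*% transmission[[s, r]])
    }
  }

  # --- neurons: nonnegative loadings + private noise ------------------------
  npr <- cfg$neurons_per_region
  act <- matrix(0, npr * 8, nf)
  region_of <- rep(CORTEX_REGIONS, each = npr)
  for (ri in 1:8) {
    r <- CORTEX_REGIONS[ri]
    W <- matrix(0, npr, d)
    if (cfg$loading_mode == "unit") {
      W[, 1] <- cfg$loading_scale
    } else {
      bg_idx <- if (has_task) 6 + seq_len(n_bg) else seq_len(d)
      home <- sample(bg_idx, npr, replace = TRUE)
      W[cbind(seq_len(npr), home)] <- stats::runif(npr, 0.7, 1.3)
      W[, bg_idx] <- W[, bg_idx] + matrix(stats::runif(npr * n_bg, 0, 0.15), npr)
      if (has_task) {
        ksel <- round(cfg$selectivity_fractions * npr)
        cls <- rep(c("stimulus", "delay", "action", "none"),
                   c(ksel, npr - sum(ksel)))
        cls <- sample(cls)
        side <- sample(1:2, npr, replace = TRUE)   # 1 = right-preferring
        pair0 <- c(delay = 0L, stimulus = 2L, action = 4L)
        selr <- which(cls != "none")
        if (length(selr))
          W[cbind(selr, pair0[cls[selr]] + side[selr])] <- stats::runif(length(selr), 0.8, 1.5)
      }
    }
    X <- tcrossprod(W, F_lat[[r]])            # npr x nf
    if (cfg$private_noise_sd > 0)
      X <- X + matrix(stats::rnorm(npr * nf, sd = cfg$private_noise_sd), npr)
    act[(ri - 1) * npr + seq_len(npr), ] <- X
  }
  if (cfg$zscore) {
    mu <- rowMeans(act)
    sdv <- apply(act, 1, stats::sd)
    sdv[sdv == 0] <- 1
    act <- (act - mu) / sdv
  }

  tr_tab <- trial_table(onset_f, stim_side, choice, outcome, dists)
  session(act, region_of, rate, tr_tab, cohort_tag = cohort_tag)
}

#' Generate a cohort of synthetic sessions
#'
#' Deterministic given `(config, n_sessions)`: the same config (including
#' its `seed`) yields bit-identical cohorts. Transmission maps are drawn
#' once per cohort so every session shares the same routing structure.
#'
#' @param config a `cortexcomm_config` (see [generator_config()],
#'   [cohort_preset()]).
#' @param n_sessions number of sessions.
#' @return list of `cortex_session`.
#' @export
generate_cohort <- function(config, n_sessions = 1) {
  stopifnot(inherits(config, "cortexcomm_config"), n_sessions >= 1)
  tag <- attr(config, "cohort")
  if (is.null(tag)) tag <- "other"
  withr_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code()
  }
  withr_seed(config$seed, function() {
    trans <- .make_transmission(config)
    lapply(seq_len(n_sessions), function(i) {
      set.seed((config$seed * 131L + i * 7919L) %% 2147483563L)
      generate_session(config, transmission = trans, cohort_tag = tag)
    })
  })
}
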