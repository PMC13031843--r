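# FORCE-trained recurrent network simulator: attractor dynamics of the
# delayed-response task, distractor perturbation, and connectivity ablation.

#' RNN hyperparameters
#'
#' Defaults follow the modeled cortical network: n = 1024 units (128 per
#' region), membrane time constant tau = 10 ms, Euler step dt = 1 ms,
#' chaotic gain g = 1.2, sigmoid slope beta = 1 and threshold theta = 3,
#' inverse-correlation initialization constant alpha = 0.005, learning rate
#' alpha_learn = 0.05, per-step state noise SD 0.15, 1500 training epochs.
#' All N(mu, s) draws interpret s as a standard deviation
#' (`dispersion = "sd"`); set `dispersion = "var"` for the variance reading.
#' `p_init = "literal"` initializes P = alpha I as printed; "conventional"
#' uses the classic recursive-least-squares form P = I / alpha.
#'
#' @param n units.
#' @param n_regions region blocks (units assigned contiguously).
#' @param tau,dt time constants in seconds.
#' @param g recurrent gain.
#' @param beta,theta sigmoid slope and threshold.
#' @param alpha P-initialization constant.
#' @param alpha_learn learning rate.
#' @param noise_sd per-step state-noise SD.
#' @param epochs training epochs.
#' @param p_init "literal" or "conventional" (see Details).
#' @param dispersion "sd" or "var".
#' @param seed integer seed.
#' @return list of class `rnn_params`.
#' @export
rnn_params <- function(n = 1024, n_regions = 8, tau = 0.010, dt = 0.001,
                       g = 1.2, beta = 1.0, theta = 3.0, alpha = 0.005,
                       alpha_learn = 0.05, noise_sd = 0.15, epochs = 1500,
                       p_init = c("literal", "conventional"),
                       dispersion = c("sd", "var"), seed = 1L) {
  stopifnot(tau > dt, dt > 0, n > 0)
  if (n %% n_regions != 0)
    stop("n must be divisible by the region count")
  structure(list(n = as.integer(n), n_regions = as.integer(n_regions),
                 tau = tau, dt = dt, g = g, beta = beta, theta = theta,
                 alpha = alpha, alpha_learn = alpha_learn,
                 noise_sd = noise_sd, epochs = as.integer(epochs),
                 p_init = match.arg(p_init),
                 dispersion = match.arg(dispersion), seed = as.integer(seed)),
            class = "rnn_params")
}

.disp_sd <- function(s, params) if (params$dispersion == "sd") s else sqrt(s)

#' Initialize an untrained network
#'
#' `J ~ N(0, g / sqrt(n))`, `W_stimulus ~ N(0, 1)`, `W_cue ~ N(0, 0.1)`
#' (second argument read as SD by default), `P = alpha I` (literal reading)
#' or `I / alpha` (conventional). The same seed yields a bit-identical
#' model.
#'
#' @param params an `rnn_params`.
#' @return list of class `rnn_model`: `J`, `W_stimulus`, `W_cue`, `P`,
#'   `region_of`, `params`.
#' @export
init_network <- function(params) {
  set.seed(params$seed)
  n <- params$n
  J <- matrix(stats::rnorm(n * n, sd = .disp_sd(params$g / sqrt(n), params)), n, n)
  wstim <- stats::rnorm(n, sd = .disp_sd(1, params))
  wcue <- stats::rnorm(n, sd = .disp_sd(0.1, params))
  P <- diag(if (params$p_init == "literal") params$alpha else 1 / params$alpha, n)
  structure(list(J = J, W_stimulus = wstim, W_cue = wcue, P = P,
                 region_of = rep(CORTEX_REGIONS[seq_len(params$n_regions)],
                                 each = n / params$n_regions),
                 params = params),
            class = "rnn_model")
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf("<rnn_model> %d units, g = %.2f, P init %s%s\n", x$params$n,
              x$params$g, x$params$p_init,
              if (!is.null(attr(x, "trained"))) " (trained)" else ""))
  invisible(x)
}

# training/trial span: 5.5 s, from 0.5 s before stimulus onset to delay
# offset. Within the span: stimulus [0.5, 1.5) s (triangular), go-cue pulse
# [1.4, 1.5) s, distractor [3.2, 3.7) s, ITI baseline [0, 0.5) s,
# pre-action window [4.5, 5.5) s.
TRIAL_SPAN_S <- 5.5

#' Trial inputs for the network
#'
#' The stimulus is a triangular pulse spanning −5.0 to −4.0 s relative to
#' the delay offset (peak drawn from N(1.0, 0.1) on right trials, exactly 0
#' on left trials); the go-cue pulse spans −4.1 to −4.0 s with peak 1.0;
#' the optional distractor spans −2.3 to −1.8 s with peak drawn from
#' N(2.5, 0.25) and enters through the stimulus pathway.
#'
#' @param trial_type "right" or "left".
#' @param with_distractor add the mid-delay distractor pulse.
#' @param params an `rnn_params`.
#' @param distractor_amp override the sampled distractor amplitude.
#' @return list of class `trial_inputs`: `istim`, `icue` (length-T step
#'   traces), `t` (step midpoints, s), `stim_peak`, `distractor_amp`.
#' @export
make_trial_inputs <- function(trial_type = c("right", "left"),
                              with_distractor = FALSE, params = rnn_params(),
                              distractor_amp = NULL) {
  trial_type <- match.arg(trial_type)
  tt <- seq(params$dt / 2, TRIAL_SPAN_S, by = params$dt)
  peak <- if (trial_type == "right")
    stats::rnorm(1, 1.0, .disp_sd(0.1, params)) else 0
  istim <- peak * pmax(0, 1 - abs(tt - 1.0) / 0.5)
  icue <- as.numeric(tt >= 1.4 & tt < 1.5)
  damp <- 0
  if (with_distractor) {
    damp <- if (is.null(distractor_amp))
      stats::rnorm(1, 2.5, .disp_sd(0.25, params)) else distractor_amp
    istim <- istim + damp * as.numeric(tt >= 3.2 & tt < 3.7)
  }
  structure(list(istim = istim, icue = icue, t = tt, stim_peak = peak,
                 distractor_amp = damp),
            class = "trial_inputs")
}

#' Build target currents from trial-averaged activity
#'
#' Trial-averaged activity traces (9.35 Hz, 5.5-s span, one row per neuron,
#' for each trial type) are turned into target membrane currents: neurons
#' whose activity never reaches `exclude_below` (in SD units of the
#' z-scored input) are excluded; values are clipped to
#' \[0.01, 4.99\] and normalized by 5; `n` units are sampled with
#' replacement; the inverse sigmoid `f = theta + log(r / (1 - r)) / beta`
#' is applied; and the result is up-sampled tenfold (9.35 to 93.5 Hz) by
#' linear interpolation and smoothed with a 400-ms boxcar.
#'
#' @param act_right,act_left neurons x frames trial-averaged activity.
#' @param params an `rnn_params`.
#' @param n units to sample (default `params$n`); sampling uses the current
#'   RNG state.
#' @param in_rate input frame rate (default 9.35).
#' @param exclude_below exclusion threshold (default 1).
#' @return list of class `target_set`: `f_right`, `f_left` (n x frames at
#'   `rate` = 10 * in_rate), `provenance` (source row per unit).
#' @export
build_target_functions <- function(act_right, act_left, params = rnn_params(),
                                   n = params$n, in_rate = 9.35,
                                   exclude_below = 1) {
  act_right <- as.matrix(act_right); act_left <- as.matrix(act_left)
  stopifnot(all(dim(act_right) == dim(act_left)))
  keep <- which(pmax(apply(act_right, 1, max), apply(act_left, 1, max)) >=
                  exclude_below)
  if (length(keep) == 0)
    stop("all neurons fall below the activity threshold; no targets")
  idx <- keep[sample.int(length(keep), n, replace = TRUE)]
  to_f <- function(act) {
    r <- pmin(pmax(act[idx, , drop = FALSE], 0.01), 4.99) / 5
    f <- params$theta + log(r / (1 - r)) / params$beta
    up <- t(apply(f, 1, function(row) {
      m <- length(row)
      stats::approx(seq_len(m), row, xout = seq(1, m, length.out = 10 * m),
                    rule = 2)$y
    }))
    smooth_boxcar(up, window_s = 0.4, rate = 10 * in_rate)
  }
  structure(list(f_right = to_f(act_right), f_left = to_f(act_left),
                 rate = 10 * in_rate, provenance = idx),
            class = "target_set")
}

#' Directly wrap precomputed target currents
#'
#' For synthetic fixtures where target currents are designed rather than
#' derived from recordings.
#'
#' @param f_right,f_left n x frames current matrices.
#' @param rate sample rate of the traces in Hz.
#' @return a `target_set`.
#' @export
target_set <- function(f_right, f_left, rate = 93.5) {
  stopifnot(all(dim(f_right) == dim(f_left)), all(is.finite(f_right)),
            all(is.finite(f_left)))
  structure(list(f_right = as.matrix(f_right), f_left = as.matrix(f_left),
                 rate = rate, provenance = seq_len(nrow(f_right))),
            class = "target_set")
}

# linear interpolation of a target matrix onto the integration grid
.target_grid <- function(f, rate, dt) {
  tt <- seq(dt / 2, TRIAL_SPAN_S, by = dt)
  src <- (seq_len(ncol(f)) - 0.5) / rate
  t(apply(f, 1, function(row) stats::approx(src, row, xout = tt, rule = 2)$y))
}

#' Simulate the network for one trial
#'
#' Euler integration of the rate equation at dt; activity is the sigmoid of
#' the membrane current, so all values lie strictly in (0, 1).
#'
#' @param model an `rnn_model`.
#' @param inputs a `trial_inputs`.
#' @param noise_on include the per-step state noise.
#' @param x0 initial membrane current (default: attribute `x0` stored by
#'   [force_train()], else zeros).
#' @return n x T activity matrix.
#' @export
simulate_rnn <- function(model, inputs, noise_on = TRUE, x0 = NULL) {
  p <- model$params
  if (is.null(x0)) {
    x0 <- attr(model, "x0")
    if (is.null(x0)) x0 <- rep(0, p$n)
  }
  cpp_rnn_simulate(model$J, model$W_stimulus, model$W_cue, inputs$istim,
                   inputs$icue, p$dt, p$tau, p$beta, p$theta,
                   if (noise_on) p$noise_sd else 0, x0)
}

#' FORCE-train a network on target currents
#'
#' Alternates right/left trial types across epochs; each epoch draws a
#' fresh stimulus amplitude and state noise, integrates the network with
#' Euler steps and applies the per-timestep recursive-least-squares update
#' of `J` and `P` (error `e = z - f`). The per-epoch MSE is averaged across
#' trial time and units. The episode initial current is the target current
#' at span start (stored on the model as attribute `x0` for later
#' simulation).
#'
#' @param model an `rnn_model` (see [init_network()]).
#' @param targets a `target_set`.
#' @param epochs training epochs (default `model$params$epochs`).
#' @return the trained `rnn_model`; attribute `mse` holds the per-epoch MSE
#'   and attribute `x0` the episode initial current.
#' @export
force_train <- function(model, targets, epochs = model$params$epochs) {
  p <- model$params
  stopifnot(nrow(targets$f_right) == p$n)
  fr <- .target_grid(targets$f_right, targets$rate, p$dt)
  fl <- .target_grid(targets$f_left, targets$rate, p$dt)
  x0 <- (fr[, 1] + fl[, 1]) / 2
  J <- model$J; P <- model$P
  mse <- numeric(epochs)
  for (e in seq_len(epochs)) {
    right <- e %% 2 == 1
    inp <- make_trial_inputs(if (right) "right" else "left", FALSE, p)
    mse[e] <- cpp_force_episode(J, P, model$W_stimulus, model$W_cue,
                                inp$istim, inp$icue, if (right) fr else fl,
                                p$alpha_learn, p$dt, p$tau, p$beta, p$theta,
                                p$noise_sd, x0)
  }
  model$J <- J
  model$P <- P
  attr(model, "mse") <- mse
  attr(model, "x0") <- x0
  attr(model, "trained") <- TRUE
  model
}

#' Choice-axis projection of population activity
#'
#' The choice axis is the l2-normalized difference of trial-averaged
#' activity between right and left trials in the pre-action window (by
#' default the last 1 s of the delay). Trial projections are
#' baseline-subtracted (trial-averaged projection during a 0.5-s ITI
#' window, per condition) and normalized by the maximum right-trial choice
#' activity.
#'
#' @param acts_right,acts_left lists of n x T activity matrices (trials).
#' @param dt integration step (s).
#' @param pre_action_window projection window, seconds within the span
#'   (default `c(4.5, 5.5)`; 0.5-s and 1.5-s variants are supported by
#'   passing e.g. `c(5.0, 5.5)`).
#' @param iti_window baseline window (default `c(0, 0.5)`).
#' @return list of class `choice_projection`: `axis` (unit n-vector),
#'   `ref_right`, `ref_left` (normalized trial-averaged trajectories),
#'   `baseline` (per condition), `norm_const`, `degenerate`.
#' @export
choice_axis_projection <- function(acts_right, acts_left, dt,
                                   pre_action_window = c(4.5, 5.5),
                                   iti_window = c(0, 0.5)) {
  stopifnot(length(acts_right) >= 1, length(acts_left) >= 1)
  Tn <- ncol(acts_right[[1]])
  tt <- seq(dt / 2, by = dt, length.out = Tn)
  pre <- tt >= pre_action_window[1] & tt < pre_action_window[2]
  iti <- tt >= iti_window[1] & tt < iti_window[2]
  avg <- function(acts) Reduce(`+`, acts) / length(acts)
  mr <- avg(acts_right); ml <- avg(acts_left)
  delta <- rowMeans(mr[, pre, drop = FALSE]) - rowMeans(ml[, pre, drop = FALSE])
  nrm <- sqrt(sum(delta^2))
  degenerate <- nrm < 1e-12
  axis <- if (degenerate) delta else delta / nrm
  pr <- as.numeric(crossprod(mr, axis))
  pl <- as.numeric(crossprod(ml, axis))
  base <- c(right = mean(pr[iti]), left = mean(pl[iti]))
  norm_const <- max(pr - base["right"])
  if (!is.finite(norm_const) || norm_const <= 0) norm_const <- 1
  structure(list(axis = axis,
                 ref_right = (pr - base["right"]) / norm_const,
                 ref_left = (pl - base["left"]) / norm_const,
                 baseline = base, norm_const = norm_const, t = tt,
                 iti_window = iti_window, degenerate = degenerate),
            class = "choice_projection")
}

#' Project one trial onto the choice axis
#'
#' @param projection a `choice_projection`.
#' @param act n x T activity matrix of the trial.
#' @param condition baseline condition applied ("left" for left and
#'   left-with-distractor trials).
#' @return normalized projected trajectory (length T).
#' @export
project_trial <- function(projection, act, condition = c("left", "right")) {
  condition <- match.arg(condition)
  p <- as.numeric(crossprod(act, projection$axis))
  (p - projection$baseline[condition]) / projection$norm_const
}

#' Decision-switch detection
#'
#' A (left, distractor) trial counts as switched if its choice-axis value
#' at the end of the delay — the mean of the final `readout_s` seconds — is
#' strictly above the midpoint between the non-distractor right and left
#' reference trajectories at that time.
#'
#' @param projection a `choice_projection` (provides the references).
#' @param traj projected trial trajectory ([project_trial()]).
#' @param readout_s readout window at the span end (default 0.010 = 10 ms).
#' @return logical.
#' @export
detect_switch <- function(projection, traj, readout_s = 0.010) {
  Tn <- length(traj)
  k <- max(1L, round(readout_s / diff(projection$t[1:2])))
  idx <- seq.int(Tn - k + 1L, Tn)
  endv <- mean(traj[idx])
  mid <- (mean(projection$ref_right[idx]) + mean(projection$ref_left[idx])) / 2
  endv > mid
}

#' Recurrent synaptic strength summaries
#'
#' Mean absolute weight overall and split into excitatory (positive) and
#' inhibitory (negative) connections.
#'
#' @param J recurrent weight matrix.
#' @return list `overall`, `excitatory`, `inhibitory` (NA when a class is
#'   empty).
#' @export
synaptic_strength <- function(J) {
  pos <- J[J > 0]; neg <- J[J < 0]
  list(overall = mean(abs(J)),
       excitatory = if (length(pos)) mean(pos) else NA_real_,
       inhibitory = if (length(neg)) mean(abs(neg)) else NA_real_)
}

#' Reduce recurrent weights
#'
#' "random" mode scales a random subset of connections by `1 - level`;
#' "region" mode scales all outgoing (including within-region) connections
#' of one region block.
#'
#' @param model an `rnn_model`.
#' @param mode "random" or "region".
#' @param level ablation level in \[0,1\] (0.1 or 0.2 typical; 0 = none).
#' @param subset_frac fraction of connections affected in random mode.
#' @param region region name for region mode.
#' @return the modified `rnn_model`.
#' @export
ablate_weights <- function(model, mode = c("random", "region"), level,
                           subset_frac = 0.5, region = NULL) {
  mode <- match.arg(mode)
  stopifnot(level >= 0, level <= 1)
  J <- model$J
  if (mode == "random") {
    k <- round(subset_frac * length(J))
    idx <- sample.int(length(J), k)
    J[idx] <- J[idx] * (1 - level)
  } else {
    if (is.null(region) || is.null(model$region_of))
      stop("region mode requires region tags and a region name")
    cols <- which(model$region_of == region)
    if (!length(cols)) stop("unknown region: ", region)
    J[, cols] <- J[, cols] * (1 - level)
  }
  model$J <- J
  model
}

#' Switching proportions under weight ablation
#'
#' For each repeat, a fresh ablation of the trained network is tested with
#' `n_trials` left-with-distractor trials; the proportion whose decision
#' switches to the right attractor is reported. References and choice axis
#' are recomputed per ablated network from non-distractor trials. Level 0
#' reproduces the unablated baseline.
#'
#' @param model trained `rnn_model`.
#' @param mode "random" or "region".
#' @param level ablation level (0, 0.1, 0.2).
#' @param repeats ablation repeats (default 20).
#' @param n_trials perturbation trials per repeat (default 100).
#' @param n_ref non-distractor trials per side for the references.
#' @param seed seed.
#' @param region region name for region mode.
#' @param subset_frac fraction of connections affected in random mode.
#' @param distractor_amp fixed distractor amplitude (default: sampled from
#'   N(2.5, 0.25) per trial).
#' @return data.frame (repeat, level, proportion).
#' @export
ablate_and_test <- function(model, mode = c("random", "region"), level,
                            repeats = 20, n_trials = 100, n_ref = 10,
                            seed = 1L, region = NULL, subset_frac = 0.5,
                            distractor_amp = NULL) {
  mode <- match.arg(mode)
  set.seed(seed)
  p <- model$params
  out <- data.frame(repeat_ = seq_len(repeats), level = level,
                    proportion = NA_real_)
  for (rep_i in seq_len(repeats)) {
    mab <- ablate_weights(model, mode, level, subset_frac, region)
    attr(mab, "x0") <- attr(model, "x0")
    sim_batch <- function(type, dist, n)
      lapply(seq_len(n), function(i)
        simulate_rnn(mab, make_trial_inputs(type, dist, p)))
    proj <- choice_axis_projection(sim_batch("right", FALSE, n_ref),
                                   sim_batch("left", FALSE, n_ref), p$dt)
    sw <- vapply(seq_len(n_trials), function(i) {
      inp <- make_trial_inputs("left", TRUE, p, distractor_amp = distractor_amp)
      detect_switch(proj, project_trial(proj, simulate_rnn(mab, inp), "left"))
    }, logical(1))
    out$proportion[rep_i] <- mean(sw)
  }
  out
}

#' Save / load an RNN checkpoint (HDF5)
#'
#' @param model an `rnn_model`.
#' @param path `.h5` file path.
#' @export
write_rnn_model <- function(model, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(model$J, path, "J")
  rhdf5::h5write(model$W_stimulus, path, "W_stimulus")
  rhdf5::h5write(model$W_cue, path, "W_cue")
  rhdf5::h5write(model$P, path, "P")
  rhdf5::h5write(model$region_of, path, "region_of")
  pr <- model$params
  pr$p_init <- match(pr$p_init, c("literal", "conventional"))
  pr$dispersion <- match(pr$dispersion, c("sd", "var"))
  pv <- unlist(pr)
  rhdf5::h5write(unname(pv), path, "params")
  rhdf5::h5write(names(pv), path, "param_names")
  x0 <- attr(model, "x0")
  if (!is.null(x0)) rhdf5::h5write(x0, path, "x0")
  invisible(path)
}

#' @rdname write_rnn_model
#' @export
read_rnn_model <- function(path) {
  pv <- as.numeric(rhdf5::h5read(path, "params"))
  names(pv) <- as.character(rhdf5::h5read(path, "param_names"))
  params <- rnn_params(n = pv[["n"]], n_regions = pv[["n_regions"]],
                       tau = pv[["tau"]], dt = pv[["dt"]], g = pv[["g"]],
                       beta = pv[["beta"]], theta = pv[["theta"]],
                       alpha = pv[["alpha"]], alpha_learn = pv[["alpha_learn"]],
                       noise_sd = pv[["noise_sd"]], epochs = pv[["epochs"]],
                       p_init = c("literal", "conventional")[pv[["p_init"]]],
                       dispersion = c("sd", "var")[pv[["dispersion"]]],
                       seed = pv[["seed"]])
  m <- structure(list(J = rhdf5::h5read(path, "J"),
                      W_stimulus = as.numeric(rhdf5::h5read(path, "W_stimulus")),
                      W_cue = as.numeric(rhdf5::h5read(path, "W_cue")),
                      P = rhdf5::h5read(path, "P"),
                      region_of = as.character(rhdf5::h5read(path, "region_of")),
                      params = params),
                 class = "rnn_model")
  if ("x0" %in% rhdf5::h5ls(path)$name)
    attr(m, "x0") <- as.numeric(rhdf5::h5read(path, "x0"))
  m
}
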