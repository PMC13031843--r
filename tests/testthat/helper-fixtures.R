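# Shared fixtures, built in code at test time.

# hand-built session: each neuron = loading * latent(region) + noise, with a
# fully controlled trial table. Used as the oracle substrate for epoch,
# selectivity and connectivity tests.
fixture_session <- function(n_trials = 12, rate = 10, neurons_per_region = 2,
                            noise_sd = 0, seed = 1, cohort = "other") {
  set.seed(seed)
  onset <- as.integer(seq(60, by = 160, length.out = n_trials))
  nf <- max(onset) + 160L
  lat <- replicate(8, as.numeric(stats::filter(rnorm(nf, sd = sqrt(1 - 0.8^2)),
                                               0.8, method = "recursive")))
  act <- do.call(rbind, lapply(1:8, function(r) {
    t(replicate(neurons_per_region,
                lat[, r] + rnorm(nf, sd = noise_sd)))
  }))
  side <- rep(c("left", "right"), length.out = n_trials)
  tr <- trial_table(onset, side, side, rep("correct", n_trials),
                    rep("none", n_trials))
  session(act, rep(CORTEX_REGIONS, each = neurons_per_region), rate, tr,
          cohort_tag = cohort, check = FALSE)
}

# session with planted epoch-selective neurons: `effect` z-units of
# side-dependent mean during the chosen epoch for the first
# `n_selective` neurons of each region.
selective_session <- function(n_trials = 40, rate = 10, neurons_per_region = 12,
                              n_selective = 4, effect = 2, epoch = "delay",
                              seed = 2) {
  set.seed(seed)
  onset <- as.integer(seq(60, by = 160, length.out = n_trials))
  nf <- max(onset) + 160L
  n <- neurons_per_region * 8
  act <- matrix(rnorm(n * nf), n, nf)
  side <- sample(rep(c("left", "right"), length.out = n_trials))
  lim <- switch(epoch, stimulus = c(0, 1), delay = c(1, 5), action = c(5, 9))
  sel <- as.vector(outer(seq_len(n_selective), (0:7) * neurons_per_region, "+"))
  half <- seq_len(ceiling(length(sel) / 2))
  sel_r <- sel[half]                     # right-preferring
  sel_l <- sel[-half]                    # left-preferring
  for (i in seq_len(n_trials)) {
    fr <- seq.int(floor(lim[1] * rate) + onset[i] + 1L,
                  floor(lim[2] * rate) + onset[i])
    boost <- if (side[i] == "right") sel_r else sel_l
    act[boost, fr] <- act[boost, fr] + effect
  }
  tr <- trial_table(onset, side, side, rep("correct", n_trials),
                    rep("none", n_trials))
  session(act, rep(CORTEX_REGIONS, each = neurons_per_region), rate, tr,
          check = FALSE)
}

# trained 64-unit FORCE fixture, cached across tests (training ~10 s)
.fixture_cache <- new.env(parent = emptyenv())

fixture_rnn_params <- function(epochs = 300, seed = 5)
  rnn_params(n = 64, epochs = epochs, seed = seed)

trained_fixture <- function(epochs = 300, seed = 5) {
  key <- sprintf("rnn_%d_%d", epochs, seed)
  if (is.null(.fixture_cache[[key]])) {
    params <- fixture_rnn_params(epochs, seed)
    tr <- reference_target_traces(64)
    set.seed(seed)
    targets <- build_target_functions(tr$right, tr$left, params, n = 64)
    model <- force_train(init_network(params), targets)
    .fixture_cache[[key]] <- list(model = model, targets = targets,
                                  params = params)
  }
  .fixture_cache[[key]]
}

# choice projection references for a (possibly ablated) model
fixture_projection <- function(model, params, n_ref = 10, seed = 30) {
  set.seed(seed)
  choice_axis_projection(
    lapply(seq_len(n_ref), function(i)
      simulate_rnn(model, make_trial_inputs("right", FALSE, params))),
    lapply(seq_len(n_ref), function(i)
      simulate_rnn(model, make_trial_inputs("left", FALSE, params))),
    params$dt)
}

# pseudo-mouse built directly from synthetic region pools (bypasses session
# machinery): one region optionally carries the side signal.
fixture_pseudo_mouse <- function(cells_per_region = 20, n_trials_per_side = 20,
                                 frames_per_trial = 10, signal_region = "ALM",
                                 signal = 1.5, seed = 3) {
  set.seed(seed)
  n_tr <- 2 * n_trials_per_side
  m <- n_tr * frames_per_trial
  side <- rep(rep(c("left", "right"), each = n_trials_per_side),
              each = frames_per_trial)
  labels <- data.frame(condition = "none", side = side,
                       replicate = rep(rep(seq_len(n_trials_per_side), 2),
                                       each = frames_per_trial),
                       time_idx = rep(seq_len(frames_per_trial), n_tr))
  labels$pseudo_trial <- cumsum(labels$time_idx == 1)
  acts <- lapply(CORTEX_REGIONS, function(r) {
    X <- matrix(rnorm(cells_per_region * m), cells_per_region, m)
    if (r == signal_region)
      X <- X + signal * matrix(rep(as.numeric(side == "right"),
                                   each = cells_per_region), cells_per_region)
    X
  })
  names(acts) <- CORTEX_REGIONS
  pools <- structure(list(activity = acts, labels = labels,
                          frames_per_trial = frames_per_trial,
                          label = "stimulus"),
                     class = "region_pools")
  build_pseudo_mouse(pools, "stimulus", cells_per_region = cells_per_region,
                     seed = seed)
}
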