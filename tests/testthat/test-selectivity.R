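# Epoch selectivity, trial-type selectivity profiles, distractor modulation.

test_that("planted selective neurons are labeled with the correct preference", {
  s <- selective_session(n_selective = 4, effect = 2)
  lab <- classify_epoch_selectivity(s, epochs = "delay")
  planted <- as.vector(outer(1:4, (0:7) * 12, "+"))
  planted_r <- planted[seq_len(16)]
  planted_l <- planted[17:32]
  expect_true(all(planted %in% lab$neuron))
  expect_true(all(lab$preferred_side[lab$neuron %in% planted_r] == "right"))
  expect_true(all(lab$preferred_side[lab$neuron %in% planted_l] == "left"))
  expect_equal(selectivity_fraction(lab, s, "ALM", "delay"), 4 / 12,
               tolerance = 0.35)       # a few false positives allowed
})

test_that("regions under the 10-neuron gate emit no labels", {
  s <- selective_session(neurons_per_region = 9, n_selective = 3, effect = 3)
  lab <- classify_epoch_selectivity(s, epochs = "delay")
  expect_equal(nrow(lab), 0)
  expect_true(is.na(selectivity_fraction(lab, s, "ALM", "delay")))
})

test_that("selectivity fraction arithmetic is exact", {
  s <- selective_session()
  lab <- classify_epoch_selectivity(s, epochs = "delay")
  r <- "M1a"
  k <- sum(lab$region == r & lab$epoch == "delay")
  expect_equal(selectivity_fraction(lab, s, r, "delay"), k / 12)
  expect_equal(selectivity_fraction(lab, s, r, "stimulus"), 0)
})

test_that("boxcar smoothing preserves the trace mean exactly", {
  set.seed(8)
  x <- rnorm(75)
  for (rate in c(9.35, 10, 20))
    expect_equal(mean(smooth_boxcar(x, 0.5, rate)), mean(x), tolerance = 1e-10)
})

test_that("selectivity profile matches hand computation on a mirror fixture", {
  # 3 neurons, 20 frames/trial-window, deterministic mirror responses
  rate <- 2.5                               # trial window = 20 frames
  onset <- c(50L, 200L, 350L, 500L)
  nf <- 700L
  side <- c("right", "left", "right", "left")
  act <- matrix(0, 3, nf)
  bump <- function(on) seq.int(floor(1 * rate) + on + 1L, floor(5 * rate) + on)
  for (i in 1:4) {
    sgn <- if (side[i] == "right") 1 else -1
    act[1, bump(onset[i])] <- sgn * 1      # right-preferring
    act[2, bump(onset[i])] <- -sgn * 1     # left-preferring (mirror)
    # neuron 3 identical across trial types
    act[3, bump(onset[i])] <- 0.7
  }
  s <- session(act, c("ALM", "ALM", "ALM"), rate,
               trial_table(onset, side, side, rep("correct", 4), rep("none", 4)),
               check = FALSE)
  lab_all <- data.frame(neuron = 1:3, region = "ALM", epoch = "delay",
                        preferred_side = c("right", "left", "right"),
                        p_value = 0.001)
  pr_all <- trial_type_selectivity_profile(s, lab_all, smooth_s = 0)
  # neuron 3 (identical across trial types) contributes 0 everywhere
  expect_equal(max(abs(pr_all$per_neuron[3, ])), 0)
  # mirror-symmetric pair: selectivity = 2 x single-group deflection
  pr <- trial_type_selectivity_profile(s, lab_all[1:2, ], smooth_s = 0)
  expect_equal(pr$selectivity, 2 * pr$right_trace)
  expect_equal(pr$left_trace, -pr$right_trace)
  # delay frames carry difference 2 (right +1 vs left -1) for neuron 1
  iv <- epoch_frames(s, 1, "delay") - epoch_frames(s, 1, "trial_window")[1]
  expect_equal(unname(pr$per_neuron[1, (iv[1] + 1):iv[2]]),
               rep(2, iv[2] - iv[1]))
  # per-neuron normalization maps concatenated extremes to exactly {0, 1}
  expect_equal(unname(apply(pr_all$normalized, 1, min)), c(0, 0, 0))
  expect_equal(unname(apply(pr_all$normalized, 1, max)), c(1, 1, 1))
})

test_that("selectivity trace is antisymmetric under swapping side labels", {
  s <- selective_session(n_trials = 30)
  lab <- classify_epoch_selectivity(s, epochs = "delay")
  pr <- trial_type_selectivity_profile(s, lab)
  s2 <- s
  s2$trials$stimulus_side <- ifelse(s$trials$stimulus_side == "left",
                                    "right", "left")
  pr2 <- trial_type_selectivity_profile(s2, lab)
  expect_equal(pr2$selectivity, -pr$selectivity, tolerance = 1e-10)
  expect_equal(pr2$per_neuron, -pr$per_neuron, tolerance = 1e-10)
})

test_that("distractor modulation is zero when distractor trials are identical", {
  # distractor label present but no activity consequence
  s <- selective_session(n_trials = 80)
  s$trials$distractor[seq(1, 80, by = 4)] <- "early"
  lab <- classify_epoch_selectivity(s, epochs = "delay",
                                    distractor = c("none", "early"))
  mod <- distractor_modulation(s, lab, "early")
  expect_true(all(is.na(mod) | abs(mod) < 1))      # only sampling noise
  expect_lt(abs(mean(mod, na.rm = TRUE)), 0.3)
  expect_equal(unname(attr(mod, "window_s_rel")), c(2.2, 3.2))
  expect_error(distractor_modulation(s, lab, "late"), "no trials")
})

test_that("halving windowed selectivity gives minus half the baseline window mean", {
  rate <- 10
  onset <- as.integer(seq(100, by = 200, length.out = 16))
  side <- rep(c("right", "left"), 8)
  dist <- rep(c("none", "none", "early", "early"), 4)
  nf <- max(onset) + 200L
  act <- matrix(0, 2, nf)
  for (i in seq_along(onset)) {
    fr <- seq.int(floor(1 * rate) + onset[i] + 1L, floor(5 * rate) + onset[i])
    amp <- if (dist[i] == "early") 0.5 else 1       # halved under distractor
    act[1, fr] <- amp * (if (side[i] == "right") 1 else -1)
    act[2, fr] <- amp * (if (side[i] == "right") -1 else 1)
  }
  s <- session(act, c("ALM", "ALM"), rate,
               trial_table(onset, side, side, rep("correct", 16), dist),
               check = FALSE)
  lab <- data.frame(neuron = 1:2, region = "ALM", epoch = "delay",
                    preferred_side = c("right", "left"), p_value = 0.001)
  mod <- distractor_modulation(s, lab, "early")
  # baseline selectivity in the window is 4 (2 neurons x diff 2); smoothing
  # keeps the interior constant, so modulation = -0.5 * 4 = -2
  expect_equal(unname(mod["ALM"]), -2, tolerance = 1e-8)
})

test_that("epoch selectivity power is high for strong planted effects", {
  # d = 1.5, 40 trials/side at the single-neuron level
  hits <- vapply(1:200, function(i) {
    set.seed(i)
    !is.null(cortexcomm:::.ranksum_label(rnorm(40), rnorm(40, 1.5)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
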