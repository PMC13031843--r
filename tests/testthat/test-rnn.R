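# FORCE RNN: initialization, inputs, integration, target construction,
# choice-axis machinery, ablation plumbing. (Training convergence and
# attractor experiments live in test-acceptance.R.)

test_that("network initialization follows the stated distributions", {
  params <- rnn_params(n = 1024, seed = 2)
  m <- init_network(params)
  expect_equal(stats::sd(m$J), 1.2 / sqrt(1024), tolerance = 0.02)
  expect_equal(mean(m$J), 0, tolerance = 0.01)
  expect_equal(unique(diag(m$P)), 0.005)
  expect_equal(max(abs(m$P[upper.tri(m$P)])), 0)
  expect_identical(init_network(params)$J, m$J)   # same seed, bit-identical
  expect_identical(table(m$region_of)[["ALM"]], 128L)
  expect_error(rnn_params(n = 100, n_regions = 8), "divisible")
})

test_that("trial inputs follow the stated pulse design", {
  params <- fixture_rnn_params()
  set.seed(3)
  left <- make_trial_inputs("left", FALSE, params)
  expect_true(all(left$istim == 0))
  expect_equal(max(left$icue), 1)
  expect_equal(range(left$t[left$icue > 0]), c(1.4005, 1.4995))
  peaks <- vapply(1:1000, function(i)
    make_trial_inputs("right", FALSE, params)$stim_peak, numeric(1))
  expect_equal(mean(peaks), 1.0, tolerance = 0.01)
  expect_equal(stats::sd(peaks), 0.1, tolerance = 0.015)
  d <- make_trial_inputs("left", TRUE, params)
  expect_equal(range(d$t[d$istim > 0]), c(3.2005, 3.6995))
  damps <- vapply(1:500, function(i)
    make_trial_inputs("left", TRUE, params)$distractor_amp, numeric(1))
  expect_equal(mean(damps), 2.5, tolerance = 0.05)
})

test_that("with no recurrence or input the state decays exponentially", {
  params <- fixture_rnn_params()
  model <- init_network(params)
  model$J[] <- 0
  model$W_stimulus[] <- 0
  model$W_cue[] <- 0
  x0 <- rep(5, 64)
  inp <- make_trial_inputs("left", FALSE, params)
  inp$icue[] <- 0
  R <- simulate_rnn(model, inp, noise_on = FALSE, x0 = x0)
  x <- params$theta + log(R / (1 - R)) / params$beta     # invert the sigmoid
  k <- c(10, 100, 1000)
  euler <- 5 * (1 - params$dt / params$tau)^k
  expect_equal(unname(x[1, k]), euler, tolerance = 1e-8)
  expect_equal(unname(x[1, k]), 5 * exp(-k * params$dt / params$tau),
               tolerance = 0.06)
  expect_true(all(R > 0 & R < 1))
  # noiseless path is deterministic
  expect_identical(R, simulate_rnn(model, inp, noise_on = FALSE, x0 = x0))
})

test_that("target construction inverts the sigmoid exactly for interior values", {
  params <- fixture_rnn_params()
  r_grid <- seq(0.01, 0.99, length.out = 30)
  act <- matrix(rep(r_grid * 5, 20), 30, 20)              # constant traces
  set.seed(4)
  ts <- build_target_functions(act, act, params, n = 30, exclude_below = 0)
  r_back <- 1 / (1 + exp(-params$beta * (ts$f_right - params$theta)))
  expect_equal(unname(rowMeans(r_back)), r_grid[ts$provenance],
               tolerance = 1e-9)
  # r = 0.5 maps to f = theta
  ts2 <- build_target_functions(matrix(2.5, 1, 10), matrix(2.5, 1, 10),
                                params, n = 1, exclude_below = 0)
  expect_true(all(abs(ts2$f_right - params$theta) < 1e-9))
  # clip ceiling stays finite
  ts3 <- build_target_functions(matrix(50, 1, 10), matrix(50, 1, 10),
                                params, n = 1, exclude_below = 0)
  expect_true(all(is.finite(ts3$f_right)))
  # all-subthreshold pool errors
  expect_error(build_target_functions(matrix(0.1, 3, 10), matrix(0.2, 3, 10),
                                      params, n = 3), "below the activity")
})

test_that("zero learning rate leaves the weights untouched", {
  params <- rnn_params(n = 16, epochs = 4, alpha_learn = 0, seed = 6)
  tr <- reference_target_traces(16)
  set.seed(6)
  targets <- build_target_functions(tr$right, tr$left, params, n = 16)
  model <- init_network(params)
  trained <- force_train(model, targets)
  expect_identical(trained$J, model$J)
  expect_length(attr(trained, "mse"), 4)
})

test_that("choice axis projection matches explicit arithmetic on a tiny fixture", {
  # 3 units, 2 timesteps, dt chosen so both steps lie in the pre-action window
  dt <- 2.6
  acts_r <- list(matrix(c(0.9, 0.1, 0.5, 0.9, 0.1, 0.5), 3, 2))
  acts_l <- list(matrix(c(0.1, 0.9, 0.5, 0.1, 0.9, 0.5), 3, 2))
  pr <- choice_axis_projection(acts_r, acts_l, dt,
                               pre_action_window = c(0, 6),
                               iti_window = c(0, 2.7))
  expect_equal(sum(pr$axis^2), 1, tolerance = 1e-10)
  expect_equal(pr$axis, c(0.8, -0.8, 0) / sqrt(1.28), tolerance = 1e-10)
  # populations differing only along a unit vector e
  e <- c(1, 0, 0)
  acts_r2 <- list(matrix(0.5 + 0.3 * e, 3, 2))
  acts_l2 <- list(matrix(0.5 - 0.3 * e, 3, 2))
  pr2 <- choice_axis_projection(acts_r2, acts_l2, dt,
                                pre_action_window = c(0, 6),
                                iti_window = c(0, 2.7))
  expect_equal(abs(sum(pr2$axis * e)), 1, tolerance = 1e-10)
  # identical trial types -> degenerate flag
  pr3 <- choice_axis_projection(acts_r2, acts_r2, dt,
                                pre_action_window = c(0, 6),
                                iti_window = c(0, 2.7))
  expect_true(pr3$degenerate)
})

test_that("switch detection uses a strict midpoint rule", {
  proj <- structure(list(axis = c(1, 0), ref_right = rep(1, 100),
                         ref_left = rep(0, 100), baseline = c(right = 0, left = 0),
                         norm_const = 1, t = seq(0.001, 0.1, by = 0.001),
                         degenerate = FALSE),
                    class = "choice_projection")
  expect_true(detect_switch(proj, rep(1, 100)))      # at right reference
  expect_false(detect_switch(proj, rep(0, 100)))     # at left reference
  expect_false(detect_switch(proj, rep(0.5, 100)))   # exact midpoint: no switch
  expect_true(detect_switch(proj, rep(0.5 + 1e-9, 100)))
})

test_that("synaptic strength statistics match closed forms", {
  J <- matrix(c(1, -1, 1, -1), 2, 2)
  s <- synaptic_strength(J)
  expect_equal(unlist(s), c(overall = 1, excitatory = 1, inhibitory = 1))
  s0 <- synaptic_strength(matrix(0, 3, 3))
  expect_equal(s0$overall, 0)
  expect_true(is.na(s0$excitatory) && is.na(s0$inhibitory))
  set.seed(7)
  Jn <- matrix(rnorm(500 * 500, sd = 0.3), 500, 500)
  expect_equal(synaptic_strength(Jn)$overall, 0.3 * sqrt(2 / pi),
               tolerance = 0.02)
})

test_that("weight ablation modes behave as specified", {
  params <- rnn_params(n = 16, seed = 8)
  m <- init_network(params)
  expect_identical(ablate_weights(m, "random", 0)$J, m$J)
  set.seed(1)
  m10 <- ablate_weights(m, "random", 0.1, subset_frac = 0.5)
  changed <- m10$J != m$J
  expect_equal(mean(changed), 0.5, tolerance = 0.02)
  expect_equal(m10$J[changed], m$J[changed] * 0.9)
  mr <- ablate_weights(m, "region", 0.2, region = "ALM")
  cols <- which(m$region_of == "ALM")
  expect_equal(mr$J[, cols], m$J[, cols] * 0.8)
  expect_equal(mr$J[, -cols], m$J[, -cols])
  expect_error(ablate_weights(m, "region", 0.1), "region mode requires")
})

test_that("RNN checkpoints round-trip through HDF5", {
  params <- rnn_params(n = 16, seed = 9)
  m <- init_network(params)
  attr(m, "x0") <- rep(0.5, 16)
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(path))
  write_rnn_model(m, path)
  m2 <- read_rnn_model(path)
  expect_equal(m2$J, m$J, ignore_attr = TRUE)
  expect_equal(m2$W_cue, m$W_cue)
  expect_equal(m2$params$alpha, params$alpha)
  expect_equal(attr(m2, "x0"), attr(m, "x0"))
})
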