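# Pseudo-mouse construction, embedding backend, kNN decoding, relative
# accuracy, region contributions.

test_that("pseudo-mouse row counts match the stacking contract", {
  pm <- fixture_pseudo_mouse(cells_per_region = 200)
  expect_equal(nrow(pm$activity), 1600)
  expect_equal(table(pm$region_of)[["vS1"]], 200L)
  pm2 <- fixture_pseudo_mouse(cells_per_region = 145)
  expect_equal(nrow(pm2$activity), 1160)
})

test_that("an undersized pool fails naming the deficient region", {
  pools <- structure(list(
    activity = stats::setNames(lapply(CORTEX_REGIONS, function(r)
      matrix(rnorm((if (r == "RSC") 150 else 250) * 40), ncol = 40)),
      CORTEX_REGIONS),
    labels = data.frame(condition = "none", side = "left",
                        replicate = rep(1:4, each = 10),
                        time_idx = rep(1:10, 4),
                        pseudo_trial = rep(1:4, each = 10)),
    frames_per_trial = 10, label = "stimulus"), class = "region_pools")
  expect_error(build_pseudo_mouse(pools, "stimulus", cells_per_region = 200),
               "RSC")
  expect_error(build_pseudo_mouse(pools, "choice"), "label = 'choice'")
})

test_that("region pools sample matched trial counts and exclude short sessions", {
  cfg <- cohort_preset("control", neurons_per_region = 10, n_trials = 120,
                       seed = 17)
  ss <- generate_cohort(cfg, 1)
  pools <- region_pools(ss, "stimulus", n_nd = 10, n_d = 2, seed = 1)
  lab <- pools$labels
  expect_equal(sum(lab$condition == "none" & lab$time_idx == 1), 20)
  expect_equal(sum(lab$condition == "early" & lab$time_idx == 1), 4)
  expect_equal(nrow(pools$activity$ALM), 10)
  expect_equal(ncol(pools$activity$ALM), nrow(lab))
  # left/right balanced within every condition
  tr1 <- lab[lab$time_idx == 1, ]
  expect_true(all(table(tr1$condition, tr1$side)[, "left"] ==
                    table(tr1$condition, tr1$side)[, "right"]))
  expect_error(suppressWarnings(region_pools(ss, "stimulus", n_nd = 500,
                                             seed = 1)), "enough trials")
})

test_that("balanced 80/20 splitting and tie-breaking work as declared", {
  pm <- fixture_pseudo_mouse(n_trials_per_side = 50)    # 100 balanced trials
  sp <- split_and_tune(pm, linear_backend(), grid = list(list(gamma = 0.1)),
                       seed = 1)
  expect_length(sp$train_trials, 80)
  expect_length(sp$test_trials, 20)
  expect_length(intersect(sp$train_trials, sp$test_trials), 0)
  # unbalanced input is balanced before splitting: drop 20 left trials
  lab <- pm$labels
  keep_tr <- setdiff(seq_len(100), 1:10)                 # 40 left / 50 right
  pm2 <- pm
  keep_fr <- lab$pseudo_trial %in% keep_tr
  pm2$activity <- pm$activity[, keep_fr]
  pm2$labels <- lab[keep_fr, ]
  sp2 <- split_and_tune(pm2, linear_backend(), grid = list(list(gamma = 0.1)),
                        seed = 1)
  expect_length(c(sp2$train_trials, sp2$test_trials), 80)  # 40 + 40 balanced
  # tied validation losses -> first grid point in declared order
  sp3 <- split_and_tune(pm, linear_backend(),
                        grid = list(list(gamma = 0.2), list(gamma = 0.2)),
                        seed = 2)
  expect_identical(sp3$chosen, 1L)
})

test_that("kNN decoding satisfies its sanity limits", {
  set.seed(5)
  emb <- matrix(rnorm(120 * 3), 120, 3)
  lab <- rep(c("left", "right"), 60)
  expect_equal(knn_decode(emb, lab, emb, lab, k = 1)$overall, 1)
  # two antipodal clusters
  base <- matrix(rnorm(60 * 3), 60, 3) + 5
  emb2 <- rbind(base, -base)
  lab2 <- rep(c("left", "right"), each = 60)
  expect_equal(knn_decode(emb2, lab2, emb2, lab2, k = 5)$overall, 1)
  expect_error(knn_decode(rbind(emb, 0), c(lab, "left"), emb, lab),
               "zero-norm")
  pf <- knn_decode(emb2, lab2, emb2, lab2, time_idx = rep(1:6, 20))$per_frame
  expect_equal(nrow(pf), 6)
})

test_that("relative accuracy differences and windows are exact", {
  mk <- function(v) data.frame(time_idx = seq_along(v), accuracy = v)
  same <- relative_accuracy(mk(rep(0.7, 37)), mk(rep(0.7, 37)), "early")
  expect_true(all(same$series$relative == 0))
  const <- relative_accuracy(mk(rep(0.6, 37)), mk(rep(0.8, 37)), "middle")
  expect_equal(const$window_mean, -0.2)
  # linear ramp: window mean equals the hand-computed average
  ramp <- seq(0, 1, length.out = 37)
  ra <- relative_accuracy(mk(ramp), mk(rep(0, 37)), "late", rate = 9.35)
  tc <- (seq_len(37) - 0.5) / 9.35
  idx <- which(tc >= 3.2 & tc < 4.2)
  expect_equal(ra$window_mean, mean(ramp[idx]))
  expect_equal(ra$window_idx, idx)
})

test_that("the supervised linear backend separates labeled classes", {
  pm <- fixture_pseudo_mouse(signal = 2)
  sp <- split_and_tune(pm, linear_backend(),
                       grid = list(list(gamma = 0.05), list(gamma = 0.5)),
                       seed = 3)
  lab <- pm$labels
  ftr <- which(lab$pseudo_trial %in% sp$train_trials)
  fte <- which(lab$pseudo_trial %in% sp$test_trials)
  acc <- knn_decode(backend_transform(sp$backend, pm$activity[, ftr]),
                    lab$side[ftr],
                    backend_transform(sp$backend, pm$activity[, fte]),
                    lab$side[fte])$overall
  expect_gte(acc, 0.95)
  # shuffled labels sit at chance
  set.seed(6)
  accs <- vapply(1:20, function(i) {
    sl <- sample(lab$side[ftr])
    knn_decode(backend_transform(sp$backend, pm$activity[, ftr]), sl,
               backend_transform(sp$backend, pm$activity[, fte]),
               sample(lab$side[fte]))$overall
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("region contribution isolates the signal-carrying region", {
  pm <- fixture_pseudo_mouse(signal = 2, signal_region = "M2")
  sp <- split_and_tune(pm, linear_backend(), grid = list(list(gamma = 0.1)),
                       seed = 4)
  baseline <- region_contribution(sp, pm, "none")
  keep_sig <- region_contribution(sp, pm, "M2")
  keep_null <- region_contribution(sp, pm, "RSC")
  expect_gte(baseline$overall, 0.9)
  expect_gte(keep_sig$overall, 0.9)
  expect_lt(abs(keep_null$overall - 0.5), 0.07)
  expect_error(region_contribution(sp, pm, "XX"), "unknown region")
})
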