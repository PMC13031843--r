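# Configuration-driven orchestration: generate cohorts, run the analyses,
# emit tables and a cohort-contrast summary.

#' Default pipeline run configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; fully determines outputs.
#' @param n_sessions sessions per cohort.
#' @param neurons_per_region,n_trials generator scale.
#' @param stages stages to run, a subset of
#'   `c("generate", "selectivity", "connectivity", "subspace", "decode",
#'   "rnn", "report")`.
#' @param n_boot bootstrap resamples for cohort contrasts.
#' @param rnn_n,rnn_epochs RNN scale (small by default; the full-scale
#'   model uses 1024 units and 1500 epochs).
#' @param generator extra [generator_config()] overrides (list).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("cortexcomm_run_"), seed = 1L,
                       n_sessions = 2, neurons_per_region = 40, n_trials = 60,
                       stages = c("generate", "selectivity", "connectivity",
                                  "subspace", "decode", "rnn", "report"),
                       n_boot = 1000, rnn_n = 64, rnn_epochs = 300,
                       generator = list()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_sessions = n_sessions,
                 neurons_per_region = neurons_per_region,
                 n_trials = n_trials, stages = stages, n_boot = n_boot,
                 rnn_n = rnn_n, rnn_epochs = rnn_epochs,
                 generator = generator),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) do.call(run_config, yaml::read_yaml(path))

# mean of inter-regional (off-diagonal) cells of a region_pair_matrix
.inter_mean <- function(rpm) {
  v <- rpm$value
  mean(v[row(v) != col(v)], na.rm = TRUE)
}

# trial-averaged correct non-distractor activity over the 5.5-s RNN span
#' Trial-averaged traces for RNN target construction
#'
#' Correct non-distractor trial averages over the training span (0.5 s
#' before stimulus onset to delay offset), per trial type.
#'
#' @param session a `cortex_session`.
#' @return list with `right`, `left` (neurons x frames) matrices.
#' @export
rnn_training_traces <- function(session) {
  rate <- session$frame_rate_hz
  tr <- session$trials
  span <- function(onset) seq.int(sec_to_frame(-0.5, rate) + onset + 1L,
                                  sec_to_frame(5, rate) + onset)
  avg <- function(side) {
    idx <- which(tr$outcome == "correct" & tr$distractor == "none" &
                   tr$stimulus_side == side)
    if (!length(idx)) stop("no correct non-distractor ", side, " trials")
    Reduce(`+`, lapply(idx, function(t)
      session$activity[, span(tr$onset_frame[t]), drop = FALSE])) / length(idx)
  }
  list(right = avg("right"), left = avg("left"))
}

#' Run the full analysis pipeline
#'
#' Generates matched-seed control and reduced-connectivity cohorts and runs
#' the enabled stages, writing per-stage CSV tables, a JSON summary of the
#' cohort contrasts (direction and one-tailed bootstrap p per metric) and a
#' structured log with per-stage timing. A stage failure is isolated: later
#' stages still run and the failure is recorded in the log and summary.
#'
#' @param config a `run_config`.
#' @return invisible list with per-stage results and the summary.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  logit <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                             "\n", file = log_path, append = TRUE)
  res <- list()
  summary <- list(seed = config$seed, contrasts = list(), failed = character(0))

  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      logit("STAGE", name, "FAILED:", conditionMessage(e))
      summary$failed <<- c(summary$failed, name)
      NULL
    })
    logit("stage", name, "done in",
          sprintf("%.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res[[name]] <<- out
    out
  }

  gen_args <- utils::modifyList(
    list(neurons_per_region = config$neurons_per_region,
         n_trials = config$n_trials, seed = config$seed),
    config$generator)
  cohorts <- NULL
  stage("generate", function() {
    ctrl <- do.call(cohort_preset,
                    c(list(cohort = "control"), gen_args))
    red <- do.call(cohort_preset,
                   c(list(cohort = "reduced_connectivity"), gen_args))
    cohorts <<- list(control = generate_cohort(ctrl, config$n_sessions),
                     reduced = generate_cohort(red, config$n_sessions))
    cohorts
  })
  if (is.null(cohorts)) {
    logit("no cohorts; remaining stages skipped")
    summary$failed <- union(summary$failed, setdiff(config$stages, "generate"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(results = res, summary = summary)))
  }

  contrast <- function(name, ctrl_vals, red_vals, tail) {
    bt <- bootstrap_diff_test(ctrl_vals, red_vals, n_boot = config$n_boot,
                              tail = tail, seed = config$seed)
    summary$contrasts[[name]] <<-
      list(control_mean = mean(ctrl_vals), reduced_mean = mean(red_vals),
           direction = if (mean(red_vals) < mean(ctrl_vals)) "reduced < control"
                       else "reduced >= control",
           tail = tail, p_value = bt$p_value)
  }

  stage("selectivity", function() {
    rows <- do.call(rbind, lapply(names(cohorts), function(cn) {
      do.call(rbind, lapply(seq_along(cohorts[[cn]]), function(si) {
        s <- cohorts[[cn]][[si]]
        lab <- classify_epoch_selectivity(s, epochs = c("stimulus", "delay", "action"))
        do.call(rbind, lapply(c("stimulus", "delay", "action"), function(ep)
          data.frame(cohort = cn, session = si, epoch = ep,
                     region = CORTEX_REGIONS,
                     fraction = vapply(CORTEX_REGIONS, function(r)
                       selectivity_fraction(lab, s, r, ep), numeric(1)))))
      }))
    }))
    utils::write.csv(rows, file.path(config$out_dir, "selectivity_fractions.csv"),
                     row.names = FALSE)
    rows
  })

  stage("connectivity", function() {
    per_cohort <- lapply(cohorts, function(ss) {
      list(iti = iti_functional_connectivity(ss),
           trial = trial_by_trial_correlation(ss))
    })
    tab <- do.call(rbind, lapply(names(per_cohort), function(cn) {
      do.call(rbind, lapply(names(per_cohort[[cn]]), function(mn) {
        v <- per_cohort[[cn]][[mn]]$value
        data.frame(cohort = cn, metric = mn,
                   source = rep(rownames(v), 8),
                   target = rep(colnames(v), each = 8),
                   value = as.vector(v))
      }))
    }))
    utils::write.csv(tab, file.path(config$out_dir, "connectivity.csv"),
                     row.names = FALSE)
    per_sess <- function(ss, fun) vapply(ss, function(s)
      .inter_mean(fun(list(s))), numeric(1))
    contrast("inter_regional_iti_connectivity",
             per_sess(cohorts$control, iti_functional_connectivity),
             per_sess(cohorts$reduced, iti_functional_connectivity), "less")
    contrast("inter_regional_trial_correlation",
             per_sess(cohorts$control, trial_by_trial_correlation),
             per_sess(cohorts$reduced, trial_by_trial_correlation), "less")
    per_cohort
  })

  stage("subspace", function() {
    spat <- function(s) {
      fr <- epoch_frames_all(s, "trial_window")
      X <- t(s$activity[s$region == "PPC", fr, drop = FALSE])
      spatial_degeneracy(X, t(s$activity[s$region == "ALM", fr, drop = FALSE]),
                         t(s$activity[s$region == "M2", fr, drop = FALSE]),
                         dims = 3, lambda = 1)
    }
    temp <- function(s) {
      w <- one_second_windows(s)
      sim <- temporal_degeneracy(s$activity[s$region == "PPC", , drop = FALSE],
                                 s$activity[s$region == "ALM", , drop = FALSE],
                                 w, dims = 3, lambda = 1)
      mean(sim[upper.tri(sim)])
    }
    sp_c <- vapply(cohorts$control, spat, numeric(1))
    sp_r <- vapply(cohorts$reduced, spat, numeric(1))
    tp_c <- vapply(cohorts$control, temp, numeric(1))
    tp_r <- vapply(cohorts$reduced, temp, numeric(1))
    contrast("spatial_degeneracy", sp_c, sp_r, "less")
    contrast("temporal_degeneracy", tp_c, tp_r, "less")
    tab <- data.frame(cohort = rep(c("control", "reduced"),
                                   times = c(length(sp_c), length(sp_r))),
                      spatial = c(sp_c, sp_r), temporal = c(tp_c, tp_r))
    utils::write.csv(tab, file.path(config$out_dir, "subspace.csv"),
                     row.names = FALSE)
    tab
  })

  stage("decode", function() {
    drop_of <- function(ss, seed) {
      pools <- region_pools(ss, "stimulus",
                            n_nd = min(20, floor(config$n_trials / 4)),
                            n_d = 2, seed = seed)
      cpr <- min(vapply(pools$activity, nrow, integer(1)))
      pm <- build_pseudo_mouse(pools, "stimulus", cells_per_region = cpr,
                               seed = seed)
      sp <- split_and_tune(pm, linear_backend(),
                           grid = list(list(gamma = 0.1)), seed = seed)
      lab <- pm$labels
      dec <- function(trials) {
        ftr <- which(lab$pseudo_trial %in% sp$train_trials)
        fq <- which(lab$pseudo_trial %in% trials)
        knn_decode(backend_transform(sp$backend, pm$activity[, ftr]),
                   lab$side[ftr],
                   backend_transform(sp$backend, pm$activity[, fq]),
                   lab$side[fq], time_idx = lab$time_idx[fq])
      }
      acc_test <- dec(sp$test_trials)$per_frame
      vapply(c("early", "middle", "late"), function(cd) {
        tr_d <- unique(lab$pseudo_trial[lab$condition == cd])
        relative_accuracy(dec(tr_d)$per_frame, acc_test, cd)$window_mean
      }, numeric(1))
    }
    dc <- drop_of(cohorts$control, config$seed)
    dr <- drop_of(cohorts$reduced, config$seed)
    contrast("distractor_decoding_drop", dc, dr, "less")
    tab <- data.frame(cohort = rep(c("control", "reduced"), each = 3),
                      distractor = rep(c("early", "middle", "late"), 2),
                      window_mean = c(dc, dr))
    utils::write.csv(tab, file.path(config$out_dir, "decoding.csv"),
                     row.names = FALSE)
    tab
  })

  stage("rnn", function() {
    # cohort selectivity propagates into attractor depth: weaker late-delay
    # separation -> shallower reference targets -> less stable choice code
    train_one <- function(ss, seed) {
      sep <- mean(vapply(ss, cohort_separation, numeric(1)))
      params <- rnn_params(n = config$rnn_n, epochs = config$rnn_epochs,
                           seed = seed)
      tr <- reference_target_traces(config$rnn_n, separation_to_depth(sep))
      set.seed(seed)
      targets <- build_target_functions(tr$right, tr$left, params, n = params$n)
      force_train(init_network(params), targets)
    }
    # matched seed for paired initialization across cohorts
    mc <- train_one(cohorts$control, config$seed)
    mr <- train_one(cohorts$reduced, config$seed)
    swc <- ablate_and_test(mc, "random", 0.1, repeats = 5, n_trials = 20,
                           n_ref = 5, seed = config$seed, subset_frac = 0.25,
                           distractor_amp = 0.3)
    swr <- ablate_and_test(mr, "random", 0.1, repeats = 5, n_trials = 20,
                           n_ref = 5, seed = config$seed, subset_frac = 0.25,
                           distractor_amp = 0.3)
    contrast("rnn_switching_after_ablation", swc$proportion, swr$proportion,
             "greater")
    tab <- rbind(cbind(cohort = "control", swc), cbind(cohort = "reduced", swr))
    utils::write.csv(tab, file.path(config$out_dir, "rnn_switching.csv"),
                     row.names = FALSE)
    tab
  })

  stage("report", function() summary$contrasts)

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  logit("run complete")
  invisible(list(results = res, summary = summary))
}

#' Expected layout of the published dataset (loader stub)
#'
#' The processed imaging dataset this package emulates is deposited on
#' Zenodo (record 14551514). Loading it is optional and outside the test
#' path; this stub only documents the expected per-session layout so a
#' loader can be written against [session()].
#'
#' @return character vector describing the expected fields.
#' @export
zenodo_layout <- function() {
  c("per-session activity: neurons x frames, z-scored deconvolved events (~9.35 Hz)",
    "per-neuron region label: one of ALM, M1a, M1p, M2, S1fl, vS1, RSC, PPC",
    "per-trial table: onset frame, stimulus side, choice side, outcome, distractor (none/early/middle/late)",
    "map each session with cortexcomm::session(activity, region, frame_rate_hz, trials, cohort_tag)")
}
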