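# Synthetic RNN training targets from a reference bistable network.
#
# FORCE fitting of arbitrary slow trajectories at small network sizes is
# dynamically fragile: a target family is reliably learnable only if it is
# realizable by stable dynamics of the same architecture. The fixture
# therefore generates its two-trial-type targets by simulating a hand-built
# reference network whose trajectories are stable by construction
# (innate-trajectory logic): a stimulus-driven winner pool (right
# attractor), an inhibition-partner pool whose elevated initial state
# commits autonomously to the left attractor, and a pool of heterogeneous
# decay units providing shared input-free temporal structure.

#' Reference-network target traces for RNN training
#'
#' Simulates the reference bistable network for one right (stimulus peak 1)
#' and one left (no stimulus) trial and returns trial-averaged-like
#' activity traces on the 0-5 scale at the imaging rate, ready for
#' [build_target_functions()].
#'
#' `separation_scale` shrinks both trajectories toward their common mean,
#' producing shallower choice attractors after training; it is the knob by
#' which cohort-level selectivity differences (see [cohort_separation()])
#' propagate into attractor depth.
#'
#' @param n units (divisible by 4).
#' @param separation_scale in (0, 1\]; 1 = full depth.
#' @param seed seed for the reference-network draw.
#' @param rate output frame rate (Hz).
#' @return list: `right`, `left` (n x frames activity), `pool` membership.
#' @export
reference_target_traces <- function(n = 64, separation_scale = 1, seed = 99,
                                    rate = 9.35) {
  stopifnot(n %% 4 == 0, separation_scale > 0, separation_scale <= 1)
  set.seed(seed)
  q <- n / 4
  pool <- rep(c("R", "L", "D"), c(q * 1.5, q * 1.5, q))
  g <- stats::runif(n, 0.85, 1.15)
  same <- outer(pool, pool, "==")
  Jstar <- (ifelse(same, 6, -1.5) / (1.5 * q)) * outer(g, g)
  Jstar[pool == "D", ] <- 0
  Jstar[, pool == "D"] <- 0
  diag(Jstar)[pool == "D"] <- stats::runif(sum(pool == "D"), 4.6, 5.3)
  ws <- 2.5 * (pool == "R") * stats::runif(n, 0.8, 1.2)
  wc <- 0.1 * stats::rnorm(n)
  sig <- function(x) 1 / (1 + exp(-(x - 3)))
  dt <- 0.001; tau <- 0.01
  x0 <- rep(0.3, n)
  x0[pool == "L"] <- 3.5 + stats::runif(sum(pool == "L"), -0.2, 0.2)
  x0[pool == "R"] <- -0.5
  x0[pool == "D"] <- 4.0 + stats::runif(sum(pool == "D"), -0.3, 0.3)
  steps <- as.integer(TRIAL_SPAN_S / dt)
  sim <- function(stim_peak) {
    tt <- (seq_len(steps) - 0.5) * dt
    istim <- stim_peak * pmax(0, 1 - abs(tt - 1.0) / 0.5)
    icue <- as.numeric(tt >= 1.4 & tt < 1.5)
    x <- x0
    out <- matrix(0, n, steps)
    for (t in seq_len(steps)) {
      z <- drop(Jstar %*% sig(x)) + ws * istim[t] + icue[t] * wc
      x <- x + dt / tau * (z - x)
      out[, t] <- x
    }
    out
  }
  frames <- floor(TRIAL_SPAN_S * rate)
  pick <- pmin(steps, round(((seq_len(frames) - 0.5) / rate) / dt))
  right <- 5 * sig(sim(1.0))[, pick]
  left <- 5 * sig(sim(0))[, pick]
  if (separation_scale < 1) {
    mid <- rowMeans(cbind(left, right))
    right <- pmax(mid + separation_scale * (right - mid), 0.05)
    left <- pmax(mid + separation_scale * (left - mid), 0.05)
  }
  list(right = right, left = left, pool = pool)
}

#' Delay-period trial-type separation of a session
#'
#' Mean absolute right-minus-left late-delay activity difference over the
#' top quartile of neurons (correct non-distractor trials) — a scalar
#' summary of how strongly the population separates the two trial types at
#' the end of the delay.
#'
#' @param session a `cortex_session`.
#' @return nonnegative scalar.
#' @export
cohort_separation <- function(session) {
  tr <- session$trials
  use <- tr$outcome == "correct" & tr$distractor == "none"
  ir <- which(use & tr$stimulus_side == "right")
  il <- which(use & tr$stimulus_side == "left")
  if (!length(ir) || !length(il)) stop("need correct non-distractor trials of both sides")
  d <- abs(rowMeans(.epoch_trial_means(session, "late_delay", ir)) -
             rowMeans(.epoch_trial_means(session, "late_delay", il)))
  mean(sort(d, decreasing = TRUE)[seq_len(max(1, round(0.25 * length(d))))])
}

#' Map a cohort separation onto an attractor-depth scale
#'
#' Affine map calibrated so that the control cohort's typical separation
#' (~0.6 z-units) gives full depth and markedly weaker separations give
#' proportionally shallower attractors; clamped to \[0.4, 1\].
#'
#' @param separation output of [cohort_separation()].
#' @return `separation_scale` for [reference_target_traces()].
#' @export
separation_to_depth <- function(separation) {
  min(1, max(0.4, (separation - 0.27) / 0.33))
}
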