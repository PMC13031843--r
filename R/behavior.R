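#' Task performance under a distractor condition
#'
#' Fraction of correct responses among responded trials: no-response trials
#' are excluded from the denominator, and the value is computed separately
#' per distractor condition when one is requested.
#'
#' @param trials trial table (see [trial_table()]).
#' @param condition "all" or one of none/early/middle/late.
#' @return fraction in \[0,1\].
#' @export
task_performance <- function(trials, condition = "all") {
  validate_trials(trials)
  condition <- match.arg(condition, c("all", DISTRACTOR_LEVELS))
  if (condition != "all") trials <- trials[trials$distractor == condition, , drop = FALSE]
  responded <- trials$outcome != "no_response"
  if (!any(responded))
    stop("undefined performance: zero responded trials under condition '",
         condition, "'")
  mean(trials$outcome[responded] == "correct")
}

#' Fit a logistic learning curve across sessions
#'
#' Nonlinear least-squares fit of `y(t) = L / (1 + exp(-k (t - t0)))` to a
#' per-session performance sequence; the slope `k` is the learning rate.
#' Bounded optimization (`L` in \[0,1\], `k` in \[0,10\], `t0` within the
#' observed session range) from three deterministic multi-starts.
#'
#' @param performance_by_session numeric vector of session performances
#'   (fractions); session index t = 1, 2, ...
#' @return list of class `learning_curve_fit` with fields `L`, `k`, `t0`,
#'   `residual_norm`, `degenerate`, `converged`, `fitted`.
#' @export
fit_learning_curve <- function(performance_by_session) {
  y <- as.numeric(performance_by_session)
  t <- seq_along(y)
  if (length(y) < 4) stop("need at least 4 sessions to fit a learning curve")
  if (stats::sd(y) < 1e-10) {
    return(structure(list(L = mean(y), k = NA_real_, t0 = NA_real_,
                          residual_norm = 0, degenerate = TRUE,
                          converged = TRUE, fitted = rep(mean(y), length(y))),
                     class = "learning_curve_fit"))
  }
  sse <- function(p) {
    yy <- p[1] / (1 + exp(-p[2] * (t - p[3])))
    sum((y - yy)^2)
  }
  lower <- c(0, 0, min(t))
  upper <- c(1, 10, max(t))
  starts <- list(c(max(y), 0.5, stats::median(t)),
                 c(max(y), 2.0, stats::quantile(t, 0.25, names = FALSE)),
                 c(min(1, max(y) + 0.05), 0.1, stats::quantile(t, 0.75, names = FALSE)))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(stats::optim(p0, sse, method = "L-BFGS-B", lower = lower,
                                 upper = upper,
                                 control = list(factr = 1e4, maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    return(structure(list(L = NA_real_, k = NA_real_, t0 = NA_real_,
                          residual_norm = NA_real_, degenerate = FALSE,
                          converged = FALSE, fitted = NULL),
                     class = "learning_curve_fit"))
  p <- best$par
  structure(list(L = p[1], k = p[2], t0 = p[3],
                 residual_norm = sqrt(best$value), degenerate = FALSE,
                 converged = best$convergence == 0,
                 fitted = p[1] / (1 + exp(-p[2] * (t - p[3])))),
            class = "learning_curve_fit")
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  if (isTRUE(x$degenerate))
    cat("<learning_curve_fit> degenerate (constant performance), L =", x$L, "\n")
  else
    cat(sprintf("<learning_curve_fit> L = %.3f, k = %.3f, t0 = %.2f, |resid| = %.4f%s\n",
                x$L, x$k, x$t0, x$residual_norm,
                if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
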