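#' Closed-form burst kinetics of the no-feedback model
#'
#' In the absence of feedback (`f = 0`) the promoter is a free telegraph
#' switch, so dwell times are exponential and the burst summaries follow
#' from \eqn{\langle BF\rangle = 1/\tau_{OFF}} and \eqn{\langle BS\rangle =
#' k_{transcription}\,\tau_{ON}}: with \eqn{D_1} the ON state
#' (\eqn{\lambda_1 \gg \lambda_0}), \eqn{\tau_{OFF} = 1/\gamma_1},
#' \eqn{\tau_{ON} = 1/\gamma_0}, hence \eqn{\langle BF\rangle = \gamma_1}
#' and \eqn{\langle BS\rangle = \lambda_1/\gamma_0}; in the mirrored case
#' (\eqn{D_0} ON) \eqn{\langle BF\rangle = \gamma_0} and
#' \eqn{\langle BS\rangle = \lambda_0/\gamma_1}. Leakage synthesis during
#' the OFF state is not part of a burst and leaves both summaries unchanged.
#'
#' With feedback the dwell times depend on the product copy number and no
#' closed form exists; use [empirical_burst()] on a simulated trajectory.
#'
#' @param params a [gene_params()] object with `f = 0` and an unambiguous
#'   ON state (`lambda1 != lambda0`).
#' @return An object of class `burst_summary`: list with `mean_bf`,
#'   `mean_bs`, `tau_on`, `tau_off`, `n_bursts` (`NA` for the theoretical
#'   path).
#' @export
theoretical_burst <- function(params) {
  p <- normalize_params(params)
  if (p$f != 0) {
    stop("closed-form burst kinetics require f = 0; ",
         "use empirical_burst() on a simulated trajectory for feedback regimes",
         call. = FALSE)
  }
  lab <- feedback_labeling(p)
  if (lab == "constitutive") {
    stop("burst labeling unresolvable: lambda1 = lambda0 has no ON state",
         call. = FALSE)
  }
  if (lab == "negative") {
    tau_off <- 1 / p$gamma1; tau_on <- 1 / p$gamma0
    bs <- p$lambda1 / p$gamma0
  } else {
    tau_off <- 1 / p$gamma0; tau_on <- 1 / p$gamma1
    bs <- p$lambda0 / p$gamma1
  }
  structure(list(mean_bf = 1 / tau_off, mean_bs = bs,
                 tau_on = tau_on, tau_off = tau_off,
                 burst_rate = 1 / (tau_on + tau_off),
                 n_bursts = NA_integer_),
            class = "burst_summary")
}

#' @export
print.burst_summary <- function(x, ...) {
  cat(sprintf("<burst_summary> BF %.4g, BS %.4g, tau_on %.4g, tau_off %.4g",
              x$mean_bf, x$mean_bs, x$tau_on, x$tau_off))
  if (!is.na(x$n_bursts)) cat(sprintf(" (%d bursts observed)", x$n_bursts))
  cat("\n")
  invisible(x)
}

#' Empirical burst kinetics from a simulated trajectory
#'
#' Bursts are delimited by the promoter state (the state with the larger
#' synthesis rate is ON), not by product-count heuristics: `tau_on` and
#' `tau_off` are means over complete dwell intervals inside the
#' post-burn-in window (intervals cut by the window boundaries are
#' discarded, for unbiased means), `mean_bf` is the reciprocal of the mean
#' OFF dwell time (the defining relation \eqn{\langle BF\rangle =
#' 1/\tau_{OFF}}; at `f = 0` this estimates \eqn{\gamma_1} directly), and
#' `mean_bs` is the mean number of synthesis events fired during complete
#' ON intervals (counted from the reaction-channel log, so interleaved
#' degradation events do not bias it). The plain burst rate — OFF-to-ON
#' transitions per unit observation time, i.e. one burst per full
#' ON/OFF cycle — is returned separately as `burst_rate`; it coincides
#' with `mean_bf` only in the bursty limit \eqn{\tau_{ON} \ll \tau_{OFF}}.
#'
#' @param traj a baseline-variant `gene_trajectory` from [simulate_gene()].
#' @param params parameter set used to label the ON state; defaults to the
#'   trajectory's own.
#' @param burn_in start of the observation window.
#' @param min_on minimum number of complete ON intervals required.
#' @return A `burst_summary` with standard errors of the dwell means and of
#'   `mean_bs` in attribute `"se"`.
#' @export
empirical_burst <- function(traj, params = traj$params,
                            burn_in = traj$burn_in, min_on = 10L) {
  stopifnot(inherits(traj, "gene_trajectory"))
  if (traj$variant != "baseline") {
    stop("empirical burst extraction is defined for baseline-variant trajectories",
         call. = FALSE)
  }
  if (is.null(traj$segments)) {
    stop("trajectory carries no promoter segment log", call. = FALSE)
  }
  if (feedback_labeling(params) == "constitutive") {
    stop("burst labeling unresolvable: lambda1 = lambda0 has no ON state",
         call. = FALSE)
  }
  on_state <- if (params$lambda1 >= params$lambda0) 1L else 0L
  seg <- traj$segments
  window <- traj$t_end - burn_in
  stopifnot(window > 0)
  # complete intervals: fully inside (burn_in, t_end) with both boundaries
  # being genuine promoter switches
  complete <- seg$t_start > burn_in & seg$t_end < traj$t_end
  on <- complete & seg$state == on_state
  off <- complete & seg$state != on_state
  if (sum(on) < min_on) {
    stop("insufficient data: only ", sum(on),
         " complete ON intervals after burn-in (need >= ", min_on, ")",
         call. = FALSE)
  }
  on_dwell <- seg$t_end[on] - seg$t_start[on]
  off_dwell <- seg$t_end[off] - seg$t_start[off]
  bs_counts <- seg$n_synth[on]
  # OFF -> ON transitions inside the window
  n_entries <- sum(seg$state == on_state & seg$t_start > burn_in)
  tau_off_mean <- mean(off_dwell)
  tau_off_se <- stats::sd(off_dwell) / sqrt(length(off_dwell))
  out <- structure(list(mean_bf = 1 / tau_off_mean,
                        mean_bs = mean(bs_counts),
                        tau_on = mean(on_dwell),
                        tau_off = tau_off_mean,
                        burst_rate = n_entries / window,
                        n_bursts = as.integer(sum(on))),
                   class = "burst_summary")
  attr(out, "se") <- c(
    bf = tau_off_se / tau_off_mean^2,  # delta method on 1/tau_off
    bs = stats::sd(bs_counts) / sqrt(length(bs_counts)),
    tau_on = stats::sd(on_dwell) / sqrt(length(on_dwell)),
    tau_off = stats::sd(off_dwell) / sqrt(length(off_dwell)))
  attr(out, "dwells") <- list(on = on_dwell, off = off_dwell)
  out
}
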