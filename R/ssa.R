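#' Exact stochastic simulation of the leaky auto-regulatory gene circuit
#'
#' Runs the direct-method Gillespie algorithm on the reaction network
#' (see [gene_params()]) from the initial condition \eqn{(D_0, n = 0)}, and
#' returns a `gene_trajectory` carrying the stationary summaries used by the
#' rest of the package: a time-weighted product-count histogram over
#' `[burn_in, t_end]`, the log of maximal constant-promoter segments (dwell
#' intervals, with the number of synthesis events fired inside each), and
#' per-reaction-channel event counters. Two runs with the same seed are
#' bit-identical.
#'
#' Variants:
#' \describe{
#'   \item{`"baseline"`}{the catalytic-feedback network: the product flips
#'     \eqn{D_1 \to D_0} without being consumed (transcription-factor
#'     binding and dissociation assumed fast).}
#'   \item{`"slow_binding"`}{feedback by sequestration: binding consumes one
#'     free product molecule (\eqn{D_1 + P \to D_0{\cdot}P} at \eqn{f n})
#'     and dissociation (`k_off`) releases it, \eqn{D_0{\cdot}P \to D_0 +
#'     P}; only the unbound \eqn{D_0} reactivates at \eqn{\gamma_1}. As
#'     `k_off` grows large the bound episodes vanish and baseline behaviour
#'     is recovered.}
#'   \item{`"two_stage"`}{explicit transcription and translation:
#'     \eqn{D_s \to D_s + M} at \eqn{\lambda_s}, \eqn{M \to M + P} at
#'     `k_p`, \eqn{M \to \emptyset} at `d_m`, \eqn{P \to \emptyset} at `d`;
#'     the protein feeds back on the promoter. Default `d_m = 5` (relative
#'     to `d = 1`) reflects mRNA half-lives being much shorter than protein
#'     half-lives; default `k_p = d_m` keeps the mean protein level equal to
#'     the baseline product level.}
#' }
#'
#' @param params a [gene_params()] object (normalized internally; time is in
#'   units of the product lifetime `1/d`).
#' @param t_end total simulated time (default `1e5`).
#' @param seed integer RNG seed; recorded in the returned object.
#' @param variant one of `"baseline"`, `"slow_binding"`, `"two_stage"`.
#' @param variant_params named list: `k_off` for `"slow_binding"`; `k_p`,
#'   `d_m` for `"two_stage"`. Missing entries take the defaults above.
#' @param burn_in initial transient excluded from all stationary summaries
#'   (default 10% of `t_end`).
#' @param store_path logical; keep the full event path (time, promoter
#'   state, count after each event). Memory grows with the event count
#'   (~`1e7` events at `t_end = 1e5` for the Figure-scale rates), so this
#'   is off by default and meant for short runs.
#' @return An object of class `gene_trajectory`.
#' @export
simulate_gene <- function(params, t_end = 1e5, seed = 1L,
                          variant = c("baseline", "slow_binding", "two_stage"),
                          variant_params = NULL,
                          burn_in = 0.1 * t_end, store_path = FALSE) {
  variant <- match.arg(variant)
  p <- normalize_params(params)
  stopifnot(t_end > 0, burn_in >= 0, burn_in < t_end)
  k_off <- 0; k_p <- 0; d_m <- 0
  if (variant == "slow_binding") {
    k_off <- if (!is.null(variant_params$k_off)) variant_params$k_off else 1
    if (k_off < 0) stop("k_off must be nonnegative", call. = FALSE)
  } else if (variant == "two_stage") {
    d_m <- if (!is.null(variant_params$d_m)) variant_params$d_m else 5
    k_p <- if (!is.null(variant_params$k_p)) variant_params$k_p else d_m
    if (d_m <= 0 || k_p < 0) stop("need d_m > 0 and k_p >= 0", call. = FALSE)
  } else if (!is.null(variant_params)) {
    stop("variant_params are only meaningful for the slow_binding and two_stage variants",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  raw <- ssa_gillespie(p$gamma1, p$gamma0, p$f, p$lambda1, p$lambda0, p$d,
                       t_end, burn_in, match(variant, c("baseline", "slow_binding", "two_stage")) - 1L,
                       k_off, k_p, d_m, store_path)
  seg <- data.frame(t_start = raw$seg_start,
                    state = raw$seg_state,
                    n_synth = raw$seg_synth)
  seg$t_end <- c(seg$t_start[-1], t_end)
  traj <- list(params = p, t_end = t_end, burn_in = burn_in, seed = seed,
               variant = variant, variant_params = variant_params,
               hist_weights = raw$hist_weights,
               segments = seg,
               channel_counts = stats::setNames(raw$channel_counts,
                 c("activate", "deactivate_basal", "deactivate_feedback",
                   "synth_on", "synth_off", "degrade", "dissoc_or_translate",
                   "mrna_degrade")),
               final_count = raw$final_count)
  if (store_path) {
    traj$times <- raw$path_time
    traj$promoter_states <- raw$path_state
    traj$counts <- raw$path_count
    if (variant == "two_stage") traj$mrna <- raw$path_mrna
  }
  structure(traj, class = "gene_trajectory")
}

#' @export
print.gene_trajectory <- function(x, ...) {
  cat(sprintf("<gene_trajectory> variant %s, t_end %g (burn-in %g), seed %d\n",
              x$variant, x$t_end, x$burn_in, x$seed),
      sprintf("  %d promoter segments, %.3g reaction events\n",
              nrow(x$segments), sum(x$channel_counts)))
  invisible(x)
}

#' Assemble a trajectory from explicit event lists
#'
#' Constructor for hand-built sample paths (used mainly to test
#' time-weighted summaries): `times[i]` is the time of the i-th event and
#' `counts[i]`/`promoter_states[i]` the state immediately after it. The
#' first entry should be the initial condition at time 0.
#'
#' @param times nondecreasing event times starting at 0.
#' @param promoter_states integer vector (0/1) after each event.
#' @param counts nonnegative product counts after each event.
#' @param t_end end of the observation window (`>= max(times)`).
#' @param burn_in default burn-in carried by the object.
#' @return A `gene_trajectory` with a stored path and no stationary
#'   summaries precomputed.
#' @export
new_trajectory <- function(times, promoter_states, counts, t_end,
                           burn_in = 0) {
  stopifnot(length(times) == length(counts),
            length(times) == length(promoter_states),
            !is.unsorted(times), times[1] >= 0, t_end >= max(times),
            all(counts >= 0))
  structure(list(params = NULL, t_end = t_end, burn_in = burn_in,
                 seed = NA_integer_, variant = "baseline",
                 hist_weights = NULL,
                 segments = NULL, channel_counts = NULL,
                 times = times, promoter_states = as.integer(promoter_states),
                 counts = counts),
            class = "gene_trajectory")
}

#' Stationary histogram of a trajectory
#'
#' Time-weighted (not event-weighted) occupancy fraction of each product
#' count level after the burn-in window, normalized to one. For a
#' trajectory simulated without `store_path` the histogram accumulated
#' during the run is used, so `burn_in` must then equal the trajectory's
#' own; with a stored path any burn-in can be applied.
#'
#' @param traj a `gene_trajectory`.
#' @param burn_in start of the averaging window.
#' @return A [discrete_pmf()].
#' @export
stationary_histogram <- function(traj, burn_in = traj$burn_in) {
  stopifnot(inherits(traj, "gene_trajectory"))
  if (burn_in >= traj$t_end) {
    stop("burn_in leaves an empty observation window", call. = FALSE)
  }
  if (!is.null(traj$times)) {
    t0 <- traj$times
    t1 <- c(t0[-1], traj$t_end)
    w <- pmax(0, pmin(t1, traj$t_end) - pmax(t0, burn_in))
    if (sum(w) <= 0) stop("burn_in leaves an empty observation window", call. = FALSE)
    probs <- vapply(0:max(traj$counts),
                    function(k) sum(w[traj$counts == k]), numeric(1))
    return(discrete_pmf(probs))
  }
  if (!isTRUE(all.equal(burn_in, traj$burn_in))) {
    stop("this trajectory has no stored path; only its own burn_in (",
         traj$burn_in, ") is available", call. = FALSE)
  }
  if (sum(traj$hist_weights) <= 0) {
    stop("burn_in leaves an empty observation window", call. = FALSE)
  }
  discrete_pmf(traj$hist_weights)
}
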