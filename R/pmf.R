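#' Discrete probability mass function on a truncated support 0..N
#'
#' Light container shared by the analytic, CME and simulation paths: a
#' numeric vector `probs` of length `N + 1`, `probs[n + 1]` being the
#' probability of observing `n` product molecules.
#'
#' @param probs numeric vector of nonnegative masses for n = 0..N.
#' @param renormalize logical; divide by the sum (the pre-normalization
#'   residual `sum(probs) - 1` is kept in attribute `"residual"`).
#' @return An object of class `discrete_pmf`.
#' @export
discrete_pmf <- function(probs, renormalize = TRUE) {
  probs <- as.numeric(probs)
  if (length(probs) == 0 || any(!is.finite(probs))) {
    stop("probs must be a nonempty finite numeric vector", call. = FALSE)
  }
  if (any(probs < 0)) {
    if (min(probs) < -1e-12 * max(probs)) {
      stop("probs has negative entries beyond tolerance", call. = FALSE)
    }
    probs[probs < 0] <- 0
  }
  total <- sum(probs)
  if (total <= 0) stop("probs must have positive total mass", call. = FALSE)
  residual <- total - 1
  if (renormalize) probs <- probs / total
  structure(probs,
            names = as.character(seq_along(probs) - 1L),
            residual = residual,
            class = "discrete_pmf")
}

#' @export
print.discrete_pmf <- function(x, ...) {
  m <- pmf_moments(x, noise_ok = FALSE)
  cat(sprintf("<discrete_pmf> support 0..%d, mean %.4g, variance %.4g\n",
              support_max(x), m$mean, m$variance))
  invisible(x)
}

#' Maximum of the truncated support
#' @param pmf a [discrete_pmf()] object.
#' @return Integer N such that the support is 0..N.
#' @export
support_max <- function(pmf) length(unclass(pmf)) - 1L

#' Moments and noise intensity of a discrete pmf
#'
#' Direct summation counterpart of the generating-function moments: mean
#' \eqn{\langle n\rangle}, variance \eqn{\sigma_n^2}, and noise intensity
#' \eqn{\eta_n^2 = \sigma_n^2/\langle n\rangle^2} (the squared coefficient of
#' variation).
#'
#' @param pmf a [discrete_pmf()] object (normalized).
#' @param noise_ok logical; if `TRUE` (default) a zero mean is an error
#'   because the noise intensity is undefined there.
#' @return An object of class `moment_summary`: list with `mean`, `variance`,
#'   `noise` (and `NA` entries `gprime`, `gdoubleprime`, filled by the
#'   analytic path in [moments()]).
#' @export
pmf_moments <- function(pmf, noise_ok = TRUE) {
  stopifnot(inherits(pmf, "discrete_pmf"))
  p <- as.numeric(pmf)
  n <- seq_along(p) - 1
  mean_n <- sum(n * p)
  var_n <- sum((n - mean_n)^2 * p)
  if (mean_n == 0) {
    if (noise_ok) stop("noise intensity undefined: mean is zero", call. = FALSE)
    noise <- NA_real_
  } else {
    noise <- var_n / mean_n^2
  }
  structure(list(mean = mean_n, variance = var_n, noise = noise,
                 gprime = NA_real_, gdoubleprime = NA_real_),
            class = "moment_summary")
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("<moment_summary> mean %.6g, variance %.6g, noise %.6g\n",
              x$mean, x$variance, x$noise))
  invisible(x)
}

#' Total variation distance between two discrete pmfs
#'
#' \eqn{\mathrm{TV}(p,q) = \frac12\sum_n |p(n) - q(n)|}; supports are aligned
#' by zero-padding the shorter one. Symmetric, in `[0, 1]`, zero iff the
#' distributions are identical.
#'
#' @param p,q [discrete_pmf()] objects.
#' @return A number in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  stopifnot(inherits(p, "discrete_pmf"), inherits(q, "discrete_pmf"))
  pv <- as.numeric(p); qv <- as.numeric(q)
  n <- max(length(pv), length(qv))
  length(pv) <- n; length(qv) <- n
  pv[is.na(pv)] <- 0; qv[is.na(qv)] <- 0
  sum(abs(pv - qv)) / 2
}

#' Count the modes of a discrete pmf
#'
#' A mode is a strict local maximum of the pmf: an index `n` with
#' `p(n) > p(n-1)` and `p(n) > p(n+1)`, the boundaries needing only the
#' one-sided inequality. Each distinct peak of the copy-number distribution
#' corresponds to a distinct phenotypic state of the cell population, so the
#' mode count is the modality readout used by the leakage scans. Two
#' pre-processing steps make the count robust: (i) entries below
#' `floor_frac` times the maximum are discarded (suppresses spurious tail
#' modes from floating-point ripple in the analytic series), and (ii) runs
#' of adjacent entries differing by less than `flat_tol` are merged into one
#' plateau, reported at its leftmost index.
#'
#' @param pmf a [discrete_pmf()] object.
#' @param floor_frac discard threshold as a fraction of `max(probs)`.
#' @param flat_tol absolute tolerance for plateau merging.
#' @return An object of class `modality_report`: list with `n_modes`,
#'   `mode_locations` (strictly increasing molecule numbers) and
#'   `mode_masses` (pmf values there).
#' @export
count_modes <- function(pmf, floor_frac = 1e-4, flat_tol = 1e-12) {
  stopifnot(inherits(pmf, "discrete_pmf"))
  p <- as.numeric(pmf)
  p[p < floor_frac * max(p)] <- 0
  # compress into runs of (near-)equal values
  run_val <- p[1]
  run_start <- 1L
  vals <- numeric(0)
  starts <- integer(0)
  for (i in seq_along(p)[-1]) {
    if (abs(p[i] - run_val) >= flat_tol) {
      vals <- c(vals, run_val); starts <- c(starts, run_start)
      run_val <- p[i]; run_start <- i
    }
  }
  vals <- c(vals, run_val); starts <- c(starts, run_start)
  k <- length(vals)
  is_mode <- logical(k)
  for (j in seq_len(k)) {
    left_ok <- j == 1L || vals[j] > vals[j - 1L]
    right_ok <- j == k || vals[j] > vals[j + 1L]
    is_mode[j] <- left_ok && right_ok && vals[j] > 0
  }
  locs <- starts[is_mode] - 1L
  structure(list(n_modes = sum(is_mode),
                 mode_locations = locs,
                 mode_masses = p[starts[is_mode]]),
            class = "modality_report")
}

#' @export
print.modality_report <- function(x, ...) {
  cat(sprintf("<modality_report> %d mode(s) at {%s}\n", x$n_modes,
              paste(x$mode_locations, collapse = ", ")))
  invisible(x)
}

#' Truncated Poisson pmf
#'
#' Poisson(`lambda`) masses on 0..`n_max`, renormalized; the stationary law
#' of the constitutive model (\eqn{\lambda_1 = \lambda_0}, `f = 0`).
#'
#' @param lambda Poisson mean.
#' @param n_max truncation point; default covers mean + 10 standard
#'   deviations (floor 50).
#' @return A [discrete_pmf()].
#' @export
poisson_pmf <- function(lambda, n_max = NULL) {
  if (is.null(n_max)) n_max <- max(50, ceiling(lambda + 10 * sqrt(lambda)))
  discrete_pmf(stats::dpois(0:n_max, lambda))
}
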