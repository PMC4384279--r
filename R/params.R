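#' Kinetic parameters of the leaky two-state auto-regulatory gene model
#'
#' Constructs the parameter set of the reaction network
#' \deqn{D_0 \to D_1 \ (\gamma_1),\quad D_1 \to D_0 \ (\gamma_0),\quad
#'       D_1 + P \to D_0 + P \ (f),}
#' \deqn{D_1 \to D_1 + P \ (\lambda_1),\quad D_0 \to D_0 + P \ (\lambda_0),\quad
#'       P \to \emptyset \ (d).}
#' The promoter switches between two activity states; product is synthesized
#' in both states (the smaller of the two synthesis rates is the leakage
#' rate), and the product feeds back on the \eqn{D_1 \to D_0} transition with
#' per-molecule strength \eqn{f} (catalytically: the molecule is not
#' consumed). When \eqn{\lambda_1 \gg \lambda_0} the circuit is a negative
#' feedback loop with \eqn{D_1} the ON state; when \eqn{\lambda_0 \gg
#' \lambda_1} it is a positive feedback loop with \eqn{D_0} the ON state.
#'
#' @param gamma1 rate of the \eqn{D_0 \to D_1} transition (per unit time).
#' @param gamma0 basal rate of the \eqn{D_1 \to D_0} transition (per unit time).
#' @param f feedback strength: per-molecule contribution to the
#'   \eqn{D_1 \to D_0} propensity (per unit time per molecule).
#' @param lambda1 product synthesis rate in state \eqn{D_1} (molecules per
#'   unit time).
#' @param lambda0 product synthesis rate in state \eqn{D_0} (molecules per
#'   unit time).
#' @param d product degradation rate (per unit time); must be positive.
#'
#' @return An object of class `gene_params` (a named list of the six rates).
#' @seealso [normalize_params()], [derived_constants()], [feedback_labeling()]
#' @examples
#' p <- gene_params(gamma1 = 0.2, gamma0 = 0.1, f = 0, lambda1 = 40, lambda0 = 0)
#' feedback_labeling(p)
#' @export
gene_params <- function(gamma1, gamma0, f = 0, lambda1, lambda0 = 0, d = 1) {
  vals <- c(gamma1 = gamma1, gamma0 = gamma0, f = f,
            lambda1 = lambda1, lambda0 = lambda0, d = d)
  if (any(!is.finite(vals))) {
    stop("all rates must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("all rates must be nonnegative", call. = FALSE)
  }
  if (d <= 0) {
    stop("degradation rate 'd' must be strictly positive", call. = FALSE)
  }
  structure(as.list(vals), class = "gene_params")
}

#' @export
print.gene_params <- function(x, ...) {
  cat("<gene_params>",
      sprintf("gamma1=%g gamma0=%g f=%g lambda1=%g lambda0=%g d=%g",
              x$gamma1, x$gamma0, x$f, x$lambda1, x$lambda0, x$d),
      sprintf("labeling: %s feedback", feedback_labeling(x)), sep = "\n")
  invisible(x)
}

#' Normalize all rates by the degradation rate
#'
#' Rescales time so that the product lifetime is the unit of time: every rate
#' is divided by `d` and `d` becomes 1. All dimensionless quantities (mean,
#' noise, burst size, distribution shape) are unchanged. Idempotent.
#'
#' @param params a [gene_params()] object.
#' @return A `gene_params` object with `d = 1`.
#' @export
normalize_params <- function(params) {
  stopifnot(inherits(params, "gene_params"))
  if (params$d == 1) return(params)
  gene_params(gamma1 = params$gamma1 / params$d,
              gamma0 = params$gamma0 / params$d,
              f = params$f / params$d,
              lambda1 = params$lambda1 / params$d,
              lambda0 = params$lambda0 / params$d,
              d = 1)
}

#' Feedback labeling of a parameter set
#'
#' Identifies which promoter state is ON (the one with the larger synthesis
#' rate) and hence the sign of the auto-regulation: `"negative"` when
#' \eqn{\lambda_1 > \lambda_0} (the product accelerates leaving the ON state
#' \eqn{D_1}; \eqn{\lambda_0} is the leakage rate), `"positive"` when
#' \eqn{\lambda_0 > \lambda_1} (the product accelerates entering the ON state
#' \eqn{D_0}; \eqn{\lambda_1} is the leakage rate), and `"constitutive"` on a
#' tie, where the promoter state is irrelevant to synthesis.
#'
#' @param params a [gene_params()] object.
#' @return One of `"negative"`, `"positive"`, `"constitutive"`.
#' @export
feedback_labeling <- function(params) {
  stopifnot(inherits(params, "gene_params"))
  if (params$lambda1 > params$lambda0) "negative"
  else if (params$lambda0 > params$lambda1) "positive"
  else "constitutive"
}

#' Leakage rate and ON-state synthesis rate under the current labeling
#'
#' @param params a [gene_params()] object.
#' @return Named numeric vector with elements `leakage` and `on_rate`.
#' @keywords internal
leakage_rate <- function(params) {
  if (feedback_labeling(params) == "positive") {
    c(leakage = params$lambda1, on_rate = params$lambda0)
  } else {
    c(leakage = params$lambda0, on_rate = params$lambda1)
  }
}

#' Derived constants of the analytical stationary distribution
#'
#' Computes the constants entering the closed-form stationary distribution of
#' the model (all rates degradation-normalized first):
#' \deqn{\lambda = \lambda_1 - \lambda_0,\qquad R = \lambda - f\lambda_0,\qquad
#'       Q = R/(f+1)^2,}
#' \deqn{g = \frac{\lambda + \gamma_1 + \gamma_0}{\gamma_1} -
#'       \frac{R}{\gamma_1 (f+1)},\qquad
#'       \alpha = 1 + \frac{\lambda\gamma_1}{R},\qquad
#'       \beta = 1 + \frac{\lambda + \gamma_0 + \gamma_1}{f+1} -
#'       \frac{R}{(f+1)^2},}
#' and the normalization prefactor
#' \eqn{A = e^{-\lambda_0} [g\,{}_1F_1(\alpha-1, \beta-1; fQ)]^{-1}}.
#'
#' The closed form degenerates as \eqn{R \to 0} (\eqn{\alpha} diverges);
#' below a relative tolerance on \eqn{|R|} the computation is refused and the
#' caller should use the chemical-master-equation solver
#' ([cme_steady_state()]) instead. Exception: the constitutive case
#' \eqn{\lambda_1 = \lambda_0}, \eqn{f = 0} is handled upstream as an exact
#' Poisson law and never reaches this function in normal use.
#'
#' @param params a [gene_params()] object (normalized internally).
#' @param tol relative tolerance on \eqn{|R|}; the threshold is
#'   `tol * max(lambda1, lambda0, 1)`.
#' @return An object of class `derived_constants`: list with elements
#'   `lam`, `R`, `Q`, `g`, `alpha`, `beta`, `A` plus `logA` (the log of
#'   \eqn{|A|}, kept for overflow-safe downstream use) and the normalized
#'   parameters.
#' @export
derived_constants <- function(params, tol = 1e-10) {
  p <- normalize_params(params)
  if (p$gamma1 <= 0) {
    stop("derived constants require gamma1 > 0 (otherwise the promoter never activates)",
         call. = FALSE)
  }
  lam <- p$lambda1 - p$lambda0
  R <- lam - p$f * p$lambda0
  if (abs(R) <= tol * max(p$lambda1, p$lambda0, 1)) {
    stop("degenerate parameters: |R| = |lambda - f*lambda0| is below tolerance; ",
         "the closed form is singular here - use cme_steady_state() instead",
         call. = FALSE)
  }
  fp1 <- p$f + 1
  Q <- R / fp1^2
  g <- (lam + p$gamma1 + p$gamma0) / p$gamma1 - R / (p$gamma1 * fp1)
  alpha <- 1 + lam * p$gamma1 / R
  beta <- 1 + (lam + p$gamma0 + p$gamma1) / fp1 - R / fp1^2
  h <- hyp1f1_log(alpha - 1, beta - 1, p$f * Q)
  # A = exp(-lambda0) / (g * 1F1(alpha-1, beta-1; f Q)); track the log
  logA <- -p$lambda0 - log(abs(g)) - h$log
  signA <- sign(g) * h$sign
  structure(list(lam = lam, R = R, Q = Q, g = g, alpha = alpha, beta = beta,
                 A = signA * exp(logA), logA = logA, signA = signA,
                 params = p),
            class = "derived_constants")
}

#' @export
print.derived_constants <- function(x, ...) {
  cat("<derived_constants>",
      sprintf("lambda=%g R=%g Q=%g g=%g alpha=%g beta=%g A=%g",
              x$lam, x$R, x$Q, x$g, x$alpha, x$beta, x$A), sep = "\n")
  invisible(x)
}

#' Read a parameter set from a flat YAML or JSON config file
#'
#' The file must contain the keys `gamma1`, `gamma0`, `f`, `lambda1`,
#' `lambda0` and optionally `d` (default 1) at top level.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [gene_params()] object.
#' @export
read_params <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    cfg <- yaml::read_yaml(path)
  }
  need <- c("gamma1", "gamma0", "f", "lambda1", "lambda0")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("config file is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  gene_params(gamma1 = cfg$gamma1, gamma0 = cfg$gamma0, f = cfg$f,
              lambda1 = cfg$lambda1, lambda0 = cfg$lambda0,
              d = if (is.null(cfg$d)) 1 else cfg$d)
}
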